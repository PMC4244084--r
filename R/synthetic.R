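# Synthetic trajectory generators with exact ground truth.
#
# The generators emulate the shape of the study system: ten 26-residue
# peptides (numbered 17-42, the alpha/gamma-secretase fragment of
# amyloid-beta) and one inhibitor entity of two 85-residue domains, in a
# periodic cubic box of ~124 A edge. Chains are coarse-grained to one bead
# (the C-alpha) per residue. The Markov generator gives exact per-frame
# ground truth for unit tests; the Brownian toy gives emergent aggregation
# for integration tests.

ABETA_17_42 <- "LVFFAEDVGSNKGAIIGLMVGGVVIA"

# Deterministic pseudo-sequence for synthetic inhibitor chains (no claim of
# biological identity; cycles through the 20 types so per-type profiles are
# exercised).
synthetic_sequence <- function(n, offset = 0L) {
  paste(AA1[((seq_len(n) - 1L + offset) %% 20L) + 1L], collapse = "")
}

# Single-character peptide chain identifiers (PDB chain fields hold one
# character); X and Y are reserved for the inhibitor domains.
pep_chain_ids <- function(n) {
  pool <- c(setdiff(LETTERS, c("X", "Y")), letters, as.character(0:9))
  if (n > length(pool)) stop("too many peptide chains for PDB chain ids")
  pool[seq_len(n)]
}

# Quasi-uniform points on a sphere (Fibonacci lattice), radius r.
fibonacci_sphere <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  r * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Compact globular peptide conformation: beads on a small sphere (radius
# `r_ball`) in spiral order. Conformational realism is not the point; the
# ball shape gives a well-defined docking footprint and easy placement.
peptide_ball <- function(n_res = 26L, r_ball = 5) {
  fibonacci_sphere(n_res, r_ball)
}

# Ideal helical chain with exact 3.8 A virtual bonds (100 degrees turn,
# 2.2 A rise); used where bonded dynamics need relaxed bond lengths.
peptide_helix <- function(n_res = 26L, bond = 3.8, rise = 2.2,
                          turn = 100 * pi / 180) {
  radius <- sqrt(bond^2 - rise^2) / (2 * sin(turn / 2))
  k <- seq_len(n_res) - 1
  xyz <- cbind(radius * cos(k * turn), radius * sin(k * turn), k * rise)
  sweep(xyz, 2, colMeans(xyz))
}

min_dist <- function(a, b, box = NULL) {
  # minimum pairwise distance between two coordinate sets (minimum image
  # when a box is given)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d * d
  }
  sqrt(min(d2))
}

count_close_res <- function(a, b, cutoff, box = NULL) {
  # number of rows of `a` whose nearest neighbour in `b` is within cutoff
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    d2 <- d2 + d * d
  }
  sum(sqrt(apply(d2, 1, min)) <= cutoff)
}

#' Build the synthetic system model
#'
#' @param n_peptides number of peptide chains (default 10)
#' @param peptide_length residues per peptide (default 26, numbered 17-42)
#' @param inhibitor include the two-domain inhibitor entity?
#' @param inhibitor_nres residues per inhibitor domain (default 85)
#' @return a \code{system_model}; peptide chains are named
#'   \code{P01, P02, ...}, inhibitor domains \code{X} and \code{Y}; every
#'   residue contributes one heavy atom named CA
#' @export
synthetic_system_model <- function(n_peptides = 10L, peptide_length = 26L,
                                   inhibitor = TRUE,
                                   inhibitor_nres = 85L) {
  pep_seq <- if (peptide_length == 26L) ABETA_17_42
             else synthetic_sequence(peptide_length, 3L)
  pep_res3 <- aa_one_to_three(strsplit(pep_seq, "")[[1]])
  rows <- list()
  roles <- character(0)
  ids <- pep_chain_ids(n_peptides)
  for (p in seq_len(n_peptides)) {
    cid <- ids[p]
    rows[[cid]] <- data.frame(
      chain = cid, resno = 17:(16 + peptide_length), resname = pep_res3,
      name = "CA", element = "C", stringsAsFactors = FALSE)
    roles[cid] <- "peptide"
  }
  if (inhibitor) {
    for (cid in c("X", "Y")) {
      sq <- synthetic_sequence(inhibitor_nres,
                               if (cid == "X") 0L else 7L)
      rows[[cid]] <- data.frame(
        chain = cid, resno = 66:(65 + inhibitor_nres),
        resname = aa_one_to_three(strsplit(sq, "")[[1]]),
        name = "CA", element = "C", stringsAsFactors = FALSE)
      roles[cid] <- "inhibitor"
    }
  }
  new_system_model(do.call(rbind, unname(rows)), roles)
}

#' Two-state Markov binding scenario
#'
#' Parameters of the synthetic binding trajectory generator. Defaults are
#' the emulated study conditions: ten 26-residue peptides and one
#' two-domain inhibitor in a 124 A cubic periodic box, frames every 0.1 ns
#' over 200 ns; unbound peptides keep at least 15 A heavy-atom separation
#' from the inhibitor and 10 A from one another.
#'
#' @param n_peptides number of peptides
#' @param k_on,k_off binding/unbinding rates per peptide, /ns
#' @param dt frame spacing, ns
#' @param n_frames number of frames
#' @param box_edge cubic box edge, Angstrom
#' @param peptide_length residues per peptide
#' @param inhibitor_nres residues per inhibitor domain (two domains)
#' @param inhibitor_radius radius of the inhibitor bead shell, Angstrom
#' @param jitter per-frame Gaussian positional noise sigma, Angstrom
#' @param min_inhibitor_sep minimum unbound peptide-inhibitor heavy-atom
#'   distance, Angstrom
#' @param min_peptide_sep minimum unbound peptide-peptide distance, Angstrom
#' @param initially_bound optional logical vector of initial states
#'   (default: stationary Bernoulli draw with p = k_on/(k_on+k_off))
#' @param seed integer seed
#' @return an object of class \code{kinetic_scenario}
#' @export
kinetic_scenario <- function(n_peptides = 10L, k_on = 0.02, k_off = 0.01,
                             dt = 0.1, n_frames = 2000L, box_edge = 124,
                             peptide_length = 26L, inhibitor_nres = 85L,
                             inhibitor_radius = 15, jitter = 0.3,
                             min_inhibitor_sep = 15, min_peptide_sep = 10,
                             initially_bound = NULL, seed = 1L) {
  stopifnot(k_on >= 0, k_off >= 0, dt > 0, n_frames >= 1)
  if (box_edge < 2 * (inhibitor_radius + min_inhibitor_sep + 12))
    stop("box too small for the separation constraints")
  structure(as.list(environment()), class = "kinetic_scenario")
}

# docking sites: icosahedron vertex directions (12 well-separated patches)
icosahedron_dirs <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, g), c(0, -1, g), c(0, 1, -g), c(0, -1, -g),
             c(1, g, 0), c(-1, g, 0), c(1, -g, 0), c(-1, -g, 0),
             c(g, 0, 1), c(g, 0, -1), c(-g, 0, 1), c(-g, 0, -1))
  v / sqrt(rowSums(v^2))
}

place_bound <- function(site_dir, center, r_inh, ball) {
  # dock the peptide ball so that its centre sits r_inh + 4.5 A from the
  # inhibitor centre along the site direction, with a random spin
  ctr <- center + site_dir * (r_inh + 4.5)
  sweep(ball %*% random_rotation(), 2, ctr, "+")
}

place_unbound <- function(ball, box, inh_xyz, others, min_inh, min_pep,
                          max_tries = 2000L) {
  for (try in seq_len(max_tries)) {
    ctr <- runif(3, 0, box[1])
    cand <- sweep(ball %*% random_rotation(), 2, ctr, "+")
    if (!is.null(inh_xyz) &&
        min_dist(cand, inh_xyz, box) < min_inh) next
    ok <- TRUE
    for (o in others) {
      if (!is.null(o) && min_dist(cand, o, box) < min_pep) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(cand)
  }
  stop("could not place an unbound peptide; box too crowded")
}

#' Generate a two-state Markov binding trajectory with ground truth
#'
#' Each peptide's bound state evolves as an independent two-state Markov
#' chain with per-step switching probabilities 1 - exp(-k dt). Bound
#' peptides are docked (as compact beads-on-a-sphere globules) at one of 12
#' well-separated surface sites of the inhibitor shell, guaranteeing more
#' than five residue contacts with the inhibitor and none with other
#' peptides; unbound peptides are placed uniformly subject to the minimum
#' separation constraints. Poses persist between state switches; small
#' Gaussian jitter is added every frame. The bound and unbound geometry
#' templates are self-validated against the contact rules at generation
#' time.
#'
#' @param scenario a \code{kinetic_scenario}
#' @return list with \code{trajectory} (a \code{trajectory}) and
#'   \code{truth}: \code{bound} (n_frames x n_peptides logical matrix),
#'   \code{residence_ns} (realized completed bound-interval durations),
#'   \code{scenario}
#' @export
markov_binding_generator <- function(scenario) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  model <- synthetic_system_model(sc$n_peptides, sc$peptide_length,
                                  inhibitor = TRUE, sc$inhibitor_nres)
  box <- rep(sc$box_edge, 3)
  center <- box / 2
  n_inh <- 2L * sc$inhibitor_nres
  inh_xyz <- sweep(fibonacci_sphere(n_inh, sc$inhibitor_radius), 2,
                   center, "+")
  ball <- peptide_ball(sc$peptide_length)
  sites <- icosahedron_dirs()

  # template self-validation: a docked ball must give > 5 residue contacts
  # with margin; a placement at the separation limit must give none
  probe <- place_bound(sites[1, ], center, sc$inhibitor_radius, ball)
  ncontact <- count_close_res(probe, inh_xyz, 5.0, box)
  ntight <- count_close_res(probe, inh_xyz, 4.0, box)
  if (ncontact <= 5 || ntight < 7)
    stop("bound-pose template failed self-validation (", ncontact,
         " contacts at 5 A, ", ntight, " at 4 A)")
  if (sc$min_inhibitor_sep <= 5 + 6 * sc$jitter)
    stop("unbound separation too small to guarantee zero contacts")

  p_on <- 1 - exp(-sc$k_on * sc$dt)
  p_off <- 1 - exp(-sc$k_off * sc$dt)
  p0 <- if (sc$k_on + sc$k_off > 0) sc$k_on / (sc$k_on + sc$k_off) else 0
  np <- sc$n_peptides
  state <- if (is.null(sc$initially_bound))
    runif(np) < p0 else rep_len(sc$initially_bound, np)

  site_of <- rep(NA_integer_, np)
  pose <- vector("list", np)
  assign_site <- function(p) {
    free <- setdiff(seq_len(nrow(sites)), site_of[-p])
    if (length(free) == 0) stop("no free docking site")
    if (length(free) == 1) free else sample(free, 1)
  }
  for (p in seq_len(np)) {
    if (state[p]) {
      site_of[p] <- assign_site(p)
      pose[[p]] <- place_bound(sites[site_of[p], ], center,
                               sc$inhibitor_radius, ball)
    }
  }
  for (p in seq_len(np)) {
    if (!state[p])
      pose[[p]] <- place_unbound(ball, box, inh_xyz, pose[-p],
                                 sc$min_inhibitor_sep, sc$min_peptide_sep)
  }

  natoms <- model$natoms
  coords <- array(0, c(natoms, 3, sc$n_frames))
  bound <- matrix(FALSE, sc$n_frames, np,
                  dimnames = list(NULL, chains_by_role(model, "peptide")))
  pep_ids <- chains_by_role(model, "peptide")
  pep_rows <- lapply(seq_len(np), function(p)
    which(model$atoms$chain == pep_ids[p]))
  inh_rows <- which(model$atoms$chain %in% c("X", "Y"))
  base <- matrix(0, natoms, 3)
  base[inh_rows, ] <- inh_xyz

  for (f in seq_len(sc$n_frames)) {
    if (f > 1) {
      flip <- runif(np)
      for (p in seq_len(np)) {
        if (state[p] && flip[p] < p_off) {
          state[p] <- FALSE
          site_of[p] <- NA_integer_
          pose[[p]] <- place_unbound(ball, box, inh_xyz, pose[-p],
                                     sc$min_inhibitor_sep,
                                     sc$min_peptide_sep)
        } else if (!state[p] && flip[p] < p_on) {
          state[p] <- TRUE
          site_of[p] <- assign_site(p)
          pose[[p]] <- place_bound(sites[site_of[p], ], center,
                                   sc$inhibitor_radius, ball)
          # an unbound peptide drifting near the docking region could now
          # graze the fresh pose; re-place any such peptide (its own bound
          # state and contacts are unaffected)
          for (q in seq_len(np)) {
            if (q == p || state[q]) next
            if (min_dist(pose[[p]], pose[[q]], box) < sc$min_peptide_sep)
              pose[[q]] <- place_unbound(ball, box, inh_xyz, pose[-q],
                                         sc$min_inhibitor_sep,
                                         sc$min_peptide_sep)
          }
        }
      }
    }
    for (p in seq_len(np)) base[pep_rows[[p]], ] <- pose[[p]]
    coords[, , f] <- base +
      matrix(rnorm(natoms * 3, 0, sc$jitter), natoms, 3)
    bound[f, ] <- state
  }
  times <- (seq_len(sc$n_frames) - 1) * sc$dt
  traj <- trajectory(model, times, coords, box)
  residence <- numeric(0)
  for (p in seq_len(np)) {
    r <- rle(bound[, p])
    keep <- r$values
    # completed intervals only: drop a bound run touching either end
    if (length(keep) > 0 && keep[1]) keep[1] <- FALSE
    if (length(keep) > 0 && keep[length(keep)]) keep[length(keep)] <- FALSE
    residence <- c(residence, r$lengths[keep] * sc$dt)
  }
  list(trajectory = traj,
       truth = list(bound = bound, residence_ns = residence,
                    scenario = sc))
}

#' Construct a single frame with a prescribed oligomer composition
#'
#' Places peptide chains so that consecutive members of an oligomer share at
#' least six residue contacts, distinct oligomers share none, and each
#' inhibitor-bound oligomer has exactly one member with more than five
#' inhibitor contacts. The scene is self-validated against the contacts
#' module before it is returned.
#'
#' @param sizes integer vector of oligomer sizes (must sum to the number of
#'   peptides placed; monomers are size 1)
#' @param bound logical vector, one per oligomer: docked on the inhibitor?
#' @param inhibitor include the inhibitor entity? (required when any
#'   oligomer is bound)
#' @param box_edge cubic box edge, Angstrom
#' @param peptide_length residues per peptide
#' @param inhibitor_nres residues per inhibitor domain
#' @param inhibitor_radius inhibitor shell radius, Angstrom
#' @param time frame time stamp, ns
#' @param seed integer seed (placement directions)
#' @return list with \code{model}, \code{frame} (a \code{traj_frame}) and
#'   \code{truth} (the intended partition, per-peptide bound flags and
#'   per-oligomer complexed flags)
#' @export
oligomer_scene_builder <- function(sizes, bound = rep(FALSE, length(sizes)),
                                   inhibitor = TRUE, box_edge = 124,
                                   peptide_length = 26L,
                                   inhibitor_nres = 85L,
                                   inhibitor_radius = 15, time = 0,
                                   seed = 1L) {
  stopifnot(length(bound) == length(sizes), all(sizes >= 1))
  if (any(bound) && !inhibitor)
    stop("bound oligomers require an inhibitor in the scene")
  if (sum(bound) > 12) stop("at most 12 bound oligomers fit the sites")
  set.seed(seed)
  np <- sum(sizes)
  model <- synthetic_system_model(np, peptide_length, inhibitor,
                                  inhibitor_nres)
  box <- rep(box_edge, 3)
  center <- box / 2
  inh_xyz <- if (inhibitor)
    sweep(fibonacci_sphere(2L * inhibitor_nres, inhibitor_radius), 2,
          center, "+") else NULL
  ball <- peptide_ball(peptide_length)
  sites <- icosahedron_dirs()
  site_pool <- sample(nrow(sites))
  pep_chains <- chains_by_role(model, "peptide")

  poses <- vector("list", np)
  partition <- vector("list", length(sizes))
  bound_flag <- setNames(rep(FALSE, np), pep_chains)
  pnext <- 1L
  stack_step <- 8.5   # centre-centre spacing of members within an oligomer
  free_anchors <- list()
  site_i <- 1L
  for (g in seq_along(sizes)) {
    members <- pnext:(pnext + sizes[g] - 1L)
    partition[[g]] <- pep_chains[members]
    if (bound[g]) {
      dir <- sites[site_pool[site_i], ]
      site_i <- site_i + 1L
      for (m in seq_along(members)) {
        ctr <- center + dir * (inhibitor_radius + 4.5 +
                                 stack_step * (m - 1))
        poses[[members[m]]] <- sweep(ball %*% random_rotation(), 2,
                                     ctr, "+")
      }
      bound_flag[members[1]] <- TRUE
    } else {
      # free group: linear stack along a random direction, rejection-placed
      for (try in seq_len(2000L)) {
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        ctr0 <- runif(3, 0, box[1])
        cand <- lapply(seq_len(sizes[g]), function(m)
          sweep(ball %*% random_rotation(), 2,
                ctr0 + dir * stack_step * (m - 1), "+"))
        all_c <- do.call(rbind, cand)
        ok <- is.null(inh_xyz) || min_dist(all_c, inh_xyz, box) >= 15
        if (ok) for (o in poses) {
          if (!is.null(o) && min_dist(all_c, o, box) < 10) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          for (m in seq_along(members)) poses[[members[m]]] <- cand[[m]]
          break
        }
        if (try == 2000L) stop("could not place a free oligomer; ",
                               "composition does not fit the box")
      }
    }
    pnext <- pnext + sizes[g]
  }

  xyz <- matrix(0, model$natoms, 3)
  if (inhibitor) xyz[model$atoms$chain %in% c("X", "Y"), ] <- inh_xyz
  for (p in seq_len(np))
    xyz[model$atoms$chain == pep_chains[p], ] <- poses[[p]]
  fr <- frame(time, xyz, box)

  # self-validate with the contacts module
  state <- aggregation_state(residue_contacts(fr, model), model,
                             threshold = 5L)
  got <- lapply(state$oligomers, sort)
  want <- lapply(partition, sort)
  if (!setequal(sapply(got, paste, collapse = ","),
                sapply(want, paste, collapse = ",")))
    stop("scene self-validation failed: oligomer partition mismatch")
  if (inhibitor && !identical(unname(state$bound[pep_chains]),
                              unname(bound_flag[pep_chains])))
    stop("scene self-validation failed: complexation flags mismatch")
  list(model = model, frame = fr,
       truth = list(partition = partition, bound = bound_flag,
                    complexed = bound))
}

#' Replicate a frame into a short jittered trajectory
#'
#' @param fr a \code{traj_frame}
#' @param model the matching \code{system_model}
#' @param n_frames number of frames
#' @param dt frame spacing, ns
#' @param jitter Gaussian noise sigma, Angstrom (0 = static)
#' @param seed integer seed
#' @return a \code{trajectory}
#' @export
replicate_frame <- function(fr, model, n_frames = 10L, dt = 0.1,
                            jitter = 0, seed = 1L) {
  set.seed(seed)
  coords <- array(0, c(model$natoms, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- fr$xyz +
      if (jitter > 0) matrix(rnorm(model$natoms * 3, 0, jitter),
                             model$natoms, 3) else 0
  trajectory(model, fr$time + (seq_len(n_frames) - 1) * dt, coords, fr$box)
}

#' Brownian bead-chain toy simulator
#'
#' Overdamped Langevin dynamics of single-bead-per-residue peptide chains
#' (harmonic bonds, soft-core repulsion, short-range Gaussian attraction)
#' around a frozen inhibitor bead shell with per-bead stickiness, in a
#' periodic cubic box. A uniformly sticky shell mimics a uniformly
#' attractive inhibitor surface; a patchy shell (a fraction of sticky
#' beads) mimics a heterogeneous one. Intended for qualitative,
#' emergent-aggregation integration tests, not thermodynamic realism.
#'
#' @param n_peptides number of peptide chains
#' @param peptide_length residues (beads) per chain
#' @param box_edge cubic box edge, Angstrom
#' @param eps_pp peptide-peptide attraction well depth, kcal/mol
#' @param inhibitor include the frozen inhibitor shell?
#' @param inhibitor_nres residues per inhibitor domain
#' @param inhibitor_radius shell radius, Angstrom
#' @param stickiness inhibitor-peptide well depth, kcal/mol (scalar, or one
#'   value per inhibitor bead for patchy surfaces)
#' @param temperature K (sets kBT for the mobility)
#' @param diff_coef bead diffusion coefficient, A^2/ns
#' @param dt integration step, ns. Stability heuristic: the stiffest chain
#'   mode feels ~8x the bond constant, so (D/kBT)*dt*8*k_bond must stay
#'   below ~1; the default step satisfies this with a safety margin
#' @param n_steps number of integration steps
#' @param save_every save a frame every this many steps
#' @param seed integer seed
#' @return list with \code{trajectory} and \code{model}
#' @export
brownian_toy_sim <- function(n_peptides = 10L, peptide_length = 26L,
                             box_edge = 120, eps_pp = 0,
                             inhibitor = TRUE, inhibitor_nres = 85L,
                             inhibitor_radius = 15, stickiness = 0,
                             temperature = 325, diff_coef = 50,
                             dt = 5e-4, n_steps = 10000L,
                             save_every = 100L, seed = 1L) {
  stopifnot(dt > 0, diff_coef > 0, n_steps >= save_every)
  set.seed(seed)
  model <- synthetic_system_model(n_peptides, peptide_length, inhibitor,
                                  inhibitor_nres)
  box <- rep(box_edge, 3)
  center <- box / 2
  natoms <- model$natoms
  xyz <- matrix(0, natoms, 3)
  n_inh <- if (inhibitor) 2L * inhibitor_nres else 0L
  moving <- rep(TRUE, natoms)
  type <- integer(natoms)
  sticky <- numeric(natoms)
  if (inhibitor) {
    rows <- which(model$atoms$chain %in% c("X", "Y"))
    xyz[rows, ] <- sweep(fibonacci_sphere(n_inh, inhibitor_radius), 2,
                         center, "+")
    moving[rows] <- FALSE
    type[rows] <- 1L
    sticky[rows] <- rep_len(stickiness, n_inh)
  }
  helix <- peptide_helix(peptide_length)
  pep_chains <- chains_by_role(model, "peptide")
  placed <- list()
  for (p in seq_along(pep_chains)) {
    pos <- place_unbound(helix, box, if (inhibitor)
      xyz[type == 1L, , drop = FALSE] else NULL, placed, 12, 8)
    placed[[p]] <- pos
    xyz[model$atoms$chain == pep_chains[p], ] <- pos
  }
  # bonds between consecutive beads of each moving chain
  bonds <- do.call(rbind, lapply(pep_chains, function(cid) {
    rows <- which(model$atoms$chain == cid)
    cbind(rows[-length(rows)], rows[-1])
  }))
  seqidx <- model$atoms$resno
  chain_code <- match(model$atoms$chain, model$chain_ids)
  kBT <- 0.0019872041 * temperature
  res <- .cpp_brownian(xyz, moving, chain_code, seqidx, type, sticky,
                       eps_pp, k_bond = 2, r_bond = 3.8, bonds = bonds,
                       k_rep = 2, r_rep = 4.0, r_min = 4.5, width = 1.5,
                       r_cut = 10, diff_coef = diff_coef, kBT = kBT,
                       dt = dt, n_steps = as.integer(n_steps),
                       save_every = as.integer(save_every), box = box,
                       max_disp = 5)
  list(trajectory = trajectory(model, res$times, res$coords, box),
       model = model)
}
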