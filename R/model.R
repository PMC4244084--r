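#' @useDynLib oligotraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom setNames optim lm coef sd
#' @importFrom utils head tail write.table read.table
NULL

CHARGED_POS <- c("K", "R")
CHARGED_NEG <- c("D", "E")
AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
         "T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
         "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' Convert between 1- and 3-letter amino-acid codes
#' @param x character vector of codes
#' @return character vector of converted codes
#' @keywords internal
aa_three_to_one <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out[is.na(out)] <- "X"
  out
}

aa_one_to_three <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  if (anyNA(out)) stop("unknown 1-letter residue code: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# ---- SystemModel -----------------------------------------------------------

new_system_model <- function(atoms, roles) {
  # atoms: data.frame(chain, resno, resname, name, element) in file order
  chain_ids <- unique(atoms$chain)
  missing <- setdiff(chain_ids, names(roles))
  if (length(missing) > 0)
    stop("no role assigned to chain(s): ", paste(missing, collapse = ", "))
  roles <- roles[chain_ids]
  if (!all(roles %in% c("peptide", "inhibitor")))
    stop("chain roles must be 'peptide' or 'inhibitor'")
  if (!any(roles == "peptide"))
    stop("at least one chain must have role 'peptide'")

  key <- paste(atoms$chain, atoms$resno)
  res_index <- match(key, unique(key))
  atoms$res_index <- res_index
  res_first <- !duplicated(res_index)
  residues <- data.frame(
    chain   = atoms$chain[res_first],
    resno   = atoms$resno[res_first],
    resname = atoms$resname[res_first],
    stringsAsFactors = FALSE
  )
  for (cid in chain_ids) {
    rn <- residues$resno[residues$chain == cid]
    if (any(diff(rn) <= 0))
      stop("residue numbering not strictly increasing in chain ", cid)
  }
  res_chain <- match(residues$chain, chain_ids)
  chains <- lapply(seq_along(chain_ids), function(i) {
    sel <- residues$chain == chain_ids[i]
    list(id = chain_ids[i], role = unname(roles[i]),
         resno = residues$resno[sel], resname = residues$resname[sel])
  })
  names(chains) <- chain_ids
  structure(list(
    chains = chains,
    atoms = atoms,
    residues = residues,
    res_chain = res_chain,
    chain_ids = chain_ids,
    roles = setNames(unname(roles), chain_ids),
    natoms = nrow(atoms),
    nres = nrow(residues)
  ), class = "system_model")
}

#' Load a structure file into a SystemModel
#'
#' Reads a PDB-style structure, drops hydrogens, and records the chain,
#' residue and heavy-atom topology. Every chain present in the file must be
#' assigned a role of either \code{"peptide"} or \code{"inhibitor"}.
#' A multi-chain inhibitor (e.g. the two domains of an alpha-crystallin-domain
#' dimer) is treated as one logical inhibitor entity.
#'
#' @param path path to a PDB file
#' @param roles named character vector mapping chain id to role
#'   (\code{"peptide"} or \code{"inhibitor"})
#' @return an object of class \code{system_model}
#' @export
load_system <- function(path, roles) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse structure file '",
                                           path, "': ", conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  bad <- is.na(elem) | elem == "" | elem == " "
  if (any(bad)) {
    # fall back to first alphabetic character of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", at$elety[bad]))
    elem[bad] <- substr(nm, 1, 1)
  }
  heavy <- toupper(elem) != "H"
  at <- at[heavy, , drop = FALSE]
  atoms <- data.frame(
    chain   = as.character(at$chain),
    resno   = as.integer(at$resno),
    resname = as.character(at$resid),
    name    = as.character(at$elety),
    element = toupper(elem[heavy]),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  m <- new_system_model(atoms[, c("chain", "resno", "resname", "name",
                                  "element")], roles)
  attr(m, "ref_xyz") <- as.matrix(atoms[, c("x", "y", "z")])
  m
}

#' @export
print.system_model <- function(x, ...) {
  cat("SystemModel:", length(x$chains), "chains,", x$nres, "residues,",
      x$natoms, "heavy atoms\n")
  for (ch in x$chains)
    cat(sprintf("  chain %s [%s]: %d residues (%d-%d)\n", ch$id, ch$role,
                length(ch$resno), min(ch$resno), max(ch$resno)))
  invisible(x)
}

#' Chains of a given role
#' @param model a \code{system_model}
#' @param role \code{"peptide"} or \code{"inhibitor"}
#' @return character vector of chain ids
#' @export
chains_by_role <- function(model, role) {
  stopifnot(inherits(model, "system_model"))
  names(model$roles)[model$roles == role]
}

#' Select heavy-atom indices by chain, role or atom name
#' @param model a \code{system_model}
#' @param role optional role filter
#' @param chains optional chain-id filter
#' @param atom_names optional atom-name filter (e.g. \code{"CA"})
#' @return integer vector of atom indices into the model's atom table
#' @export
select_atoms <- function(model, role = NULL, chains = NULL,
                         atom_names = NULL) {
  stopifnot(inherits(model, "system_model"))
  keep <- rep(TRUE, model$natoms)
  if (!is.null(role))
    keep <- keep & model$atoms$chain %in% chains_by_role(model, role)
  if (!is.null(chains)) keep <- keep & model$atoms$chain %in% chains
  if (!is.null(atom_names))
    keep <- keep & trimws(model$atoms$name) %in% atom_names
  which(keep)
}

# ---- Frame / Trajectory ----------------------------------------------------

#' Construct a single coordinate frame
#' @param time time stamp in ns
#' @param xyz numeric matrix (n_atoms x 3), Angstrom
#' @param box orthorhombic box edge lengths (Lx, Ly, Lz), Angstrom
#' @return an object of class \code{traj_frame}
#' @export
frame <- function(time, xyz, box) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, length(box) == 3)
  if (any(box <= 0)) stop("all box edges must be > 0")
  structure(list(time = as.numeric(time), xyz = xyz,
                 box = as.numeric(box)), class = "traj_frame")
}

#' Construct a trajectory
#' @param model a \code{system_model}
#' @param times frame time stamps in ns (strictly increasing)
#' @param coords numeric array (n_atoms x 3 x n_frames), Angstrom
#' @param box either a length-3 vector (constant box) or an
#'   (n_frames x 3) matrix
#' @return an object of class \code{trajectory}
#' @export
trajectory <- function(model, times, coords, box) {
  stopifnot(inherits(model, "system_model"))
  dm <- dim(coords)
  if (length(dm) != 3 || dm[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dm[1] != model$natoms)
    stop("atom count mismatch: coords have ", dm[1], " atoms, model has ",
         model$natoms)
  nf <- dm[3]
  if (length(times) != nf) stop("length(times) must equal n_frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (any(box <= 0)) stop("all box edges must be > 0")
  dt <- if (nf > 1) stats::median(diff(times)) else NA_real_
  structure(list(model = model, times = as.numeric(times), coords = coords,
                 box = box, dt = dt, n_frames = nf),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %.3g-%.4g ns (dt ~ %.3g ns), %d atoms\n",
              x$n_frames, x$times[1], x$times[x$n_frames], x$dt,
              x$model$natoms))
  invisible(x)
}

#' Extract one frame from a trajectory
#' @param traj a \code{trajectory}
#' @param i frame index (1-based)
#' @return a \code{traj_frame}
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= traj$n_frames)
  frame(traj$times[i], traj$coords[, , i, drop = TRUE], traj$box[i, ])
}

#' Number of frames
#' @param traj a \code{trajectory}
#' @return integer
#' @export
n_frames <- function(traj) traj$n_frames

# ---- plain-text trajectory format -----------------------------------------

#' Write a trajectory in the plain-text fallback format
#'
#' Self-describing text format used for fixtures and archival: a header line
#' with the atom count, then one \code{frame <time> <Lx> <Ly> <Lz>} line per
#' frame followed by \code{n_atoms} rows of \code{x y z} (Angstrom).
#'
#' @param traj a \code{trajectory}
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# oligotraj-trajectory 1",
               paste("natoms", traj$model$natoms)), con)
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("frame %.10g %.10g %.10g %.10g", traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    xyz <- traj$coords[, , f]
    writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory from the plain-text fallback format
#'
#' Frames are returned in file order and must carry strictly increasing time
#' stamps; the atom count in the header must match the model.
#'
#' @param path input file path
#' @param model the \code{system_model} the coordinates belong to
#' @return a \code{trajectory}
#' @export
read_trajectory <- function(path, model) {
  stopifnot(inherits(model, "system_model"))
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^# oligotraj-trajectory", lines[1]))
    stop("not an oligotraj trajectory file: ", path)
  natoms <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]][2])
  if (is.na(natoms) || natoms <= 0) stop("bad atom count header in ", path)
  if (natoms != model$natoms)
    stop("atom count mismatch: file has ", natoms, " atoms, model has ",
         model$natoms)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  per_frame <- natoms + 1
  if (length(body) %% per_frame != 0)
    stop("truncated trajectory file: ", path)
  nf <- length(body) %/% per_frame
  times <- numeric(nf)
  box <- matrix(0, nf, 3)
  coords <- array(0, c(natoms, 3, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1) * per_frame
    hdr <- strsplit(trimws(body[off + 1]), "\\s+")[[1]]
    if (hdr[1] != "frame") stop("malformed frame header at frame ", f)
    times[f] <- as.numeric(hdr[2])
    box[f, ] <- as.numeric(hdr[3:5])
    xyz <- scan(text = body[(off + 2):(off + per_frame)], quiet = TRUE)
    coords[, , f] <- matrix(xyz, natoms, 3, byrow = TRUE)
  }
  if (nf > 1 && any(diff(times) <= 0))
    stop("non-monotonic frame times in ", path)
  trajectory(model, times, coords, box)
}

# ---- system-preparation arithmetic ----------------------------------------

#' Formal charge of a peptide sequence at pH 7
#'
#' Sums side-chain formal charges (Asp, Glu: -1; Lys, Arg: +1; His treated as
#' neutral) and, when \code{charged_termini} is \code{TRUE}, records the
#' N-terminal +1 and C-terminal -1 contributions (which cancel in the total).
#'
#' @param sequence 1-letter amino-acid string (20 standard residues)
#' @param charged_termini logical; are the termini charged (NH3+/COO-)?
#' @return integer net charge in units of e, with attributes
#'   \code{side_chain}, \code{n_term} and \code{c_term} giving the breakdown
#' @export
formal_charge <- function(sequence, charged_termini = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(aa, AA1)
  if (length(unknown) > 0)
    stop("unknown residue letter(s): ", paste(unknown, collapse = ", "))
  side <- sum(aa %in% CHARGED_POS) - sum(aa %in% CHARGED_NEG)
  nt <- if (charged_termini) 1L else 0L
  ct <- if (charged_termini) -1L else 0L
  structure(as.integer(side + nt + ct),
            side_chain = as.integer(side), n_term = nt, c_term = ct)
}

#' Molar concentration of n molecules in an orthorhombic box
#'
#' @param n number of molecules
#' @param edges box edge lengths in Angstrom (length 1 for cubic, or 3)
#' @return concentration in mM
#' @export
molar_concentration <- function(n, edges) {
  stopifnot(n >= 0)
  if (length(edges) == 1) edges <- rep(edges, 3)
  stopifnot(length(edges) == 3)
  if (any(edges <= 0)) stop("box edges must be positive")
  avogadro <- 6.02214076e23
  vol_l <- prod(edges) * 1e-27          # A^3 -> litres
  1000 * n / (avogadro * vol_l)         # mol/L -> mM
}

#' Write a SystemModel + coordinates as a PDB file
#'
#' Emits the topology of a (typically synthetic) system so external tools
#' and \code{\link{load_system}} can round-trip it.
#'
#' @param model a \code{system_model}
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom)
#' @param path output PDB path
#' @return invisibly, \code{path}
#' @export
write_system_pdb <- function(model, xyz, path) {
  stopifnot(inherits(model, "system_model"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != model$natoms) stop("coordinate/atom count mismatch")
  if (any(nchar(model$chain_ids) != 1))
    stop("PDB chain identifiers are single characters; chain id(s) ",
         paste(model$chain_ids[nchar(model$chain_ids) != 1],
               collapse = ", "), " cannot be written")
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   type = rep("ATOM", model$natoms),
                   resno = at$resno, resid = at$resname,
                   chain = at$chain, elety = at$name,
                   eleno = seq_len(model$natoms),
                   elesy = at$element)
  invisible(path)
}

#' Read a 1-letter sequence from a plain-text file
#'
#' Skips comment lines starting with \code{#} and concatenates the rest.
#'
#' @param path text file path
#' @return single character string
#' @export
read_sequence <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gsub("\\s", "", paste(lines, collapse = ""))
}

#' Read a binary DCD trajectory
#'
#' Thin adapter over \code{bio3d::read.dcd} producing a \code{trajectory}.
#' DCD files do not carry reliable physical time stamps, so the frame
#' spacing is supplied explicitly. The per-frame unit cell is used when the
#' file stores one; otherwise a constant box must be given.
#'
#' @param path DCD file path
#' @param model the matching \code{system_model}
#' @param dt frame spacing in ns
#' @param t0 time of the first frame in ns
#' @param box fallback orthorhombic box edges (Lx, Ly, Lz) in Angstrom,
#'   used when the file has no cell information
#' @return a \code{trajectory}
#' @export
read_trajectory_dcd <- function(path, model, dt, t0 = 0, box = NULL) {
  stopifnot(inherits(model, "system_model"), dt > 0)
  dcd <- bio3d::read.dcd(path, verbose = FALSE)
  xyz <- if (is.matrix(dcd)) dcd else as.matrix(dcd)
  nf <- nrow(xyz)
  natoms <- ncol(xyz) / 3
  if (natoms != model$natoms)
    stop("atom count mismatch: file has ", natoms, " atoms, model has ",
         model$natoms)
  coords <- array(0, c(natoms, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], natoms, 3, byrow = TRUE)
  cell <- attr(dcd, "cell")
  boxes <- if (!is.null(cell)) as.matrix(cell)[, 1:3, drop = FALSE]
           else if (!is.null(box)) matrix(box, nf, 3, byrow = TRUE)
           else stop("file carries no unit cell; supply `box`")
  trajectory(model, t0 + (seq_len(nf) - 1) * dt, coords, boxes)
}
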