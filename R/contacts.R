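# Residue-residue heavy-atom contact detection.
#
# Two residues are in contact when any pair of their heavy atoms lies within
# the cutoff (default 5 A), measured under the minimum-image convention in an
# orthorhombic periodic box. A distance exactly at the cutoff counts as a
# contact. "Number of contacts" between two chains is the number of residue
# pairs in contact (an atom-pair count is available via `count = "atom"`).

#' Contact-detection configuration
#'
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 5)
#' @param minimum_image apply the minimum-image convention (orthorhombic
#'   boxes only)?
#' @param method neighbor search: \code{"auto"} (cell list for large periodic
#'   systems, brute force otherwise), \code{"cells"}, or \code{"brute"}
#' @return an object of class \code{contact_config}
#' @export
contact_config <- function(cutoff = 5.0, minimum_image = TRUE,
                           method = c("auto", "cells", "brute")) {
  stopifnot(cutoff > 0)
  method <- match.arg(method)
  structure(list(cutoff = cutoff, minimum_image = minimum_image,
                 method = method), class = "contact_config")
}

method_code <- function(config) {
  match(config$method, c("auto", "cells", "brute")) - 1L
}

check_image_ambiguity <- function(box, config) {
  if (config$minimum_image && any(box < 2 * config$cutoff))
    warning("box edge smaller than twice the cutoff: minimum-image ",
            "distances may be ambiguous", call. = FALSE)
}

#' Residue-residue contacts in one frame
#'
#' @param fr a \code{traj_frame}
#' @param model the \code{system_model}
#' @param config a \code{contact_config}
#' @return an object of class \code{contact_record} with elements
#'   \code{time}, \code{pairs} (m x 2 matrix of global residue indices,
#'   i < j), \code{atom_counts} (heavy-atom pairs within the cutoff per
#'   residue pair), and \code{chain_counts} (chain x chain matrix of
#'   residue-pair contact counts; diagonal = intra-chain pairs)
#' @export
residue_contacts <- function(fr, model, config = contact_config()) {
  stopifnot(inherits(fr, "traj_frame"), inherits(model, "system_model"))
  if (nrow(fr$xyz) != model$natoms)
    stop("frame/model atom count mismatch")
  check_image_ambiguity(fr$box, config)
  res <- .cpp_frame_contacts(fr$xyz, model$atoms$res_index,
                             model$res_chain, fr$box, config$cutoff,
                             config$minimum_image, method_code(config))
  dimnames(res$chain_counts) <- list(model$chain_ids, model$chain_ids)
  structure(list(time = fr$time, pairs = res$pairs,
                 atom_counts = res$atom_counts,
                 chain_counts = res$chain_counts,
                 model = model, config = config),
            class = "contact_record")
}

#' @export
print.contact_record <- function(x, ...) {
  cat(sprintf("ContactRecord @ %.4g ns: %d residue pairs in contact\n",
              x$time, nrow(x$pairs)))
  invisible(x)
}

#' Brute-force contact oracle (pure R)
#'
#' Reference O(n^2) implementation used to validate the neighbor-search
#' kernel; computes every heavy-atom pair distance explicitly.
#'
#' @inheritParams residue_contacts
#' @return m x 2 matrix of residue-index pairs (i < j) in contact
#' @export
residue_contacts_brute <- function(fr, model, config = contact_config()) {
  stopifnot(inherits(fr, "traj_frame"), inherits(model, "system_model"))
  xyz <- fr$xyz
  n <- nrow(xyz)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    d <- outer(xyz[, k], xyz[, k], "-")
    if (config$minimum_image) d <- d - fr$box[k] * round(d / fr$box[k])
    d2 <- d2 + d * d
  }
  hit <- which(d2 <= config$cutoff^2 & upper.tri(d2), arr.ind = TRUE)
  ri <- model$atoms$res_index[hit[, 1]]
  rj <- model$atoms$res_index[hit[, 2]]
  keep <- ri != rj
  pr <- cbind(pmin(ri[keep], rj[keep]), pmax(ri[keep], rj[keep]))
  pr <- unique(pr)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  dimnames(pr) <- NULL
  pr
}

#' Number of residue-pair contacts between two chain sets
#'
#' @param record a \code{contact_record}
#' @param chains_a,chains_b disjoint sets of chain ids
#' @param count \code{"residue"} for residue-pair counts (default) or
#'   \code{"atom"} for heavy-atom-pair counts
#' @return integer contact count
#' @export
chain_pair_contact_count <- function(record, chains_a, chains_b,
                                     count = c("residue", "atom")) {
  stopifnot(inherits(record, "contact_record"))
  count <- match.arg(count)
  if (length(intersect(chains_a, chains_b)) > 0)
    stop("chain sets must be disjoint")
  model <- record$model
  ca <- match(chains_a, model$chain_ids)
  cb <- match(chains_b, model$chain_ids)
  if (anyNA(ca) || anyNA(cb)) stop("unknown chain id")
  if (count == "residue")
    return(sum(record$chain_counts[ca, cb, drop = FALSE]))
  chain_of <- model$res_chain
  ci <- chain_of[record$pairs[, 1]]
  cj <- chain_of[record$pairs[, 2]]
  sel <- (ci %in% ca & cj %in% cb) | (ci %in% cb & cj %in% ca)
  sum(record$atom_counts[sel])
}

#' Per-frame chain-pair contact counts over a trajectory
#'
#' Computes, for every frame, the matrix of residue-pair contact counts
#' between every pair of chains. This is the workhorse input for species
#' classification, binding kinetics and the contact-count landscapes.
#'
#' @param traj a \code{trajectory}
#' @param config a \code{contact_config}
#' @return integer array (n_chains x n_chains x n_frames) with chain-id
#'   dimnames
#' @export
trajectory_chain_counts <- function(traj, config = contact_config()) {
  stopifnot(inherits(traj, "trajectory"))
  model <- traj$model
  check_image_ambiguity(traj$box[1, ], config)
  counts <- .cpp_traj_chain_counts(
    as.numeric(traj$coords), model$natoms, traj$n_frames,
    model$atoms$res_index, model$res_chain, traj$box,
    config$cutoff, config$minimum_image, method_code(config))
  dimnames(counts) <- list(model$chain_ids, model$chain_ids, NULL)
  counts
}

#' Per-frame contact records over a trajectory
#'
#' Like \code{\link{trajectory_chain_counts}} but also retains the residue-
#' pair lists each frame, as required by the residue-level contact maps.
#'
#' @inheritParams trajectory_chain_counts
#' @return an object of class \code{contact_ensemble}: a list with
#'   \code{records} (per-frame \code{contact_record}s), \code{chain_counts}
#'   (as in \code{trajectory_chain_counts}), \code{times}, \code{model},
#'   \code{config}
#' @export
contact_ensemble <- function(traj, config = contact_config()) {
  stopifnot(inherits(traj, "trajectory"))
  model <- traj$model
  check_image_ambiguity(traj$box[1, ], config)
  nc <- length(model$chain_ids)
  counts <- array(0L, c(nc, nc, traj$n_frames),
                  dimnames = list(model$chain_ids, model$chain_ids, NULL))
  records <- vector("list", traj$n_frames)
  mcode <- method_code(config)
  for (f in seq_len(traj$n_frames)) {
    res <- .cpp_frame_contacts(traj$coords[, , f, drop = TRUE],
                               model$atoms$res_index, model$res_chain,
                               traj$box[f, ], config$cutoff,
                               config$minimum_image, mcode)
    counts[, , f] <- res$chain_counts
    records[[f]] <- list(pairs = res$pairs, atom_counts = res$atom_counts)
  }
  structure(list(records = records, chain_counts = counts,
                 times = traj$times, model = model, config = config),
            class = "contact_ensemble")
}

inhibitor_counts_from_array <- function(counts, model) {
  # per-frame count of residue contacts between each peptide chain and the
  # whole inhibitor entity (possibly several chains)
  pep <- chains_by_role(model, "peptide")
  inh <- chains_by_role(model, "inhibitor")
  if (length(inh) == 0)
    stop("model has no inhibitor chains", call. = FALSE)
  out <- apply(counts[inh, pep, , drop = FALSE], c(2, 3), sum)
  if (is.null(dim(out))) out <- matrix(out, nrow = length(pep))
  rownames(out) <- pep
  out   # n_peptides x n_frames
}

interpeptide_counts_from_array <- function(counts, model) {
  # per-frame count of residue contacts between each peptide and all others
  pep <- chains_by_role(model, "peptide")
  sub <- counts[pep, pep, , drop = FALSE]
  nf <- dim(sub)[3]
  out <- matrix(0L, length(pep), nf, dimnames = list(pep, NULL))
  for (f in seq_len(nf)) {
    m <- sub[, , f]
    diag(m) <- 0L
    out[, f] <- rowSums(m)
  }
  out
}

#' Distribution of contact counts among interacting pairs
#'
#' Pools, over all frames, the contact counts of "bound" pairs -- pairs with
#' more than \code{min_contacts} residue contacts -- and returns a normalized
#' histogram over the integer counts. Pairings: \code{"peptide-peptide"}
#' (all peptide chain pairs), \code{"inhibitor-monomer"} (the inhibitor
#' entity versus peptides that are monomeric in that frame), and
#' \code{"inhibitor-oligomer"} (the inhibitor versus each oligomer of size
#' >= 2, summing member contacts). The last two require the per-frame
#' aggregation states.
#'
#' @param ensemble a \code{contact_ensemble} or a chain-counts array from
#'   \code{\link{trajectory_chain_counts}} (with a \code{model} supplied)
#' @param pairing which pair population to histogram
#' @param model required when \code{ensemble} is a bare counts array
#' @param states list of \code{aggregation_state}s (one per frame); required
#'   for the inhibitor pairings
#' @param min_contacts strict lower bound for a pair to enter (default 5:
#'   pairs with more than five contacts qualify)
#' @return a data.frame with columns \code{count} and \code{probability}
#'   (summing to 1), or \code{NULL} when no pair qualifies
#' @export
contact_count_distribution <- function(ensemble,
                                       pairing = c("peptide-peptide",
                                                   "inhibitor-monomer",
                                                   "inhibitor-oligomer"),
                                       model = NULL, states = NULL,
                                       min_contacts = 5L) {
  pairing <- match.arg(pairing)
  if (inherits(ensemble, "contact_ensemble")) {
    counts <- ensemble$chain_counts
    model <- ensemble$model
  } else {
    counts <- ensemble
    if (is.null(model)) stop("supply a model with a bare counts array")
  }
  nf <- dim(counts)[3]
  pep <- chains_by_role(model, "peptide")
  vals <- integer(0)
  if (pairing == "peptide-peptide") {
    idx <- match(pep, model$chain_ids)
    ut <- which(upper.tri(diag(length(pep))))
    for (f in seq_len(nf)) {
      m <- counts[idx, idx, f]
      vals <- c(vals, m[ut][m[ut] > min_contacts])
    }
  } else {
    if (is.null(states))
      stop("inhibitor pairings need per-frame aggregation states")
    if (length(states) != nf) stop("one aggregation state per frame required")
    inh_cnt <- inhibitor_counts_from_array(counts, model)
    for (f in seq_len(nf)) {
      olis <- states[[f]]$oligomers
      sizes <- lengths(olis)
      keep <- if (pairing == "inhibitor-monomer") sizes == 1 else sizes >= 2
      for (o in olis[keep]) {
        v <- sum(inh_cnt[o, f])
        if (v > min_contacts) vals <- c(vals, v)
      }
    }
  }
  if (length(vals) == 0) return(NULL)
  tb <- table(vals)
  data.frame(count = as.integer(names(tb)),
             probability = as.numeric(tb) / sum(tb))
}
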