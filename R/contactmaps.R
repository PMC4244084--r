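# Ensemble-averaged residue-level contact probability maps.
#
# All maps are conditioned populations: Fig-4-style inhibitor/peptide maps
# average over "complexed peptide-frames" (peptide with more than `threshold`
# inhibitor contacts in that frame); tertiary maps condition a peptide-frame
# on being complexed or free; quaternary maps consider dimeric combinations
# of interacting peptides (> threshold mutual contacts) in which, for the
# complexed population, at least one member is inhibitor-bound.

as_contact_ensemble <- function(x, config = contact_config()) {
  if (inherits(x, "contact_ensemble")) return(x)
  if (inherits(x, "trajectory")) return(contact_ensemble(x, config))
  stop("x must be a trajectory or contact_ensemble")
}

peptide_layout <- function(model) {
  pep <- chains_by_role(model, "peptide")
  lens <- vapply(pep, function(cid) length(model$chains[[cid]]$resno),
                 integer(1))
  if (length(unique(lens)) != 1)
    stop("pooled peptide maps require identical peptide chain lengths")
  first <- model$chains[[pep[1]]]
  list(chains = pep, length = lens[1], resno = first$resno,
       resname = first$resname)
}

new_cpmap <- function(P, n_obs, row_labels, col_labels, row_resname,
                      col_resname, conditioning, row_any = NULL,
                      col_any = NULL, mask = NULL) {
  structure(list(P = P, n_obs = n_obs, row_labels = row_labels,
                 col_labels = col_labels, row_resname = row_resname,
                 col_resname = col_resname, row_any = row_any,
                 col_any = col_any, mask = mask,
                 conditioning = conditioning),
            class = "contact_probability_map")
}

#' @export
print.contact_probability_map <- function(x, ...) {
  cat(sprintf("ContactProbabilityMap: %d x %d, %d observations [%s]\n",
              nrow(x$P), ncol(x$P), x$n_obs, x$conditioning))
  invisible(x)
}

pairs_between <- function(rec, res_chain, set_a, set_b) {
  # rows of rec$pairs with one residue in chain set a, the other in set b
  ca <- res_chain[rec$pairs[, 1]]
  cb <- res_chain[rec$pairs[, 2]]
  fwd <- ca %in% set_a & cb %in% set_b
  rev <- ca %in% set_b & cb %in% set_a
  rbind(rec$pairs[fwd, , drop = FALSE],
        rec$pairs[rev, 2:1, drop = FALSE])   # column 1 in set_a
}

#' Inhibitor-peptide residue contact probability map
#'
#' Cell (i, j): fraction of complexed peptide-frame observations (peptide
#' with more than \code{threshold} residue contacts with the inhibitor) in
#' which inhibitor residue i contacts peptide residue j. Observations are
#' pooled over peptides and frames.
#'
#' @param x a \code{trajectory} or \code{contact_ensemble}
#' @param config contact configuration (for trajectories)
#' @param threshold strict complexation threshold (default 5)
#' @return a \code{contact_probability_map} (rows: inhibitor residues,
#'   columns: peptide residues) that also carries the per-observation
#'   any-contact marginals used by \code{\link{per_residue_profile}} and
#'   \code{\link{per_type_profile}}; \code{NULL} when no complexed
#'   observation exists
#' @export
inhibitor_peptide_map <- function(x, config = contact_config(),
                                  threshold = 5L) {
  ens <- as_contact_ensemble(x, config)
  model <- ens$model
  lay <- peptide_layout(model)
  inh <- chains_by_role(model, "inhibitor")
  if (length(inh) == 0) stop("model has no inhibitor chains")
  inh_res <- which(model$residues$chain %in% inh)
  nI <- length(inh_res)
  L <- lay$length
  inh_cnt <- inhibitor_counts_from_array(ens$chain_counts, model)
  inh_set <- match(inh, model$chain_ids)
  res_chain <- model$res_chain
  res_local <- stats::ave(seq_len(model$nres), res_chain,
                          FUN = seq_along)   # position within chain
  inh_row <- match(seq_len(model$nres), inh_res)   # global -> row index
  acc <- matrix(0, nI, L)
  row_any <- numeric(nI)
  col_any <- numeric(L)
  n_obs <- 0L
  nf <- length(ens$records)
  for (f in seq_len(nf)) {
    rec <- ens$records[[f]]
    for (pi in seq_along(lay$chains)) {
      if (inh_cnt[pi, f] <= threshold) next
      pset <- match(lay$chains[pi], model$chain_ids)
      pr <- pairs_between(rec, res_chain, inh_set, pset)
      if (nrow(pr) == 0) next   # cannot happen when count > threshold
      ri <- inh_row[pr[, 1]]
      cj <- res_local[pr[, 2]]
      acc[cbind(ri, cj)] <- acc[cbind(ri, cj)] + 1
      row_any[unique(ri)] <- row_any[unique(ri)] + 1
      col_any[unique(cj)] <- col_any[unique(cj)] + 1
      n_obs <- n_obs + 1L
    }
  }
  if (n_obs == 0) return(NULL)
  new_cpmap(acc / n_obs, n_obs,
            row_labels = paste0(model$residues$chain[inh_res], ":",
                                model$residues$resno[inh_res]),
            col_labels = lay$resno,
            row_resname = model$residues$resname[inh_res],
            col_resname = lay$resname,
            conditioning = sprintf(
              "complexed peptide-frames (> %d inhibitor contacts)",
              threshold),
            row_any = row_any / n_obs, col_any = col_any / n_obs)
}

#' Per-residue any-contact probability profile
#'
#' Probability that each peptide residue contacts any inhibitor residue,
#' over the same conditioned observations as the map. Computed from the
#' per-observation contact sets accumulated by
#' \code{\link{inhibitor_peptide_map}}, not by combining map cells.
#'
#' @param map a \code{contact_probability_map} from
#'   \code{\link{inhibitor_peptide_map}}
#' @return data.frame with \code{resno}, \code{resname},
#'   \code{probability}
#' @export
per_residue_profile <- function(map) {
  stopifnot(inherits(map, "contact_probability_map"))
  if (is.null(map$col_any))
    stop("map does not carry any-contact marginals")
  data.frame(resno = map$col_labels, resname = map$col_resname,
             probability = map$col_any)
}

#' Contact probability per amino-acid type
#'
#' For each of the 20 standard residue types on the chosen side, the mean
#' over residues of that type of the residue's any-contact probability.
#' Types absent from the sequence are flagged absent (probability NA), not
#' reported as zero.
#'
#' @param map a \code{contact_probability_map} from
#'   \code{\link{inhibitor_peptide_map}}
#' @param side \code{"inhibitor"} (rows) or \code{"peptide"} (columns)
#' @return data.frame with \code{type} (1-letter), \code{probability},
#'   \code{n_residues}, \code{present}
#' @export
per_type_profile <- function(map, side = c("inhibitor", "peptide")) {
  stopifnot(inherits(map, "contact_probability_map"))
  side <- match.arg(side)
  if (side == "inhibitor") {
    p <- map$row_any; rn <- map$row_resname
  } else {
    p <- map$col_any; rn <- map$col_resname
  }
  type <- aa_three_to_one(rn)
  out <- data.frame(type = AA1, probability = NA_real_, n_residues = 0L,
                    present = FALSE)
  for (i in seq_along(AA1)) {
    sel <- type == AA1[i]
    if (any(sel)) {
      out$probability[i] <- mean(p[sel])
      out$n_residues[i] <- sum(sel)
      out$present[i] <- TRUE
    }
  }
  out
}

qualifying_peptide_frames <- function(ens, population, threshold) {
  # matrix n_peptides x n_frames of logicals
  model <- ens$model
  pep <- chains_by_role(model, "peptide")
  has_inh <- length(chains_by_role(model, "inhibitor")) > 0
  if (population == "complexed") {
    if (!has_inh)
      stop("complexed population requires an inhibitor in the model")
    inhibitor_counts_from_array(ens$chain_counts, model) > threshold
  } else {
    if (!has_inh)
      matrix(TRUE, length(pep), dim(ens$chain_counts)[3],
             dimnames = list(pep, NULL))
    else inhibitor_counts_from_array(ens$chain_counts, model) <= threshold
  }
}

#' Intra-peptide tertiary contact map
#'
#' Cell (i, j): fraction of qualifying peptide-frames in which residues i
#' and j of the same peptide chain are in contact, restricted to
#' non-sequential pairs (sequence separation >= 3; the i+1 and i+2 bands
#' are masked NA). Populations: \code{"complexed"} peptide-frames (> 5
#' inhibitor contacts) or \code{"free"} (unbound peptide-frames, or every
#' peptide-frame of an inhibitor-free control system).
#'
#' @inheritParams inhibitor_peptide_map
#' @param population \code{"complexed"} or \code{"free"}
#' @param min_sep minimum sequence separation shown (default 3)
#' @return a symmetric \code{contact_probability_map} over peptide residues,
#'   or \code{NULL} when the population is empty
#' @export
tertiary_map <- function(x, config = contact_config(),
                         population = c("complexed", "free"),
                         threshold = 5L, min_sep = 3L) {
  population <- match.arg(population)
  ens <- as_contact_ensemble(x, config)
  model <- ens$model
  lay <- peptide_layout(model)
  L <- lay$length
  qual <- qualifying_peptide_frames(ens, population, threshold)
  res_chain <- model$res_chain
  res_local <- stats::ave(seq_len(model$nres), res_chain, FUN = seq_along)
  acc <- matrix(0, L, L)
  n_obs <- 0L
  for (f in seq_along(ens$records)) {
    rec <- ens$records[[f]]
    pc <- res_chain[rec$pairs[, 1]]
    same <- pc == res_chain[rec$pairs[, 2]]
    for (pi in seq_along(lay$chains)) {
      if (!qual[pi, f]) next
      pidx <- match(lay$chains[pi], model$chain_ids)
      sel <- same & pc == pidx
      n_obs <- n_obs + 1L
      if (!any(sel)) next
      i <- res_local[rec$pairs[sel, 1]]
      j <- res_local[rec$pairs[sel, 2]]
      keep <- abs(i - j) >= min_sep
      if (!any(keep)) next
      acc[cbind(i[keep], j[keep])] <- acc[cbind(i[keep], j[keep])] + 1
      acc[cbind(j[keep], i[keep])] <- acc[cbind(j[keep], i[keep])] + 1
    }
  }
  if (n_obs == 0) return(NULL)
  P <- acc / n_obs
  mask <- abs(outer(seq_len(L), seq_len(L), "-")) < min_sep
  P[mask] <- NA_real_
  new_cpmap(P, n_obs, row_labels = lay$resno, col_labels = lay$resno,
            row_resname = lay$resname, col_resname = lay$resname,
            conditioning = sprintf("%s peptide-frames, |i-j| >= %d",
                                   population, min_sep),
            mask = mask)
}

#' Inter-peptide quaternary contact map
#'
#' Considers dimeric combinations of peptides sharing more than
#' \code{threshold} mutual residue contacts in a frame. For the
#' \code{"complexed"} population a pair qualifies when at least one member
#' is inhibitor-bound (> threshold inhibitor contacts); for \code{"free"},
#' when neither is. Cell (i, j): fraction of qualifying ordered pair-frame
#' observations with a cross-chain contact between residue i of one chain
#' and residue j of the other (each unordered pair contributes both orders,
#' so the map is symmetric).
#'
#' @inheritParams tertiary_map
#' @return a symmetric \code{contact_probability_map} over peptide residues,
#'   or \code{NULL} when no pair qualifies
#' @export
quaternary_map <- function(x, config = contact_config(),
                           population = c("complexed", "free"),
                           threshold = 5L) {
  population <- match.arg(population)
  ens <- as_contact_ensemble(x, config)
  model <- ens$model
  lay <- peptide_layout(model)
  L <- lay$length
  pep_idx <- match(lay$chains, model$chain_ids)
  has_inh <- length(chains_by_role(model, "inhibitor")) > 0
  if (population == "complexed" && !has_inh)
    stop("complexed population requires an inhibitor in the model")
  bound <- if (has_inh)
    inhibitor_counts_from_array(ens$chain_counts, model) > threshold
  else matrix(FALSE, length(lay$chains), dim(ens$chain_counts)[3])
  res_chain <- model$res_chain
  res_local <- stats::ave(seq_len(model$nres), res_chain, FUN = seq_along)
  acc <- matrix(0, L, L)
  n_obs <- 0L
  np <- length(lay$chains)
  for (f in seq_along(ens$records)) {
    rec <- ens$records[[f]]
    cc <- ens$chain_counts[pep_idx, pep_idx, f]
    for (a in seq_len(np - 1)) for (b in (a + 1):np) {
      if (cc[a, b] <= threshold) next
      ok <- if (population == "complexed") bound[a, f] || bound[b, f]
            else !bound[a, f] && !bound[b, f]
      if (!ok) next
      pr <- pairs_between(rec, res_chain, pep_idx[a], pep_idx[b])
      i <- res_local[pr[, 1]]
      j <- res_local[pr[, 2]]
      acc[cbind(i, j)] <- acc[cbind(i, j)] + 1
      acc[cbind(j, i)] <- acc[cbind(j, i)] + 1
      n_obs <- n_obs + 2L     # both ordered observations
    }
  }
  if (n_obs == 0) return(NULL)
  new_cpmap(acc / n_obs, n_obs,
            row_labels = lay$resno, col_labels = lay$resno,
            row_resname = lay$resname, col_resname = lay$resname,
            conditioning = sprintf(
              "%s interacting peptide pairs (> %d mutual contacts)",
              population, threshold))
}
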