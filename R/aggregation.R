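# Oligomer detection and species classification.
#
# Peptides sharing more than `threshold` (default 5, strict) residue contacts
# are joined by an edge; oligomers are the connected components of that
# graph. A peptide is inhibitor-complexed when it forms more than `threshold`
# contacts with the inhibitor entity; an oligomer is complexed when at least
# one member is. Species classes follow the monomer / small (n = 2-5) /
# large (n > 5) size convention.

SPECIES_CLASSES <- c("free_monomer", "free_small", "free_large",
                     "complexed_monomer", "complexed_small",
                     "complexed_large", "uncomplexed_inhibitor")

#' Peptide interaction graph of one frame
#'
#' @param record a \code{contact_record}, or a chain x chain counts matrix
#' @param model required when \code{record} is a bare matrix
#' @param threshold strict contact-count threshold: an edge requires more
#'   than \code{threshold} residue contacts (default 5, so >= 6)
#' @return 2-column character matrix of peptide chain-id edges
#' @export
peptide_graph <- function(record, model = NULL, threshold = 5L) {
  if (inherits(record, "contact_record")) {
    model <- record$model
    counts <- record$chain_counts
  } else counts <- record
  stopifnot(inherits(model, "system_model"))
  pep <- chains_by_role(model, "peptide")
  m <- counts[pep, pep, drop = FALSE]
  hit <- which(m > threshold & upper.tri(m), arr.ind = TRUE)
  cbind(pep[hit[, 1]], pep[hit[, 2]])
}

#' Partition peptide chains into oligomers
#'
#' Connected components of the peptide interaction graph; isolated peptides
#' are singleton monomers.
#'
#' @param edges 2-column matrix of chain-id edges (from
#'   \code{\link{peptide_graph}})
#' @param peptide_chains character vector of all peptide chain ids
#' @return list of character vectors, one per oligomer, covering every
#'   peptide chain exactly once
#' @export
oligomers <- function(edges, peptide_chains) {
  if (nrow(edges) > 0 &&
      !all(unique(as.vector(edges)) %in% peptide_chains))
    stop("edge references unknown peptide chain")
  g <- igraph::make_empty_graph(n = length(peptide_chains),
                                directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = peptide_chains)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(matrix(match(edges, peptide_chains),
                                       ncol = 2)))
  comp <- igraph::components(g)
  unname(split(peptide_chains, comp$membership))
}

#' Per-peptide inhibitor-complexation flags of one frame
#'
#' @inheritParams peptide_graph
#' @return named logical vector over peptide chains: \code{TRUE} when the
#'   peptide forms more than \code{threshold} residue contacts with the
#'   inhibitor entity
#' @export
complexation_flags <- function(record, model = NULL, threshold = 5L) {
  if (inherits(record, "contact_record")) {
    model <- record$model
    counts <- record$chain_counts
  } else counts <- record
  stopifnot(inherits(model, "system_model"))
  pep <- chains_by_role(model, "peptide")
  inh <- chains_by_role(model, "inhibitor")
  if (length(inh) == 0)
    stop("model has no inhibitor chains; complexation is undefined")
  cnt <- colSums(counts[inh, pep, drop = FALSE])
  setNames(cnt > threshold, pep)
}

#' Full aggregation state of one frame
#'
#' @inheritParams peptide_graph
#' @param time frame time stamp (ns), recorded in the state
#' @return an \code{aggregation_state}: list with \code{time},
#'   \code{oligomers} (partition of peptide chains), \code{bound} (per-
#'   peptide flags; all \code{FALSE} for inhibitor-free control systems),
#'   and \code{complexed} (per-oligomer flag: any member bound)
#' @export
aggregation_state <- function(record, model = NULL, threshold = 5L,
                              time = NA_real_) {
  if (inherits(record, "contact_record")) {
    if (is.na(time)) time <- record$time
    model <- record$model
    counts <- record$chain_counts
  } else counts <- record
  stopifnot(inherits(model, "system_model"))
  pep <- chains_by_role(model, "peptide")
  parts <- oligomers(peptide_graph(counts, model, threshold), pep)
  has_inh <- length(chains_by_role(model, "inhibitor")) > 0
  bound <- if (has_inh) complexation_flags(counts, model, threshold)
           else setNames(rep(FALSE, length(pep)), pep)
  complexed <- vapply(parts, function(o) any(bound[o]), logical(1))
  structure(list(time = time, oligomers = parts, bound = bound,
                 complexed = complexed), class = "aggregation_state")
}

classify_state <- function(state) {
  sizes <- lengths(state$oligomers)
  cls <- ifelse(sizes == 1, "monomer", ifelse(sizes <= 5, "small", "large"))
  cls <- paste0(ifelse(state$complexed, "complexed_", "free_"), cls)
  out <- setNames(numeric(length(SPECIES_CLASSES)), SPECIES_CLASSES)
  tb <- table(cls)
  out[names(tb)] <- as.numeric(tb)
  out["uncomplexed_inhibitor"] <- as.numeric(!any(state$bound))
  out
}

#' Per-frame aggregation states of a trajectory
#'
#' @param x a \code{trajectory}, \code{contact_ensemble}, or chain-counts
#'   array
#' @param config contact configuration (used when \code{x} is a trajectory)
#' @param model required when \code{x} is a bare counts array
#' @param threshold strict contact-count threshold
#' @return list of \code{aggregation_state}, one per frame
#' @export
aggregation_states <- function(x, config = contact_config(), model = NULL,
                               threshold = 5L) {
  if (inherits(x, "trajectory")) {
    counts <- trajectory_chain_counts(x, config)
    model <- x$model
    times <- x$times
  } else if (inherits(x, "contact_ensemble")) {
    counts <- x$chain_counts
    model <- x$model
    times <- x$times
  } else {
    counts <- x
    if (is.null(model)) stop("supply a model with a bare counts array")
    times <- rep(NA_real_, dim(counts)[3])
  }
  lapply(seq_len(dim(counts)[3]), function(f)
    aggregation_state(counts[, , f], model, threshold, time = times[f]))
}

#' Time-binned species counts
#'
#' Classifies every frame's oligomers into the seven species classes
#' (free/complexed x monomer/small/large, plus the uncomplexed-inhibitor
#' indicator) and averages the per-frame counts within consecutive time bins.
#'
#' @inheritParams aggregation_states
#' @param bin_ns bin width in ns (default 50)
#' @param times frame times; required for bare counts arrays
#' @return a \code{species_timeseries} data.frame with columns
#'   \code{bin_start}, \code{bin_end}, \code{n_frames} and one column per
#'   species class; the last bin may be partial (see attribute
#'   \code{partial_last_bin}). For control systems without an inhibitor the
#'   \code{uncomplexed_inhibitor} column is \code{NA}.
#' @export
species_counts <- function(x, config = contact_config(), threshold = 5L,
                           bin_ns = 50, model = NULL, times = NULL) {
  if (bin_ns <= 0) stop("bin width must be positive")
  states <- aggregation_states(x, config, model, threshold)
  if (is.null(times))
    times <- vapply(states, `[[`, numeric(1), "time")
  if (anyNA(times)) stop("frame times required for binning")
  per_frame <- t(vapply(states, classify_state,
                        numeric(length(SPECIES_CLASSES))))
  has_inh <- if (inherits(x, "trajectory"))
    length(chains_by_role(x$model, "inhibitor")) > 0
  else if (inherits(x, "contact_ensemble"))
    length(chains_by_role(x$model, "inhibitor")) > 0
  else length(chains_by_role(model, "inhibitor")) > 0
  t0 <- times[1]
  bin <- floor((times - t0) / bin_ns)
  ub <- sort(unique(bin))
  rows <- lapply(ub, function(b) {
    sel <- bin == b
    cbind(data.frame(bin_start = t0 + b * bin_ns,
                     bin_end = t0 + (b + 1) * bin_ns,
                     n_frames = sum(sel)),
          as.data.frame(t(colMeans(per_frame[sel, , drop = FALSE]))))
  })
  out <- do.call(rbind, rows)
  if (!has_inh) out$uncomplexed_inhibitor <- NA_real_
  last_span <- max(times) - out$bin_start[nrow(out)]
  structure(out, class = c("species_timeseries", "data.frame"),
            bin_ns = bin_ns, partial_last_bin = last_span < bin_ns)
}

#' Average species time series across runs
#'
#' @param series_list list of \code{species_timeseries} with identical bins
#' @return a \code{species_timeseries}: the unweighted per-bin mean
#' @export
multirun_average <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  ref <- series_list[[1]]
  for (s in series_list[-1]) {
    if (nrow(s) != nrow(ref) ||
        any(s$bin_start != ref$bin_start) || any(s$bin_end != ref$bin_end))
      stop("species time series have mismatched bins")
  }
  out <- ref
  for (cl in SPECIES_CLASSES) {
    vals <- vapply(series_list, function(s) s[[cl]],
                   numeric(nrow(ref)))
    out[[cl]] <- rowMeans(matrix(vals, nrow = nrow(ref)))
  }
  out$n_frames <- rowMeans(vapply(series_list, function(s)
    as.numeric(s$n_frames), numeric(nrow(ref))))
  out
}
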