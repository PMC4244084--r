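# Two-dimensional potential-of-mean-force surfaces over contact counts.
#
# For every peptide in every frame we record the pair
# (x = residue contacts with the inhibitor entity,
#  y = residue contacts with all other peptides),
# histogram the pooled samples, and Boltzmann-invert:
#   W(x, y) = -kB T ln[ P(x, y) / Pmax ],
# so the most populated bin sits at W = 0 and empty bins are masked.

#' Landscape (PMF) configuration
#'
#' @param temperature simulation temperature in K (default 325)
#' @param kB Boltzmann constant in kcal/mol/K
#' @param bin_width histogram bin width in contacts (default 1)
#' @param contour contour interval for plotting, kcal/mol (default 0.5)
#' @return an object of class \code{landscape_config}
#' @export
landscape_config <- function(temperature = 325, kB = 0.0019872041,
                             bin_width = 1, contour = 0.5) {
  stopifnot(temperature > 0, bin_width > 0)
  structure(list(temperature = temperature, kB = kB,
                 kBT = kB * temperature, bin_width = bin_width,
                 contour = contour), class = "landscape_config")
}

#' Per-peptide contact-count observables
#'
#' @param x a \code{trajectory} or \code{contact_ensemble}
#' @param config a \code{contact_config} (used for trajectories)
#' @return data.frame with one row per peptide per frame: \code{frame},
#'   \code{time}, \code{peptide}, \code{x} (contacts with the inhibitor),
#'   \code{y} (contacts with all other peptides)
#' @export
observable_series <- function(x, config = contact_config()) {
  if (inherits(x, "trajectory")) {
    counts <- trajectory_chain_counts(x, config)
    model <- x$model
    times <- x$times
  } else if (inherits(x, "contact_ensemble")) {
    counts <- x$chain_counts
    model <- x$model
    times <- x$times
  } else stop("x must be a trajectory or contact_ensemble")
  xi <- inhibitor_counts_from_array(counts, model)     # errors w/o inhibitor
  yi <- interpeptide_counts_from_array(counts, model)
  pep <- rownames(xi)
  nf <- ncol(xi)
  data.frame(frame = rep(seq_len(nf), each = length(pep)),
             time = rep(times, each = length(pep)),
             peptide = rep(pep, nf),
             x = as.integer(xi), y = as.integer(yi))
}

#' Two-dimensional PMF from contact-count samples
#'
#' @param samples data.frame with integer columns \code{x} and \code{y}
#'   (e.g. from \code{\link{observable_series}})
#' @param config a \code{landscape_config}
#' @return an object of class \code{pmf_grid}: \code{x_centers},
#'   \code{y_centers}, \code{P} (probabilities, summing to 1 over unmasked
#'   bins), \code{W} (kcal/mol, minimum 0, \code{Inf} on empty bins),
#'   \code{mask} (TRUE = empty), plus the temperature and kBT used
#' @export
pmf2d <- function(samples, config = landscape_config()) {
  if (is.null(samples) || nrow(samples) == 0) return(NULL)
  bw <- config$bin_width
  bx <- floor(samples$x / bw)
  by <- floor(samples$y / bw)
  xr <- range(bx); yr <- range(by)
  nx <- xr[2] - xr[1] + 1L
  ny <- yr[2] - yr[1] + 1L
  H <- matrix(0, nx, ny)
  tb <- table(factor(bx, levels = xr[1]:xr[2]),
              factor(by, levels = yr[1]:yr[2]))
  H[] <- as.numeric(tb)
  P <- H / sum(H)
  mask <- P == 0
  W <- matrix(Inf, nx, ny)
  W[!mask] <- -config$kBT * log(P[!mask] / max(P))
  structure(list(x_centers = (xr[1]:xr[2]) * bw + (bw - 1) / 2,
                 y_centers = (yr[1]:yr[2]) * bw + (bw - 1) / 2,
                 P = P, W = W, mask = mask,
                 temperature = config$temperature, kBT = config$kBT,
                 n_samples = nrow(samples)),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("PMFGrid: %d x %d bins, %d samples, T = %g K (kBT = %.4f)\n",
              length(x$x_centers), length(x$y_centers), x$n_samples,
              x$temperature, x$kBT))
  invisible(x)
}

#' Fraction of samples in a landscape region
#'
#' @param samples data.frame with columns \code{x} and \code{y}
#' @param predicate function of (x, y) returning a logical vector
#' @return fraction of samples satisfying the predicate, in [0, 1]
#' @export
region_population <- function(samples, predicate) {
  if (is.null(samples) || nrow(samples) == 0) return(NA_real_)
  mean(predicate(samples$x, samples$y))
}
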