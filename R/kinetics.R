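# Binding kinetics: bound/unbound series and survival-time correlation.
#
# A peptide is "bound" in a frame when it forms more than `threshold`
# residue contacts with the inhibitor. The survival correlation S(t) is the
# average, over time origins, of the number of peptides that are bound at
# the origin and remain continuously bound for a further lag t; unbound
# excursions strictly shorter than the escape tolerance t0 (default 1 ns)
# are bridged beforehand. S(0) is therefore the average number of
# simultaneously complexed peptides, and S is non-increasing in the lag.

#' Kinetics configuration
#'
#' @param threshold strict contact threshold defining "bound" (> threshold)
#' @param t0 escape tolerance in ns: unbound gaps strictly shorter than t0
#'   that are flanked by bound frames are bridged (default 1)
#' @param origin_stride time-origin stride in frames (default 1: every frame)
#' @param max_lag maximum lag in ns (default: half the trajectory length)
#' @return an object of class \code{kinetics_config}
#' @export
kinetics_config <- function(threshold = 5L, t0 = 1.0, origin_stride = 1L,
                            max_lag = NULL) {
  stopifnot(t0 >= 0, origin_stride >= 1)
  structure(list(threshold = threshold, t0 = t0,
                 origin_stride = as.integer(origin_stride),
                 max_lag = max_lag), class = "kinetics_config")
}

#' Per-peptide bound/unbound indicator series
#'
#' @param x a \code{trajectory}, \code{contact_ensemble}, or a peptide x
#'   frame matrix of inhibitor contact counts
#' @param config a \code{contact_config} (for trajectories)
#' @param kcfg a \code{kinetics_config}
#' @param model required for bare count matrices
#' @param times frame times (for bare count matrices)
#' @return an object of class \code{bound_series}: list with \code{times},
#'   \code{dt}, and \code{b}, an n_frames x n_peptides 0/1 matrix
#' @export
bound_series <- function(x, config = contact_config(),
                         kcfg = kinetics_config(), model = NULL,
                         times = NULL) {
  if (inherits(x, "trajectory")) {
    counts <- trajectory_chain_counts(x, config)
    inh <- inhibitor_counts_from_array(counts, x$model)
    times <- x$times
  } else if (inherits(x, "contact_ensemble")) {
    inh <- inhibitor_counts_from_array(x$chain_counts, x$model)
    times <- x$times
  } else {
    inh <- x
    if (is.null(times)) stop("times required with a bare count matrix")
  }
  b <- t(inh > kcfg$threshold) * 1L          # frames x peptides
  dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  structure(list(times = times, dt = dt, b = b,
                 peptides = colnames(b)), class = "bound_series")
}

bridge_one <- function(b, max_gap_frames) {
  # set to 1 every maximal run of 0s shorter than max_gap_frames+1 frames
  # that is flanked by 1s; leading/trailing zero runs untouched
  r <- rle(b)
  n <- length(r$lengths)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (r$values[i] == 0 && r$lengths[i] <= max_gap_frames &&
          r$values[i - 1] == 1 && r$values[i + 1] == 1)
        r$values[i] <- 1L
    }
  }
  inverse.rle(r)
}

#' Bridge short unbound excursions
#'
#' Gaps (runs of 0) with duration strictly less than \code{t0} that are
#' flanked by bound frames on both sides are set to bound. A gap of g frames
#' in a series with spacing dt has duration g*dt; it is bridged iff
#' g*dt < t0.
#'
#' @param bs a \code{bound_series} (or a plain 0/1 vector with \code{dt}
#'   given)
#' @param t0 escape tolerance in ns
#' @param dt frame spacing in ns (taken from the series when omitted)
#' @return same type as the input, with short gaps filled
#' @export
bridge_excursions <- function(bs, t0 = 1.0, dt = NULL) {
  if (t0 <= 0) return(bs)
  if (inherits(bs, "bound_series")) {
    if (is.null(dt)) dt <- bs$dt
    if (is.na(dt)) stop("series has no frame spacing")
    gmax <- ceiling(t0 / dt) - 1L          # gaps of g*dt < t0
    if (t0 / dt == round(t0 / dt)) gmax <- as.integer(t0 / dt) - 1L
    bs$b <- apply(bs$b, 2, bridge_one, max_gap_frames = gmax)
    return(bs)
  }
  if (is.null(dt)) stop("dt required for a plain vector")
  gmax <- ceiling(t0 / dt) - 1L
  if (t0 / dt == round(t0 / dt)) gmax <- as.integer(t0 / dt) - 1L
  bridge_one(bs, gmax)
}

#' Survival-time correlation function
#'
#' S(lag) = average over time origins t of the number of peptides that are
#' bound at t and remain continuously bound over [t, t + lag]. Origins are
#' restricted so t + lag stays inside the trajectory. Short unbound
#' excursions are bridged first (see \code{\link{bridge_excursions}}); set
#' \code{bridge = FALSE} if the series is already bridged or the strict
#' continuous-occupancy function is wanted.
#'
#' @param bs a \code{bound_series}
#' @param kcfg a \code{kinetics_config}
#' @param bridge apply \code{bridge_excursions} with \code{kcfg$t0} first?
#' @return an object of class \code{survival_curve}: data.frame with
#'   \code{lag_ns}, \code{S} (average number of still-bound peptides),
#'   \code{S_norm} (= S/S(0)), \code{n_origins}; attributes \code{N}
#'   (number of peptides) and \code{S0}
#' @export
survival_correlation <- function(bs, kcfg = kinetics_config(),
                                 bridge = TRUE) {
  stopifnot(inherits(bs, "bound_series"))
  if (bridge) bs <- bridge_excursions(bs, kcfg$t0)
  b <- bs$b
  nf <- nrow(b)
  np <- ncol(b)
  dt <- bs$dt
  max_lag_fr <- if (is.null(kcfg$max_lag)) (nf - 1L) %/% 2L
                else as.integer(round(kcfg$max_lag / dt))
  if (max_lag_fr >= nf)
    stop("max lag exceeds the trajectory length")
  lags <- 0:max_lag_fr
  if (kcfg$origin_stride == 1L) {
    # run-length counting: a bound run of R frames contributes max(0, R - L)
    # origins at lag L frames
    runs <- integer(0)
    for (j in seq_len(np)) {
      r <- rle(b[, j])
      runs <- c(runs, r$lengths[r$values == 1])
    }
    numer <- numeric(length(lags))
    if (length(runs) > 0) {
      cnt <- tabulate(runs, nbins = nf)
      # numer[L+1] = sum over runs of max(0, R - L)
      tail_n <- rev(cumsum(rev(cnt)))                 # number of runs >= r
      tail_s <- rev(cumsum(rev(cnt * seq_len(nf))))   # sum of lengths >= r
      for (i in seq_along(lags)) {
        L <- lags[i]
        if (L + 1 <= nf) numer[i] <- tail_s[L + 1] - L * tail_n[L + 1]
      }
    }
    n_origins <- nf - lags
    S <- numer / n_origins
  } else {
    origins_all <- seq(1L, nf, by = kcfg$origin_stride)
    S <- numeric(length(lags))
    n_origins <- integer(length(lags))
    run_fwd <- apply(b, 2, function(v) {
      r <- numeric(length(v))
      acc <- 0
      for (t in length(v):1) {
        acc <- if (v[t] == 1) acc + 1 else 0
        r[t] <- acc
      }
      r
    })
    for (i in seq_along(lags)) {
      L <- lags[i]
      orig <- origins_all[origins_all + L <= nf]
      n_origins[i] <- length(orig)
      S[i] <- mean(rowSums(run_fwd[orig, , drop = FALSE] > L))
    }
  }
  S0 <- S[1]
  out <- data.frame(lag_ns = lags * dt, S = S,
                    S_norm = if (S0 > 0) S / S0 else rep(NA_real_,
                                                         length(S)),
                    n_origins = n_origins)
  structure(out, class = c("survival_curve", "data.frame"),
            N = np, S0 = S0, dt = dt)
}

#' Average survival curves across runs
#'
#' @param curves list of \code{survival_curve} objects on identical lag
#'   grids
#' @return a \code{survival_curve}: the unweighted mean of S per lag
#' @export
average_survival_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  ref <- curves[[1]]
  for (cv in curves[-1])
    if (nrow(cv) != nrow(ref) || any(cv$lag_ns != ref$lag_ns))
      stop("survival curves have mismatched lag grids")
  S <- rowMeans(vapply(curves, function(cv) cv$S, numeric(nrow(ref))))
  S0 <- S[1]
  out <- data.frame(lag_ns = ref$lag_ns, S = S,
                    S_norm = if (S0 > 0) S / S0 else rep(NA_real_,
                                                         length(S)),
                    n_origins = rowSums(vapply(curves, function(cv)
                      as.numeric(cv$n_origins), numeric(nrow(ref)))))
  structure(out, class = c("survival_curve", "data.frame"),
            N = attr(ref, "N"), S0 = S0, dt = attr(ref, "dt"))
}

#' Mean residence time from a survival curve
#'
#' \code{exp_fit}: least-squares fit of ln(S/S0) versus lag over the lags
#' where S > 0.05 S0, returning -1/slope. \code{integral}: trapezoidal
#' integral of S/S0 up to the maximum lag; when S has not decayed below
#' 0.05 S0 by then, the value is flagged as a lower bound.
#'
#' @param curve a \code{survival_curve}
#' @param method \code{"exp_fit"} or \code{"integral"}
#' @return residence time in ns; attribute \code{lower_bound} is TRUE when
#'   the integral estimate is censored by the maximum lag. Returns NULL when
#'   S(0) = 0.
#' @export
mean_residence_time <- function(curve, method = c("exp_fit", "integral")) {
  method <- match.arg(method)
  S0 <- attr(curve, "S0")
  if (is.null(S0) || S0 <= 0) return(NULL)
  s <- curve$S / S0
  lag <- curve$lag_ns
  decayed <- any(s <= 0.05)
  if (method == "exp_fit") {
    sel <- s > 0.05
    if (sum(sel) < 2) stop("too few lags above 0.05 S0 for a fit")
    fit <- stats::lm(log(s[sel]) ~ lag[sel])
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0)
      stop("survival curve does not decay; no exponential fit possible")
    tau <- -1 / slope
    return(structure(tau, lower_bound = FALSE))
  }
  # trapezoidal integral of S/S0
  tau <- sum(diff(lag) * (head(s, -1) + tail(s, -1)) / 2)
  structure(tau, lower_bound = !decayed)
}
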