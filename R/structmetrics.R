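# Rigid-body superposition (Kabsch), RMSD time series and per-residue RMSF.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping
#' \code{mobile} onto \code{reference}, via the SVD of the weighted
#' covariance matrix with a determinant correction that excludes
#' reflections.
#'
#' @param reference,mobile numeric n x 3 coordinate matrices (n >= 3)
#' @param weights optional non-negative per-point weights
#' @return an object of class \code{superposition}: list with
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length 3), and
#'   \code{rmsd} (Angstrom) after alignment. Aligned coordinates are
#'   \code{mobile \%*\% rotation + translation} (rows).
#' @export
kabsch <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)))
    stop("reference and mobile must have the same dimensions")
  n <- nrow(reference)
  if (n < 3) stop("at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cr <- colSums(reference * w)
  cm <- colSums(mobile * w)
  A <- sweep(reference, 2, cr)
  B <- sweep(mobile, 2, cm)
  H <- t(B * w) %*% A
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    warning("near-degenerate (collinear) configuration; ",
            "rotation is ill-conditioned", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  aligned <- B %*% R
  rmsd <- sqrt(sum(w * rowSums((aligned - A)^2)))
  structure(list(rotation = R, translation = cr - as.numeric(cm %*% R),
                 rmsd = rmsd), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp a \code{superposition}
#' @param xyz n x 3 coordinate matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
}

#' RMSD time series against a reference frame
#'
#' Per-frame Kabsch-aligned RMSD over an atom selection (C-alpha atoms of
#' the inhibitor chains, typically).
#'
#' @param traj a \code{trajectory}
#' @param reference a \code{traj_frame}, an n x 3 matrix over the selection,
#'   or a frame index into \code{traj}
#' @param selection integer atom indices (see \code{\link{select_atoms}})
#' @return data.frame with \code{time} and \code{rmsd} (Angstrom)
#' @export
rmsd_series <- function(traj, reference = 1L, selection) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(selection) == 0) stop("empty atom selection")
  ref_xyz <- if (inherits(reference, "traj_frame"))
    reference$xyz[selection, , drop = FALSE]
  else if (is.matrix(reference)) reference
  else traj$coords[selection, , reference, drop = TRUE]
  if (nrow(ref_xyz) != length(selection))
    stop("reference does not cover the selection")
  vals <- vapply(seq_len(traj$n_frames), function(f)
    kabsch(ref_xyz, traj$coords[selection, , f, drop = TRUE])$rmsd,
    numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}

#' Per-residue RMSF about the aligned mean structure
#'
#' Aligns every frame to the running average structure (two
#' align-average-realign iterations), then computes, for each residue in the
#' selection, the root-mean-square fluctuation of its selected atoms about
#' their time-averaged positions.
#'
#' @param traj a \code{trajectory} (>= 2 frames)
#' @param selection integer atom indices
#' @param reference \code{"mean"} (default: iteratively aligned average
#'   structure) or \code{"first"} (align to the first frame)
#' @param iterations alignment iterations for the mean reference
#' @return data.frame with \code{res_index}, \code{chain}, \code{resno},
#'   \code{resname}, \code{rmsf} (Angstrom)
#' @export
rmsf_per_residue <- function(traj, selection, reference = c("mean", "first"),
                             iterations = 2L) {
  stopifnot(inherits(traj, "trajectory"))
  reference <- match.arg(reference)
  if (length(selection) == 0) stop("empty atom selection")
  if (traj$n_frames < 2) stop("RMSF needs at least 2 frames")
  nf <- traj$n_frames
  sub <- traj$coords[selection, , , drop = FALSE]
  ref <- sub[, , 1, drop = TRUE]
  iters <- if (reference == "first") 1L else as.integer(iterations)
  aligned <- array(0, dim(sub))
  for (it in seq_len(iters)) {
    for (f in seq_len(nf)) {
      sp <- kabsch(ref, sub[, , f, drop = TRUE])
      aligned[, , f] <- apply_superposition(sp, sub[, , f, drop = TRUE])
    }
    if (reference == "mean") ref <- apply(aligned, c(1, 2), mean)
  }
  mean_xyz <- apply(aligned, c(1, 2), mean)
  dev2 <- apply((aligned - as.vector(mean_xyz))^2, c(1, 3), sum)
  msf_atom <- rowMeans(dev2)
  res_idx <- traj$model$atoms$res_index[selection]
  msf_res <- tapply(msf_atom, res_idx, mean)
  out_idx <- as.integer(names(msf_res))
  data.frame(res_index = out_idx,
             chain = traj$model$residues$chain[out_idx],
             resno = traj$model$residues$resno[out_idx],
             resname = traj$model$residues$resname[out_idx],
             rmsf = sqrt(as.numeric(msf_res)))
}
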