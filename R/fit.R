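#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets, via singular value
#' decomposition of the weighted covariance matrix with the usual
#' determinant correction that excludes reflections.
#'
#' The returned transform maps the mobile set onto the reference:
#' `y = x %*% t(rotation) + translation` (see [apply_superposition()]).
#'
#' @param mobile,reference `n x 3` matrices of paired points, `n >= 3`,
#'   not collinear
#' @param weights optional non-negative per-point weights
#' @return object of class `SuperpositionResult`: `rotation` (3x3,
#'   `det = +1`), `translation` (length 3), `rmsd` (the minimised value, A)
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stopf("point sets differ in size (%d vs %d)", n, nrow(reference))
  if (n < 3L) stopf("need at least 3 points for a superposition")
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stopf("weights must be non-negative")
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(reference, 2L, cr)
  # degenerate geometry: all points on a line leave the rotation about that
  # axis undetermined
  if (min(svd(sqrt(w) * X)$d) < 1e-8 && sum(svd(sqrt(w) * X)$d > 1e-8) < 2L)
    stopf("degenerate (collinear) point set")
  H <- crossprod(X * w, Y)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.vector(R %*% cm)
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  obj <- list(rotation = R, translation = t_vec, rmsd = rmsd)
  class(obj) <- "SuperpositionResult"
  obj
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param x `n x 3` coordinate matrix
#' @param fit a `SuperpositionResult`
#' @export
apply_superposition <- function(x, fit) {
  sweep(as.matrix(x) %*% t(fit$rotation), 2L, fit$translation, "+")
}

plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series over a trajectory
#'
#' Per frame, superposes the frame onto the reference on `fit_sel` (Kabsch,
#' unweighted) and computes the RMSD of `calc_sel` after the fit — the
#' standard "fit on core backbone, measure a part" protocol.
#'
#' @param traj a `Trajectory`
#' @param reference a `StructureModel` (e.g. the equilibrated structure)
#' @param fit_sel selection used for the least-squares fit
#' @param calc_sel selection the deviation is computed over (default: the
#'   fit selection)
#' @param label series label
#' @return object of class `RMSDSeries`: data.frame `time`, `rmsd` with the
#'   selections as attributes
#' @export
rmsd_series <- function(traj, reference, fit_sel, calc_sel = fit_sel,
                        label = NULL) {
  res <- rmsd_multi(traj, reference, fit_sel, list(calc = calc_sel))
  out <- data.frame(time = traj$times, rmsd = res$calc)
  class(out) <- c("RMSDSeries", "data.frame")
  attr(out, "label") <- label %||%
    (if (inherits(calc_sel, "Selection")) calc_sel$label else "selection")
  attr(out, "fit_selection") <- if (inherits(fit_sel, "Selection")) fit_sel$label else "indices"
  out
}

# one fit per frame, many measured selections: returns a data.frame of RMSD
# series, one column per calc selection
rmsd_multi <- function(traj, reference, fit_sel, calc_sels) {
  ref_xyz <- coords(reference)
  fit_idx <- resolve_selection(fit_sel, reference)
  if (!length(fit_idx)) stopf("empty fit selection")
  calc_idx <- lapply(calc_sels, function(s) {
    idx <- resolve_selection(s, reference)
    if (!length(idx)) stopf("empty calc selection")
    idx
  })
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow = nf, ncol = length(calc_idx),
                dimnames = list(NULL, names(calc_sels)))
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    fit <- kabsch_fit(fr[fit_idx, , drop = FALSE], ref_xyz[fit_idx, , drop = FALSE])
    moved <- apply_superposition(fr, fit)
    for (k in seq_along(calc_idx)) {
      idx <- calc_idx[[k]]
      out[f, k] <- plain_rmsd(moved[idx, , drop = FALSE], ref_xyz[idx, , drop = FALSE])
    }
  }
  as.data.frame(out)
}

#' Fluctuation profile: RMSF and B-factors over a frame window
#'
#' Frames in the window are superposed on `fit_sel` onto the window-mean
#' structure, the mean is recomputed and the fit iterated (twice by
#' default) to remove rigid-body drift; then per atom
#' `B = (8 pi^2 / 3) * <|r - <r>|^2>`.
#'
#' @param traj a `Trajectory`
#' @param sel selection of atoms to profile
#' @param frame_window integer frame indices (default: all frames);
#'   at least 2 frames
#' @param fit_sel selection used for the iterated mean-structure fit
#'   (default: `sel`); `NULL` to treat the frames as pre-aligned (no
#'   superposition — appropriate when the trajectory carries no rigid-body
#'   motion, as for stationary synthetic ensembles; with alignment, a small
#'   downward bias of order `2/N` atoms is inherent to absorbing the six
#'   rigid degrees of freedom)
#' @param n_iter mean-structure fit iterations
#' @return object of class `FluctuationProfile`: data.frame `chain`,
#'   `resid`, `name`, mean position `mx my mz`, `rmsf` (A), `b` (A^2)
#' @export
bfactors <- function(traj, sel = select_all(), frame_window = NULL,
                     fit_sel = sel, n_iter = 2L) {
  window <- frame_window %||% seq_len(n_frames(traj))
  if (length(window) < 2L) stopf("fluctuations need a window of at least 2 frames")
  idx <- resolve_selection(sel, traj$topology)
  if (!length(idx)) stopf("empty selection")
  frames <- traj$frames[window]
  aligned <- frames
  if (!is.null(fit_sel)) {
    fit_idx <- resolve_selection(fit_sel, traj$topology)
    if (!length(fit_idx)) stopf("empty fit selection")
    for (it in seq_len(n_iter)) {
      mean_xyz <- Reduce(`+`, aligned) / length(aligned)
      aligned <- lapply(frames, function(fr) {
        fit <- kabsch_fit(fr[fit_idx, , drop = FALSE],
                          mean_xyz[fit_idx, , drop = FALSE])
        apply_superposition(fr, fit)
      })
    }
  }
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  msf <- Reduce(`+`, lapply(aligned, function(fr)
    rowSums((fr[idx, , drop = FALSE] - mean_xyz[idx, , drop = FALSE])^2))) /
    length(aligned)
  a <- traj$topology$atoms[idx, , drop = FALSE]
  out <- data.frame(chain = a$chain, resid = a$resid, name = a$name,
                    mx = mean_xyz[idx, 1L], my = mean_xyz[idx, 2L],
                    mz = mean_xyz[idx, 3L],
                    rmsf = sqrt(msf), b = (8 * pi^2 / 3) * msf,
                    stringsAsFactors = FALSE)
  class(out) <- c("FluctuationProfile", "data.frame")
  out
}

#' Order parameter R_T: truncated vs intact RMSD ratio
#'
#' `R_T` for a selection (histone monomer, structural domain or DNA
#' segment) is the ratio of the tail-truncated simulation's RMSD to the
#' intact simulation's RMSD, each averaged over the entire trajectory.
#' `R_T > 1` is read as destabilization of the selection; the reference
#' structures underlying the two series must have been aligned (zero mutual
#' RMSD) for the ratio to be meaningful, which is the caller's contract.
#'
#' A delta-method standard error (treating frames as independent) is
#' attached so callers can ask whether `R_T` exceeds 1 by more than noise.
#'
#' @param trunc,intact `RMSDSeries` for the same selection semantics from
#'   the truncated and intact trajectories
#' @param label result label
#' @return object of class `OrderParameter`: `label`, `RT`, `mean_trunc`,
#'   `mean_intact`, `se`, `destabilized` (`RT > 1`)
#' @export
order_parameter_RT <- function(trunc, intact, label = NULL) {
  vt <- trunc$rmsd; vi <- intact$rmsd
  if (!length(vt) || !length(vi)) stopf("empty RMSD series")
  mt <- mean(vt); mi <- mean(vi)
  if (mi == 0) stopf("intact mean RMSD is zero; R_T undefined")
  rt <- mt / mi
  var_mt <- stats::var(vt) / length(vt)
  var_mi <- stats::var(vi) / length(vi)
  se <- sqrt(var_mt / mi^2 + mt^2 * var_mi / mi^4)
  obj <- list(label = label %||% attr(trunc, "label") %||% "selection",
              RT = rt, mean_trunc = mt, mean_intact = mi, se = se,
              destabilized = rt > 1)
  class(obj) <- "OrderParameter"
  obj
}

#' @export
print.OrderParameter <- function(x, ...) {
  cat(sprintf("R_T[%s] = %.3f (trunc %.3f / intact %.3f A, se %.3g)%s\n",
              x$label, x$RT, x$mean_trunc, x$mean_intact, x$se,
              if (x$destabilized) "  [R_T > 1]" else ""))
  invisible(x)
}
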