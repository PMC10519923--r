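#' Global structural similarity index
#'
#' Whole-image SSIM computed from global moments (no sliding window):
#' `SSIM = (2 mu_g mu_d + c1)(2 cov_gd + c2) /
#'         ((mu_g^2 + mu_d^2 + c1)(var_g + var_d + c2))`
#' with `c1 = c2 = 0.01^2`. Both images are normalized by the ground-truth
#' peak before the moments are taken, so the constants act on a unit-range
#' scale. Population (1/n) moments are used.
#'
#' @param ground ground-truth image or volume (any dimension).
#' @param denoised test image of identical shape.
#' @param c1,c2 stabilizing constants (default `0.01^2`).
#' @return scalar SSIM.
#' @export
ssim_global <- function(ground, denoised, c1 = 1e-4, c2 = 1e-4) {
  if (!identical(dim(ground) %||% length(ground),
                 dim(denoised) %||% length(denoised)))
    stop_input("ground and denoised images must share the same shape")
  peak <- max(ground)
  if (peak <= 0) stop_input("ground truth must have a positive peak")
  g <- as.vector(ground) / peak
  d <- as.vector(denoised) / peak
  n <- length(g)
  mg <- mean(g); md <- mean(d)
  vg <- mean(g^2) - mg^2
  vd <- mean(d^2) - md^2
  cgd <- mean(g * d) - mg * md
  (2 * mg * md + c1) * (2 * cgd + c2) / ((mg^2 + md^2 + c1) * (vg + vd + c2))
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(peak / RMSE)` in dB, where `peak` is the maximum of the
#' ground truth and RMSE is taken over all voxels. Identical images give
#' `Inf`.
#'
#' @param ground ground-truth image or volume.
#' @param denoised test image of identical shape.
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(ground, denoised) {
  if (!identical(dim(ground) %||% length(ground),
                 dim(denoised) %||% length(denoised)))
    stop_input("ground and denoised images must share the same shape")
  if (max(ground) == min(ground)) stop_input("ground truth is constant")
  rmse <- sqrt(mean((as.vector(ground) - as.vector(denoised))^2))
  if (rmse == 0) return(Inf)
  20 * log10(max(ground) / rmse)
}

#' Extract a time-activity curve from a reconstructed volume
#'
#' Per-frame mean over a cubic volume of interest of edge `voi_size`
#' (default 4, i.e. a 4 x 4 x 4-voxel VOI). For even sizes the cube spans
#' indices `center - size/2 + 1` through `center + size/2` along each axis.
#'
#' @param volume a `recon_volume` or bare 4-D array `[row, col, slice, frame]`.
#' @param voi_center integer `(row, col, slice)` center.
#' @param voi_size cube edge in voxels.
#' @return numeric vector of per-frame VOI means.
#' @export
extract_tac <- function(volume, voi_center, voi_size = 4) {
  arr <- if (inherits(volume, "recon_volume")) volume$data else volume
  d <- dim(arr)
  lo <- voi_center - voi_size %/% 2 + 1 - (voi_size %% 2)
  hi <- lo + voi_size - 1
  if (any(lo < 1) || any(hi > d[1:3]))
    stop_input("VOI [%s]..[%s] outside volume %s",
               paste(lo, collapse = ","), paste(hi, collapse = ","),
               paste(d[1:3], collapse = "x"))
  vapply(seq_len(d[4]), function(f)
    mean(arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], f]), numeric(1))
}

#' Root-mean-square error between two time-activity curves
#'
#' @param gt ground-truth TAC.
#' @param est estimated TAC of the same length.
#' @return scalar RMSE.
#' @export
tac_rmse <- function(gt, est) {
  if (length(gt) != length(est)) stop_input("TAC length mismatch")
  sqrt(mean((gt - est)^2))
}

#' Per-frame image-quality metrics of a reconstruction
#'
#' Computes the global SSIM and PSNR of every frame volume of `test` against
#' the matching frame of `truth` (conventionally the reconstruction of the
#' noiseless sinogram, so that the reconstruction algorithm's own bias
#' cancels out of the comparison).
#'
#' @param truth,test `recon_volume` objects (or bare 4-D arrays) of the same
#'   shape.
#' @param method label stored in the output.
#' @return data.frame with columns `method`, `frame`, `ssim`, `psnr_db`.
#' @export
evaluate_recon <- function(truth, test, method = "test") {
  gt <- if (inherits(truth, "recon_volume")) truth$data else truth
  te <- if (inherits(test, "recon_volume")) test$data else test
  if (!identical(dim(gt), dim(te))) stop_input("volume shapes differ")
  nf <- dim(gt)[4]
  data.frame(
    method = method, frame = seq_len(nf),
    ssim = vapply(seq_len(nf), function(f)
      ssim_global(gt[, , , f], te[, , , f]), numeric(1)),
    psnr_db = vapply(seq_len(nf), function(f)
      psnr(gt[, , , f], te[, , , f]), numeric(1)))
}

#' Metric table for several methods
#'
#' Stacks [evaluate_recon()] results for a named list of reconstructions into
#' one long table (methods x frames), the layout quantitative denoising
#' comparisons are reported in.
#'
#' @param truth reference `recon_volume`.
#' @param tests named list of `recon_volume` objects.
#' @return data.frame with columns `method`, `frame`, `ssim`, `psnr_db`.
#' @export
metric_table <- function(truth, tests) {
  do.call(rbind, lapply(names(tests), function(nm)
    evaluate_recon(truth, tests[[nm]], method = nm)))
}

#' Time-activity-curve report over tissue VOIs
#'
#' Extracts per-tissue TACs from a reference and a test reconstruction at the
#' given VOI centers and reports per-tissue RMSE.
#'
#' @param truth,test `recon_volume` objects of the same shape.
#' @param centers named list of `(row, col, slice)` VOI centers.
#' @param voi_size cube edge in voxels (default 4).
#' @return list with `tacs` (data.frame tissue, frame, gt, est) and `rmse`
#'   (named numeric vector).
#' @export
tac_report <- function(truth, test, centers, voi_size = 4) {
  rows <- list(); rmse <- numeric(0)
  for (nm in names(centers)) {
    g <- extract_tac(truth, centers[[nm]], voi_size)
    e <- extract_tac(test, centers[[nm]], voi_size)
    rows[[nm]] <- data.frame(tissue = nm, frame = seq_along(g), gt = g, est = e)
    rmse[nm] <- tac_rmse(g, e)
  }
  list(tacs = do.call(rbind, rows), rmse = rmse)
}
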