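## Geometry cache: sparse system matrices and derived per-subset operators,
## keyed by (image size, angles, bins [, subsets]).
.geom_cache <- new.env(parent = emptyenv())

#' Parallel-beam system matrix
#'
#' Builds the discrete Radon operator `H` for an `n x n` image and
#' `n_angles` projection angles uniformly spaced over `[0, 180)` degrees with
#' `n_bins` radial bins (1-pixel spacing, centered). Each ray is sampled at
#' unit steps and distributed to its four neighboring pixels by bilinear
#' weights, so `H %*% vec(image)` is the sinogram (angle-major layout:
#' `matrix(H %*% v, n_angles, n_bins)`) and `t(H)` is the exactly matched
#' back-projector. The matrix is cached per geometry.
#'
#' @param n image edge length.
#' @param n_angles number of angles (default `n`).
#' @param n_bins number of radial bins (default `n`).
#' @return list with `H` (sparse `Matrix::dgCMatrix`), `fov` (logical
#'   in-field-of-view pixel mask, `n x n`), and the geometry sizes.
#' @export
radon_system_matrix <- function(n, n_angles = n, n_bins = n) {
  key <- sprintf("H_%d_%d_%d", n, n_angles, n_bins)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  c0 <- (n + 1) / 2
  theta <- (seq_len(n_angles) - 1) * pi / n_angles
  rbin <- seq_len(n_bins) - (n_bins + 1) / 2
  L <- ceiling(n / 2)
  l <- seq(-L, L, by = 1)
  ## sample points for all (angle, bin, step) combinations
  nA <- n_angles; nB <- n_bins; nL <- length(l)
  ct <- rep(cos(theta), times = nB * nL)
  st <- rep(sin(theta), times = nB * nL)
  rr <- rep(rep(rbin, each = nA), times = nL)
  ll <- rep(l, each = nA * nB)
  px <- c0 + rr * ct - ll * st        # row coordinate
  py <- c0 + rr * st + ll * ct        # column coordinate
  row_id <- rep(seq_len(nA * nB), times = nL)
  ok <- px >= 1 & px <= n & py >= 1 & py <= n
  px <- px[ok]; py <- py[ok]; row_id <- row_id[ok]
  i0 <- pmin(floor(px), n - 1); fx <- px - i0
  j0 <- pmin(floor(py), n - 1); fy <- py - j0
  cols <- c(i0 + (j0 - 1) * n,       i0 + 1 + (j0 - 1) * n,
            i0 + j0 * n,             i0 + 1 + j0 * n)
  w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  H <- Matrix::sparseMatrix(i = rep(row_id, 4), j = cols, x = w,
                            dims = c(nA * nB, n * n))
  ax <- seq_len(n) - c0
  fov <- outer(ax, ax, function(a, b) sqrt(a^2 + b^2)) <= n / 2
  geom <- list(H = H, fov = fov, n = n, n_angles = n_angles, n_bins = n_bins)
  .geom_cache[[key]] <- geom
  geom
}

#' Forward-project an activity volume
#'
#' Parallel-beam Radon transform of every square slice of a 3-D volume.
#'
#' @param volume_frame 3-D array `[row, col, slice]` with square slices.
#' @param n_angles number of projection angles (default: slice edge length).
#' @param n_bins number of radial bins (default: slice edge length).
#' @return sinogram array `[angle, bin, slice]`.
#' @export
forward_project <- function(volume_frame, n_angles = NULL, n_bins = NULL) {
  d <- dim(volume_frame)
  if (length(d) != 3L) stop_input("forward_project expects a 3-D volume")
  if (d[1] != d[2]) stop_input("slices must be square, got %d x %d", d[1], d[2])
  n_angles <- n_angles %||% d[1]
  n_bins <- n_bins %||% d[1]
  geom <- radon_system_matrix(d[1], n_angles, n_bins)
  out <- array(0, c(n_angles, n_bins, d[3]))
  for (s in seq_len(d[3]))
    out[, , s] <- matrix(geom$H %*% as.vector(volume_frame[, , s]),
                         n_angles, n_bins)
  out
}

#' Add count-budgeted Poisson noise to a clean sinogram
#'
#' Globally rescales the clean 4-D sinogram so that its total over all
#' frames, slices and bins equals `total_counts`, then draws independent
#' Poisson counts per bin. The scaling is global, so early high-activity
#' frames receive proportionally more counts, as in a real acquisition.
#'
#' @param clean_sino nonnegative 4-D array `[angle, bin, slice, frame]`.
#' @param total_counts expected total photon count (> 0).
#' @param seed integer seed (RNG state is restored afterwards).
#' @param frame_durations per-frame durations in minutes.
#' @return a [dynamic_sinogram()] carrying both the counts and the scaled
#'   clean expectation.
#' @export
add_poisson_noise <- function(clean_sino, total_counts, seed,
                              frame_durations = rep(1, dim(clean_sino)[4])) {
  if (any(clean_sino < 0)) stop_input("clean sinogram must be nonnegative")
  if (total_counts <= 0) stop_input("total_counts must be positive")
  s <- sum(clean_sino)
  if (s == 0) stop_input("all-zero sinogram cannot carry a positive count budget")
  lam <- clean_sino * (total_counts / s)
  counts <- with_seed(seed, rpois(length(lam), as.vector(lam)))
  counts <- array(as.double(counts), dim(clean_sino))
  dynamic_sinogram(counts, frame_durations, clean = lam)
}

#' Simulate a dynamic PET sinogram
#'
#' Forward-projects every frame of a dynamic activity volume and applies
#' count-budgeted Poisson noise.
#'
#' @param activity 4-D activity array `[row, col, slice, frame]`, e.g. from
#'   [make_dynamic_phantom()].
#' @param scheme a [frame_scheme()].
#' @param total_counts total photon count budget across all frames and slices.
#' @param seed integer seed.
#' @param n_angles,n_bins sinogram geometry (default: image edge length).
#' @return a [dynamic_sinogram()].
#' @export
simulate_dynamic_sinogram <- function(activity, scheme, total_counts, seed,
                                      n_angles = NULL, n_bins = NULL) {
  d <- dim(activity)
  if (length(d) != 4L) stop_input("activity must be 4-D [row, col, slice, frame]")
  n_angles <- n_angles %||% d[1]
  n_bins <- n_bins %||% d[1]
  clean <- array(0, c(n_angles, n_bins, d[3], d[4]))
  for (f in seq_len(d[4])) {
    fr <- activity[, , , f, drop = FALSE]
    dim(fr) <- d[1:3]
    clean[, , , f] <- forward_project(fr, n_angles, n_bins)
  }
  add_poisson_noise(clean, total_counts, seed,
                    frame_durations = rep(scheme$frame_duration, scheme$n_frames))
}
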