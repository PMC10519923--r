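## per-subset forward/back operators, cached per (geometry, n_subsets)
osem_operators <- function(n, n_angles, n_bins, n_subsets) {
  key <- sprintf("OSEM_%d_%d_%d_%d", n, n_angles, n_bins, n_subsets)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  if (n_angles %% n_subsets != 0)
    stop_input("n_subsets (%d) must divide the number of angles (%d)",
               n_subsets, n_angles)
  geom <- radon_system_matrix(n, n_angles, n_bins)
  subsets <- vector("list", n_subsets)
  for (b in seq_len(n_subsets)) {
    angles_b <- seq(b, n_angles, by = n_subsets)  # angle-interleaved partition
    rows <- as.vector(outer(angles_b, (seq_len(n_bins) - 1L) * n_angles, "+"))
    Hb <- geom$H[rows, , drop = FALSE]
    subsets[[b]] <- list(rows = rows, H = Hb, Ht = Matrix::t(Hb),
                         sens = Matrix::colSums(Hb))
  }
  ops <- list(geom = geom, subsets = subsets)
  .geom_cache[[key]] <- ops
  ops
}

#' OSEM reconstruction of one sinogram slice
#'
#' Ordered-subset expectation maximization with the multiplicative update
#' `f_j <- f_j / sum_{i in S_b} H_ij * sum_{i in S_b} H_ij p_i / (H f)_i`,
#' cycling over angle-interleaved subsets (`n_subsets = 1` is plain MLEM).
#' The estimate is initialized to 1 inside the circular field of view and 0
#' outside; nonnegativity is preserved by construction and small epsilon
#' guards protect both denominators. Deterministic.
#'
#' @param sino_slice nonnegative matrix `[angle, bin]`.
#' @param n_iterations full iterations (default 20).
#' @param n_subsets number of subsets (default 8); must divide the angles.
#' @param image_size reconstructed matrix size (default `n_bins`).
#' @param init optional nonnegative starting image (matrix); the default is 1
#'   inside the field of view and 0 outside.
#' @return nonnegative `image_size x image_size` matrix.
#' @export
osem_reconstruct <- function(sino_slice, n_iterations = 20, n_subsets = 8,
                             image_size = ncol(sino_slice), init = NULL) {
  if (any(sino_slice < 0)) stop_input("sinogram entries must be nonnegative")
  n_angles <- nrow(sino_slice); n_bins <- ncol(sino_slice)
  ops <- osem_operators(image_size, n_angles, n_bins, n_subsets)
  eps <- 1e-12
  f <- if (is.null(init)) as.double(ops$geom$fov) else as.double(init)
  p <- as.vector(sino_slice)
  for (it in seq_len(n_iterations)) {
    for (sub in ops$subsets) {
      q <- as.vector(sub$H %*% f)
      ratio <- ifelse(q > eps, p[sub$rows] / q, 0)
      f <- f / pmax(sub$sens, eps) * as.vector(sub$Ht %*% ratio)
      f[sub$sens <= eps] <- 0
    }
  }
  matrix(f, image_size, image_size)
}

#' Reconstruct a dynamic sinogram frame by frame
#'
#' Applies [osem_reconstruct()] independently to every (frame, slice) of a
#' dynamic sinogram.
#'
#' @param sino a [dynamic_sinogram()], or a bare nonnegative 4-D array
#'   `[angle, bin, slice, frame]` (e.g. a denoised sinogram).
#' @param n_iterations,n_subsets OSEM settings (defaults 20 and 8).
#' @param image_size reconstructed matrix size (default: number of bins).
#' @param voxel_size_mm voxel edge length recorded in the result (default 1.5).
#' @return object of class `recon_volume`: list with `data`
#'   (`[row, col, slice, frame]`, nonnegative), `voxel_size_mm`,
#'   `iterations`, `subsets`.
#' @export
reconstruct_dynamic <- function(sino, n_iterations = 20, n_subsets = 8,
                                image_size = NULL, voxel_size_mm = 1.5) {
  arr <- if (inherits(sino, "dynamic_sinogram")) sino$counts else sino
  d <- dim(arr)
  if (length(d) != 4L) stop_input("expected a 4-D sinogram array")
  image_size <- image_size %||% d[2]
  data <- array(0, c(image_size, image_size, d[3], d[4]))
  for (f in seq_len(d[4]))
    for (s in seq_len(d[3]))
      data[, , s, f] <- osem_reconstruct(arr[, , s, f], n_iterations,
                                         n_subsets, image_size)
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 iterations = n_iterations, subsets = n_subsets),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("recon_volume: %d x %d x %d slices x %d frames (OSEM %d it x %d subsets)\n",
              d[1], d[2], d[3], d[4], x$iterations, x$subsets))
  invisible(x)
}

#' Poisson log-likelihood of a sinogram slice under an image estimate
#'
#' `sum_i (p_i log (H f)_i - (H f)_i)` over bins with positive forward
#' projection; used to verify the monotone-likelihood property of MLEM.
#'
#' @param sino_slice matrix `[angle, bin]` of counts.
#' @param image reconstructed image matrix.
#' @return scalar log-likelihood (up to the data-only constant).
#' @export
poisson_loglik <- function(sino_slice, image) {
  geom <- radon_system_matrix(nrow(image), nrow(sino_slice), ncol(sino_slice))
  q <- as.vector(geom$H %*% as.vector(image))
  p <- as.vector(sino_slice)
  ok <- q > 0
  sum(p[ok] * log(q[ok]) - q[ok]) - sum(q[!ok])
}

#' Filtered back-projection reconstruction (reference method)
#'
#' Single-pass ramp-filtered back-projection using the same system geometry,
#' provided as a classical baseline to compare iterative reconstructions
#' against. Projections are ramp-filtered in the frequency domain per angle
#' and back-projected with the adjoint operator, scaled by
#' `pi / (2 n_angles)`; negative values are clipped.
#'
#' @param sino_slice matrix `[angle, bin]`.
#' @param image_size output matrix size (default `n_bins`).
#' @return nonnegative image matrix.
#' @export
fbp_reconstruct <- function(sino_slice, image_size = ncol(sino_slice)) {
  n_angles <- nrow(sino_slice); n_bins <- ncol(sino_slice)
  pad <- 2^ceiling(log2(2 * n_bins))
  freq <- c(seq(0, pad / 2), seq(pad / 2 - 1, 1)) / pad
  filt <- 2 * freq[seq_len(pad)]
  filtered <- matrix(0, n_angles, n_bins)
  for (a in seq_len(n_angles)) {
    row <- c(sino_slice[a, ], rep(0, pad - n_bins))
    fr <- Re(fft(fft(row) * filt, inverse = TRUE)) / pad
    filtered[a, ] <- fr[seq_len(n_bins)]
  }
  geom <- radon_system_matrix(image_size, n_angles, n_bins)
  img <- as.vector(Matrix::t(geom$H) %*% as.vector(filtered)) * pi / (2 * n_angles)
  matrix(pmax(img, 0), image_size, image_size)
}
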