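## shared test fixtures and independent oracles, all built in code

## small stabilized sinogram filled with reproducible Gaussian noise
random_stab <- function(nr = 32, nc = 32, n_slices = 1, n_frames = 3,
                        seed = 1, mean = 5, sd = 1) {
  arr <- gbm4d:::with_seed(seed,
    array(mean + sd * rnorm(nr * nc * n_slices * n_frames),
          c(nr, nc, n_slices, n_frames)))
  stabilized_sinogram(arr, sigma = sd)
}

## independent orthonormal DCT-II matrix built from the analytic definition,
## deliberately not via dct_matrix()
oracle_dct_matrix <- function(n) {
  M <- matrix(0, n, n)
  for (k in 0:(n - 1)) for (i in 0:(n - 1)) {
    ck <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    M[k + 1, i + 1] <- ck * cos((2 * i + 1) * k * pi / (2 * n))
  }
  M
}

oracle_dct2 <- function(block) {
  M <- oracle_dct_matrix(nrow(block))
  M %*% block %*% t(M)
}

## brute-force guided matcher: exhaustive window scan with per-candidate
## prefiltered distances, naive sorting, raster (column-major) tie-break
oracle_match <- function(guide, x_ref, N, window, tau_abs, max_group,
                         prefilter_thr) {
  vr <- nrow(guide) - N + 1; vc <- ncol(guide) - N + 1
  half <- (window - 1) %/% 2
  M <- oracle_dct_matrix(N)
  pf <- function(i, j) {
    b <- M %*% guide[i:(i + N - 1), j:(j + N - 1)] %*% t(M)
    b[abs(b) <= prefilter_thr] <- 0
    b
  }
  ref <- pf(x_ref[1], x_ref[2])
  cand <- expand.grid(i = max(1, x_ref[1] - half):min(vr, x_ref[1] + half),
                      j = max(1, x_ref[2] - half):min(vc, x_ref[2] + half))
  d <- mapply(function(i, j) sum((pf(i, j) - ref)^2) / N^2, cand$i, cand$j)
  is_ref <- cand$i == x_ref[1] & cand$j == x_ref[2]
  keep <- which(!is_ref & d <= tau_abs)
  keep <- keep[order(d[keep])]
  sel <- c(which(is_ref), keep)[seq_len(min(max_group, length(keep) + 1))]
  cbind(cand$i[sel], cand$j[sel])
}

## small blob image, strictly positive inside the field of view
fov_blob <- function(n, width = 0.15) {
  ax <- seq(-1, 1, length.out = n)
  r2 <- outer(ax, ax, function(a, b) a^2 + b^2)
  img <- exp(-r2 / width)
  img[r2 > (1 - 1.5 / n)^2] <- 0
  img
}
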