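#' Build the accumulated guide image for one slice
#'
#' The guide image is the elementwise sum of the (stabilized) sinogram over
#' the frame axis for a single slice. Because independent per-frame noise
#' averages out relative to the accumulated signal, matching blocks on the
#' guide is far more reliable than matching on any individual low-count frame.
#'
#' @param stab a [stabilized_sinogram()].
#' @param slice_index slice to accumulate.
#' @param source provenance tag, `"noisy_accumulated"` for the Step-1 guide or
#'   `"basic_estimate_accumulated"` for the Step-2 guide.
#' @return matrix `[angle, bin]` with attribute `source`.
#' @export
build_guide <- function(stab, slice_index, source = "noisy_accumulated") {
  stopifnot(inherits(stab, "stabilized_sinogram"))
  d <- dim(stab$data)
  if (slice_index < 1 || slice_index > d[3])
    stop_input("slice_index %d out of range [1, %d]", slice_index, d[3])
  A <- stab$data[, , slice_index, , drop = FALSE]
  dim(A) <- d[c(1, 2, 4)]
  g <- rowSums(A, dims = 2)
  attr(g, "source") <- source
  g
}

## 2-D DCT coefficients of every fully-contained N x N block of `img`,
## as a (n_valid_row * n_valid_col) x N^2 matrix, positions in column-major
## raster order of the block's top-left corner.
block_coeff_matrix <- function(img, N) {
  nr <- nrow(img); nc <- ncol(img)
  vr <- nr - N + 1L; vc <- nc - N + 1L
  if (vr < 1L || vc < 1L) stop_input("block size %d exceeds image %d x %d", N, nr, nc)
  base <- as.vector(outer(seq_len(vr), (seq_len(vc) - 1L) * nr, "+"))
  offs <- as.vector(outer(0:(N - 1L), (0:(N - 1L)) * nr, "+"))
  B <- matrix(img[outer(base, offs, "+")], length(base), N * N)
  C <- dct_matrix(N)
  K <- kronecker(C, C)  # vec(C %*% X %*% t(C)) = (C %x% C) %*% vec(X)
  B %*% t(K)
}

## hard-threshold prefilter used on guide-image coefficients before distance
prefilter_coeffs <- function(coeffs, threshold) {
  if (threshold <= 0) return(coeffs)
  coeffs * (abs(coeffs) > threshold)
}

#' Prefiltered block distance on a guide image
#'
#' Distance between the `N x N` blocks whose top-left corners sit at `x_ref`
#' and `x` in the guide image: both blocks are taken to the orthonormal 2-D
#' DCT domain, coefficients with magnitude at or below
#' `prefilter_threshold * sigma_guide` are zeroed (coarse prefiltering, which
#' suppresses the noise contribution that would otherwise bias the distance),
#' and the squared l2 distance of the surviving spectra is normalized by
#' `N^2`. With the prefilter disabled the distance equals the plain
#' pixel-domain `||.||_2^2 / N^2` by Parseval's identity.
#'
#' @param guide numeric matrix (one guide image).
#' @param x_ref,x integer length-2 positions `(row, col)` of block top-left
#'   corners, 1-based.
#' @param block_size block edge length `N`.
#' @param prefilter_threshold hard-threshold multiplier applied to coefficient
#'   magnitudes in units of `sigma_guide`; 0 disables prefiltering.
#' @param sigma_guide noise standard deviation of the guide image.
#' @return nonnegative scalar distance.
#' @export
prefiltered_distance <- function(guide, x_ref, x, block_size = 8,
                                 prefilter_threshold = 2, sigma_guide = 1) {
  N <- block_size
  for (p in list(x_ref, x)) {
    if (p[1] < 1 || p[2] < 1 || p[1] + N - 1 > nrow(guide) || p[2] + N - 1 > ncol(guide))
      stop_input("block at (%d, %d) not fully inside the %d x %d guide",
                 p[1], p[2], nrow(guide), ncol(guide))
  }
  C <- dct_matrix(N)
  thr <- prefilter_threshold * sigma_guide
  b1 <- guide[x_ref[1]:(x_ref[1] + N - 1), x_ref[2]:(x_ref[2] + N - 1)]
  b2 <- guide[x[1]:(x[1] + N - 1), x[2]:(x[2] + N - 1)]
  c1 <- prefilter_coeffs(C %*% b1 %*% t(C), thr)
  c2 <- prefilter_coeffs(C %*% b2 %*% t(C), thr)
  sum((c1 - c2)^2) / N^2
}

#' Match-set container
#'
#' @param members integer matrix `|S| x 2` of block top-left positions
#'   `(row, col)`, reference first.
#' @param distances per-member prefiltered distances (reference's is 0).
#' @return object of class `match_set`.
#' @export
match_set <- function(members, distances) {
  members <- matrix(as.integer(members), ncol = 2)
  if (nrow(members) < 1L) stop_input("a match set must contain the reference")
  if (distances[1] != 0) stop_input("reference must be first with distance 0")
  structure(list(reference = members[1, ], members = members,
                 distances = as.numeric(distances)),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set: reference (%d, %d), %d members, max distance %.4g\n",
              x$reference[1], x$reference[2], nrow(x$members), max(x$distances)))
  invisible(x)
}

## Core matcher working on a precomputed (prefiltered) coefficient matrix.
## Cth: P x N^2, n2: rowSums(Cth^2), valid grid vr x vc in column-major order.
match_core <- function(Cth, n2, vr, vc, ref_i, ref_j, window, tau_abs,
                       max_group, N) {
  half <- (window - 1L) %/% 2L
  is <- max(1L, ref_i - half):min(vr, ref_i + half)
  js <- max(1L, ref_j - half):min(vc, ref_j + half)
  cand <- as.vector(outer(is, (js - 1L) * vr, "+"))
  ref_id <- ref_i + (ref_j - 1L) * vr
  dot <- as.vector(Cth[cand, , drop = FALSE] %*% Cth[ref_id, ])
  d <- pmax(0, n2[cand] + n2[ref_id] - 2 * dot) / N^2
  others <- which(cand != ref_id & d <= tau_abs)
  ord <- others[order(d[others], method = "radix")]  # stable: ties in raster order
  sel <- c(which(cand == ref_id)[1], ord)
  sel <- sel[seq_len(min(max_group, length(sel)))]
  ids <- cand[sel]
  match_set(cbind((ids - 1L) %% vr + 1L, (ids - 1L) %/% vr + 1L),
            c(0, d[sel[-1]]))
}

#' Guided block matching around a reference position
#'
#' Scans every candidate block position inside the search window whose block
#' lies fully in the guide image, computes the prefiltered distance to the
#' reference block, and keeps those at or below the matching threshold.
#' Members are ordered by ascending distance with the reference first
#' (distance ties broken by column-major raster order of candidate positions)
#' and truncated to `max_group`. Entirely deterministic.
#'
#' @param guide guide-image matrix.
#' @param x_ref reference block top-left `(row, col)`.
#' @param config matching configuration, see [denoise_config()]; the distance
#'   threshold applied is `tau * sigma_guide^2` with `tau` taken from
#'   `config$tau_match` (or `config$tau_match_wiener` when `wiener = TRUE`,
#'   in which case the coarse prefilter is also disabled, matching the plain
#'   distance used in the second denoising step).
#' @param sigma_guide guide-image noise standard deviation.
#' @param wiener logical; use the second-step (Wiener) matching rule.
#' @return a [match_set()].
#' @export
match_blocks <- function(guide, x_ref, config = denoise_config()$match,
                         sigma_guide = 1, wiener = FALSE) {
  N <- config$block_size
  vr <- nrow(guide) - N + 1L; vc <- ncol(guide) - N + 1L
  if (x_ref[1] < 1 || x_ref[1] > vr || x_ref[2] < 1 || x_ref[2] > vc)
    stop_input("reference position (%d, %d) invalid for block size %d",
               x_ref[1], x_ref[2], N)
  thr <- if (wiener) 0 else config$prefilter_threshold * sigma_guide
  tau <- if (wiener) config$tau_match_wiener else config$tau_match
  Cth <- prefilter_coeffs(block_coeff_matrix(guide, N), thr)
  match_core(Cth, rowSums(Cth^2), vr, vc, as.integer(x_ref[1]),
             as.integer(x_ref[2]), config$window, tau * sigma_guide^2,
             config$max_group, N)
}

## gather a 4-D group stack from a per-slice array A (nr x nc x T)
stack_blocks <- function(A, members, N) {
  nr <- dim(A)[1]; nc <- dim(A)[2]; Tn <- dim(A)[3]
  if (any(members[, 1] < 1 | members[, 2] < 1 |
          members[, 1] + N - 1 > nr | members[, 2] + N - 1 > nc))
    stop_input("match member block out of bounds for %d x %d slice", nr, nc)
  offs <- as.vector(outer(0:(N - 1L), (0:(N - 1L)) * nr, "+"))
  pix_t <- outer(offs, (0:(Tn - 1L)) * (nr * nc), "+")        # N^2 x T
  base <- members[, 1] + (members[, 2] - 1L) * nr              # |S|
  idx <- outer(as.vector(pix_t), base, "+")                    # (N^2 T) x |S|
  array(A[as.vector(idx)], dim = c(N, N, Tn, nrow(members)))
}

#' Stack matched blocks into a 4-D group
#'
#' For every member position of a match set, extracts the `N x N` block at
#' that position from every frame of the given slice and stacks the results
#' into an `N x N x |T| x |S|` array (`stack[i, j, t, m]` is the sinogram
#' value at frame `t`, member `m`, in-block offset `(i, j)`).
#'
#' @param stab a [stabilized_sinogram()].
#' @param match a [match_set()].
#' @param block_size block edge length `N`.
#' @param slice_index slice the match set refers to.
#' @return object of class `block_group` with fields `stack`, `match`,
#'   `slice_index`.
#' @export
stack_group <- function(stab, match, block_size = 8, slice_index = 1) {
  stopifnot(inherits(stab, "stabilized_sinogram"), inherits(match, "match_set"))
  d <- dim(stab$data)
  A <- stab$data[, , slice_index, , drop = FALSE]
  dim(A) <- d[c(1, 2, 4)]
  structure(list(stack = stack_blocks(A, match$members, block_size),
                 match = match, slice_index = slice_index),
            class = "block_group")
}

## reference-grid coordinates along one axis: regular step with the final
## position snapped to the border so every pixel is covered by some block
ref_positions <- function(n_valid, step) {
  p <- seq.int(1L, n_valid, by = step)
  if (p[length(p)] != n_valid) p <- c(p, n_valid)
  p
}
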