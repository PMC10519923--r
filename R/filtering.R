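#' Denoiser configuration
#'
#' Returns the default configuration of the two-step guided block-matching
#' 4-D collaborative filter, as a nested list that can be partially overridden
#' via `...` (e.g. `denoise_config(filter = list(lambda_4d = 3))`).
#'
#' Sections:
#' \describe{
#'   \item{vst}{`mode` (`"poisson"`), `sigma`: stabilized-domain noise
#'     standard deviation (1 is exact for ideal Poisson counts).}
#'   \item{match}{`block_size` (N = 8), `step` (reference grid stride, 3),
#'     `window` (search window edge, 39), `max_group` (largest group size,
#'     16), `tau_match` and `tau_match_wiener` (distance thresholds in units
#'     of `sigma_guide^2`; defaults 4.8 and 0.64), `prefilter_threshold`
#'     (coarse-prefilter multiplier in units of `sigma_guide`, 2.0; applied in
#'     Step 1 matching only).}
#'   \item{filter}{`lambda_4d`: hard-threshold multiplier (2.8),
#'     `kaiser_beta`: aggregation window shape (2.0), `wiener_passthrough`:
#'     force the Wiener gain to 1 (identity second step; diagnostics only).}
#' }
#'
#' The guide-image noise level is derived internally as
#' `sigma_guide = sigma * sqrt(n_frames)` (the guide is a sum of `n_frames`
#' independent unit-variance frames), which keeps the matching thresholds
#' calibrated as the frame count changes.
#'
#' @param ... named lists merged over the defaults section-wise.
#' @return nested configuration list.
#' @export
denoise_config <- function(...) {
  cfg <- list(
    vst = list(mode = "poisson", sigma = 1.0),
    match = list(block_size = 8L, step = 3L, window = 39L, max_group = 16L,
                 tau_match = 4.8, tau_match_wiener = 0.64,
                 prefilter_threshold = 2.0),
    filter = list(lambda_4d = 2.8, kaiser_beta = 2.0,
                  wiener_passthrough = FALSE, steps = 2L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop_input("unknown config section '%s'", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  cfg
}

#' Hard thresholding of transform coefficients
#'
#' Zeroes every coefficient whose magnitude is at or below
#' `lambda_4d * sigma` (the boundary itself is shrunk to zero) and counts the
#' nonzero coefficients that survive.
#'
#' @param coeffs numeric array of transform coefficients.
#' @param sigma noise standard deviation (> 0).
#' @param lambda_4d threshold multiplier.
#' @return list with `coeffs` (same shape) and `n_retained`.
#' @export
hard_threshold <- function(coeffs, sigma = 1, lambda_4d = 2.8) {
  if (sigma <= 0) stop_input("sigma must be positive")
  keep <- abs(coeffs) > lambda_4d * sigma
  out <- coeffs * keep
  list(coeffs = out, n_retained = sum(out != 0))
}

filtered_group <- function(stack, weight, match) {
  if (!is.finite(weight) || weight <= 0)
    stop_input("aggregation weight must be positive and finite")
  structure(list(stack = stack, weight = weight, match = match),
            class = "filtered_group")
}

#' Step-1 collaborative filtering of one group (hard thresholding)
#'
#' Transforms the 4-D stack with the separable orthonormal DCT, hard-thresholds
#' at `lambda_4d * sigma`, inverts the transform, and attaches the
#' sparsity-based aggregation weight `1 / (sigma^2 * max(n_retained, 1))`
#' (groups whose spectrum collapses to fewer coefficients are more reliable
#' and weigh more in aggregation).
#'
#' @param group a `block_group` from [stack_group()].
#' @param cfg configuration from [denoise_config()].
#' @return a `filtered_group` (fields `stack`, `weight`, `match`).
#' @export
ht_filter_group <- function(group, cfg = denoise_config()) {
  sigma <- cfg$vst$sigma
  ht <- hard_threshold(transform_4d(group$stack), sigma, cfg$filter$lambda_4d)
  filtered_group(inverse_transform_4d(ht$coeffs),
                 1 / (sigma^2 * max(ht$n_retained, 1)),
                 group$match)
}

#' Step-2 collaborative filtering of one group (empirical Wiener shrinkage)
#'
#' Uses the Step-1 (basic) estimate's spectrum as a pilot: the Wiener gain is
#' `W = |T(basic)|^2 / (|T(basic)|^2 + sigma^2)`, applied to the noisy stack's
#' coefficients. Every entry of `W` lies in `[0, 1)`. The aggregation weight is
#' `1 / (sigma^2 * ||W||_2^2)`.
#'
#' @param noisy_group `block_group` stacked from the noisy sinogram.
#' @param basic_group `block_group` stacked from the basic estimate at the
#'   same match set.
#' @param sigma stabilized-domain noise standard deviation.
#' @param passthrough force `W` to 1 everywhere (identity filter;
#'   diagnostics only).
#' @return a `filtered_group`.
#' @export
wiener_filter_group <- function(noisy_group, basic_group, sigma = 1,
                                passthrough = FALSE) {
  if (!identical(dim(noisy_group$stack), dim(basic_group$stack)))
    stop_input("noisy and basic group stacks must share the same shape")
  if (passthrough) {
    W2 <- length(noisy_group$stack)
    return(filtered_group(noisy_group$stack, 1 / (sigma^2 * W2),
                          noisy_group$match))
  }
  P <- transform_4d(basic_group$stack)^2
  W <- P / (P + sigma^2)
  out <- inverse_transform_4d(W * transform_4d(noisy_group$stack))
  filtered_group(out, 1 / (sigma^2 * max(sum(W^2), 1e-12)), noisy_group$match)
}

#' Kaiser window
#'
#' Standard Kaiser window of length `n` with shape parameter `beta`, used as a
#' 2-D separable spatial taper in aggregation to down-weight block borders.
#'
#' @param n window length.
#' @param beta shape parameter.
#' @return numeric vector of length `n` with values in (0, 1].
#' @export
kaiser_window <- function(n, beta) {
  if (n == 1) return(1)
  x <- 2 * (0:(n - 1)) / (n - 1) - 1
  besselI(beta * sqrt(1 - x^2), 0) / besselI(beta, 0)
}

#' Weighted-average aggregation of filtered groups
#'
#' Returns every filtered block to its source position and combines
#' overlapping estimates by a weighted average, where each contribution is
#' weighted by its group's reliability weight times a 2-D Kaiser window over
#' the block (reducing border effects). Pixels covered by no block are left
#' at zero; with `require_coverage = TRUE` (as used inside the denoiser,
#' whose snapped reference grid guarantees coverage) an uncovered pixel
#' raises an error instead, since it indicates a broken reference grid.
#'
#' @param filtered list of `filtered_group` objects for one slice.
#' @param slice_shape integer `(n_row, n_col)` of the slice.
#' @param kaiser_beta Kaiser shape parameter.
#' @param require_coverage error on uncovered pixels instead of zeroing them.
#' @return 3-D array `n_row x n_col x n_frames`, the aggregated slice
#'   estimate for all frames.
#' @export
aggregate_groups <- function(filtered, slice_shape, kaiser_beta = 2.0,
                             require_coverage = FALSE) {
  stopifnot(length(filtered) >= 1)
  N <- dim(filtered[[1]]$stack)[1]
  Tn <- dim(filtered[[1]]$stack)[3]
  nr <- slice_shape[1]; nc <- slice_shape[2]
  num <- array(0, c(nr, nc, Tn))
  den <- array(0, c(nr, nc, Tn))
  kw <- kaiser_window(N, kaiser_beta)
  k2 <- as.vector(outer(kw, kw))
  offs <- as.vector(outer(0:(N - 1L), (0:(N - 1L)) * nr, "+"))
  pix_t <- as.vector(outer(offs, (0:(Tn - 1L)) * (nr * nc), "+"))  # N^2 T
  for (g in filtered) {
    w <- g$weight * k2
    wv <- rep(w, Tn)
    mem <- g$match$members
    for (m in seq_len(nrow(mem))) {
      if (mem[m, 1] + N - 1 > nr || mem[m, 2] + N - 1 > nc || any(mem[m, ] < 1))
        stop_input("block at (%d, %d) out of bounds during aggregation",
                   mem[m, 1], mem[m, 2])
      idx <- pix_t + (mem[m, 1] - 1L) + (mem[m, 2] - 1L) * nr + 1L
      num[idx] <- num[idx] + wv * as.vector(g$stack[, , , m])
      den[idx] <- den[idx] + wv
    }
  }
  if (any(den == 0)) {
    if (require_coverage)
      stop_input("aggregation left %d uncovered voxels (broken reference grid)",
                 sum(den == 0))
    den[den == 0] <- 1  # uncovered pixels stay zero
  }
  num / den
}

## per-slice two-step denoiser; A is the stabilized slice (nr x nc x T)
denoise_slice <- function(A, cfg) {
  m <- cfg$match; N <- m$block_size
  sigma <- cfg$vst$sigma
  nr <- dim(A)[1]; nc <- dim(A)[2]; Tn <- dim(A)[3]
  sig_g <- sigma * sqrt(Tn)
  vr <- nr - N + 1L; vc <- nc - N + 1L
  ri <- ref_positions(vr, m$step); rj <- ref_positions(vc, m$step)
  refs <- cbind(rep(ri, times = length(rj)), rep(rj, each = length(ri)))

  run_step <- function(guide, tau, prefilter_thr, filter_fun) {
    Cth <- prefilter_coeffs(block_coeff_matrix(guide, N), prefilter_thr)
    n2 <- rowSums(Cth^2)
    tau_abs <- tau * sig_g^2
    groups <- vector("list", nrow(refs))
    for (r in seq_len(nrow(refs))) {
      ms <- match_core(Cth, n2, vr, vc, refs[r, 1], refs[r, 2],
                       m$window, tau_abs, m$max_group, N)
      groups[[r]] <- filter_fun(ms)
    }
    aggregate_groups(groups, c(nr, nc), cfg$filter$kaiser_beta,
                     require_coverage = TRUE)
  }

  ## Step 1: guide from the noisy accumulation, hard-threshold filtering
  guide1 <- rowSums(A, dims = 2)
  basic <- run_step(guide1, m$tau_match, m$prefilter_threshold * sig_g,
                    function(ms) {
                      grp <- list(stack = stack_blocks(A, ms$members, N),
                                  match = ms)
                      ht_filter_group(grp, cfg)
                    })
  if ((cfg$filter$steps %||% 2L) == 1L) return(basic)

  ## Step 2: guide from the basic-estimate accumulation, re-matching (plain
  ## distance), Wiener shrinkage with the basic estimate as pilot
  guide2 <- rowSums(basic, dims = 2)
  run_step(guide2, m$tau_match_wiener, 0,
           function(ms) {
             gN <- list(stack = stack_blocks(A, ms$members, N), match = ms)
             gB <- list(stack = stack_blocks(basic, ms$members, N), match = ms)
             wiener_filter_group(gN, gB, sigma,
                                 passthrough = cfg$filter$wiener_passthrough)
           })
}

#' Two-step guided 4-D collaborative denoiser
#'
#' Denoises a variance-stabilized dynamic sinogram slice by slice. Step 1
#' builds a guide image by accumulating the noisy frames, matches blocks on
#' it, stacks the matched space-time blocks into 4-D groups, filters each
#' group by hard thresholding in the separable orthonormal DCT domain, and
#' aggregates the overlapping filtered blocks into a basic estimate. Step 2
#' rebuilds the guide from the basic estimate's accumulation, re-matches on
#' it, and filters the noisy groups by empirical Wiener shrinkage with the
#' basic estimate as the pilot spectrum, followed by the same aggregation.
#' The procedure contains no randomness and is fully deterministic. Setting
#' `filter$steps = 1` in the configuration stops after the hard-threshold
#' stage and returns the basic estimate.
#'
#' @param stab a [stabilized_sinogram()].
#' @param cfg configuration from [denoise_config()].
#' @return a [stabilized_sinogram()] with the denoised data, same shape.
#' @export
gbm4d_denoise <- function(stab, cfg = denoise_config()) {
  stopifnot(inherits(stab, "stabilized_sinogram"))
  if (!all(is.finite(stab$data))) stop_input("sinogram must be finite")
  cfg$vst$sigma <- stab$sigma
  d <- dim(stab$data)
  out <- array(0, d)
  for (s in seq_len(d[3])) {
    A <- stab$data[, , s, , drop = FALSE]
    dim(A) <- d[c(1, 2, 4)]
    out[, , s, ] <- denoise_slice(A, cfg)
  }
  stabilized_sinogram(out, sigma = stab$sigma,
                      frame_durations = stab$frame_durations)
}

#' Denoise a dynamic count sinogram end to end
#'
#' Convenience wrapper: Anscombe stabilization, [gbm4d_denoise()], exact
#' unbiased inverse transform back to the count domain.
#'
#' @param sino a [dynamic_sinogram()].
#' @param cfg configuration from [denoise_config()].
#' @return 4-D array of denoised count-domain values (Poisson mean estimates).
#' @export
gbm4d_denoise_counts <- function(sino, cfg = denoise_config()) {
  stab <- stabilize(sino, sigma = cfg$vst$sigma)
  unstabilize(gbm4d_denoise(stab, cfg))
}
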