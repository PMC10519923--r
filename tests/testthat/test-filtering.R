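test_that("4-D transform is orthonormal with an exact inverse", {
  x <- gbm4d:::with_seed(1, array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4)))
  expect_lt(max(abs(inverse_transform_4d(transform_4d(x)) - x)), 1e-10)
  expect_equal(sum(transform_4d(x)^2), sum(x^2), tolerance = 1e-12)
  ## constant stack concentrates in the DC coefficient
  cs <- array(3, c(8, 8, 3, 5))
  tc <- transform_4d(cs)
  expect_equal(tc[1, 1, 1, 1], 3 * sqrt(8 * 8 * 3 * 5), tolerance = 1e-10)
  expect_lt(max(abs(tc[-1])), 1e-10)
  expect_error(transform_4d(matrix(1, 2, 2)), "4-D")
})

test_that("singleton-frame 4-D transform equals the 3-D transform bitwise", {
  y <- gbm4d:::with_seed(2, array(rnorm(8 * 8 * 1 * 6), c(8, 8, 1, 6)))
  y3 <- y; dim(y3) <- c(8, 8, 6)
  expect_identical(as.vector(transform_4d(y)), as.vector(transform_3d(y3)))
  expect_identical(as.vector(inverse_transform_4d(y)),
                   as.vector(inverse_transform_3d(y3)))
})

test_that("hard thresholding zeroes the closed boundary and counts survivors", {
  ## the threshold condition is inclusive: |v| = lambda * sigma is shrunk
  r <- hard_threshold(c(2.8, -2.8, 2.8000001, 0), sigma = 1, lambda_4d = 2.8)
  expect_identical(r$coeffs, c(0, 0, 2.8000001, 0))
  expect_identical(r$n_retained, 1L)
  z <- hard_threshold(array(0, c(4, 4)), 1, 2.8)
  expect_true(all(z$coeffs == 0))
  expect_identical(z$n_retained, 0L)
  ## scalar-loop oracle
  x <- gbm4d:::with_seed(3, array(rnorm(8 * 8 * 4 * 4, sd = 3), c(8, 8, 4, 4)))
  got <- hard_threshold(x, sigma = 1.3, lambda_4d = 2.8)
  ref <- x; n <- 0L
  for (k in seq_along(ref)) {
    if (abs(ref[k]) <= 2.8 * 1.3) ref[k] <- 0 else n <- n + 1L
  }
  expect_identical(got$coeffs, ref)
  expect_identical(got$n_retained, n)
})

test_that("hard-threshold group filtering composes transform, shrinkage, inverse", {
  cfg <- denoise_config()
  ms <- match_set(rbind(c(1, 1), c(3, 3)), c(0, 0.1))
  ## noiseless constant group passes through with weight 1/sigma^2
  grp <- list(stack = array(50, c(8, 8, 4, 2)), match = ms)
  fg <- ht_filter_group(grp, cfg)
  expect_equal(fg$stack, grp$stack, tolerance = 1e-10)
  expect_equal(fg$weight, 1)
  ## sub-threshold group shrinks to zero with the clamped weight
  tiny <- list(stack = array(0.01, c(8, 8, 4, 2)) *
                 gbm4d:::with_seed(4, array(rnorm(512), c(8, 8, 4, 2))),
               match = ms)
  fg2 <- ht_filter_group(tiny, cfg)
  expect_true(all(fg2$stack == 0))
  expect_equal(fg2$weight, 1)
  ## compositional oracle
  big <- list(stack = gbm4d:::with_seed(5, array(rnorm(512, sd = 4), c(8, 8, 4, 2))),
              match = ms)
  fg3 <- ht_filter_group(big, cfg)
  ht <- hard_threshold(transform_4d(big$stack), cfg$vst$sigma, cfg$filter$lambda_4d)
  expect_identical(fg3$stack, inverse_transform_4d(ht$coeffs))
  expect_identical(fg3$weight, 1 / max(ht$n_retained, 1))
  ## energy contraction
  expect_lte(sum(fg3$stack^2), sum(big$stack^2) + 1e-10)
})

test_that("Wiener shrinkage uses the basic estimate's spectrum", {
  ms <- match_set(rbind(c(1, 1)), 0)
  noisy <- list(stack = gbm4d:::with_seed(6, array(rnorm(256, sd = 2), c(8, 8, 2, 2))),
                match = ms)
  ## zero pilot: gain identically zero
  basic0 <- list(stack = array(0, c(8, 8, 2, 2)), match = ms)
  w0 <- wiener_filter_group(noisy, basic0, sigma = 1)
  expect_true(all(w0$stack == 0))
  ## pilot coefficient equal to sigma: that coefficient is halved
  co <- array(0, c(8, 8, 2, 2)); co[2, 3, 1, 1] <- 1.7
  basic1 <- list(stack = inverse_transform_4d(co), match = ms)
  w1 <- wiener_filter_group(basic1, basic1, sigma = 1.7)
  expect_equal(w1$stack, basic1$stack / 2, tolerance = 1e-10)
  ## vanishing sigma: passthrough of the noisy stack
  wp <- wiener_filter_group(noisy, noisy, sigma = 1e-8)
  expect_equal(wp$stack, noisy$stack, tolerance = 1e-6)
  ## energy contraction
  basicr <- list(stack = gbm4d:::with_seed(7, array(rnorm(256), c(8, 8, 2, 2))),
                 match = ms)
  wr <- wiener_filter_group(noisy, basicr, sigma = 1)
  expect_lte(sum(wr$stack^2), sum(noisy$stack^2) + 1e-10)
  expect_error(wiener_filter_group(noisy, list(stack = array(0, c(4, 4, 2, 2)),
                                               match = ms), 1), "shape")
})

test_that("aggregation is a Kaiser-weighted average of covering blocks", {
  ## single group, single member, unit weight, flat window
  ms <- match_set(rbind(c(3, 4)), 0)
  stack <- gbm4d:::with_seed(8, array(rnorm(4 * 4 * 2), c(4, 4, 2, 1)))
  fg <- structure(list(stack = stack, weight = 1, match = ms),
                  class = "filtered_group")
  out <- aggregate_groups(list(fg), c(10, 12), kaiser_beta = 0)
  expect_equal(out[3:6, 4:7, ], stack[, , , 1], tolerance = 1e-12)
  touched <- array(FALSE, c(10, 12, 2)); touched[3:6, 4:7, ] <- TRUE
  expect_true(all(out[!touched] == 0))
  expect_error(aggregate_groups(list(fg), c(10, 12), 0, require_coverage = TRUE),
               "uncovered")

  ## overlapping identical values: the overlap keeps that value
  msA <- match_set(rbind(c(1, 1)), 0); msB <- match_set(rbind(c(3, 3)), 0)
  v <- array(7, c(4, 4, 1, 1))
  fa <- structure(list(stack = v, weight = 0.2, match = msA), class = "filtered_group")
  fb <- structure(list(stack = v, weight = 5, match = msB), class = "filtered_group")
  ## cover the remaining corners so every pixel is reached
  msC <- match_set(rbind(c(1, 3)), 0); msD <- match_set(rbind(c(3, 1)), 0)
  fc <- structure(list(stack = v, weight = 1, match = msC), class = "filtered_group")
  fd <- structure(list(stack = v, weight = 1, match = msD), class = "filtered_group")
  out2 <- aggregate_groups(list(fa, fb, fc, fd), c(6, 6), kaiser_beta = 2)
  expect_equal(as.vector(out2), rep(7, 36), tolerance = 1e-12)

  ## accumulation-loop oracle with random overlapping blocks and weights
  groups <- lapply(1:6, function(k) {
    mem <- gbm4d:::with_seed(30 + k, rbind(c(sample(9, 1), sample(9, 1)),
                                           c(sample(9, 1), sample(9, 1))))
    structure(list(stack = gbm4d:::with_seed(60 + k,
                     array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))),
                   weight = k / 3,
                   match = match_set(mem, c(0, 0.2))),
              class = "filtered_group")
  })
  ## ensure full coverage with a coarse grid of flat groups
  for (i in c(1, 5, 9)) for (j in c(1, 5, 9)) {
    groups[[length(groups) + 1]] <- structure(
      list(stack = array(1, c(4, 4, 2, 1)), weight = 1e-3,
           match = match_set(rbind(c(i, j)), 0)),
      class = "filtered_group")
  }
  beta <- 2
  got <- aggregate_groups(groups, c(12, 12), kaiser_beta = beta)
  kw <- kaiser_window(4, beta); k2 <- outer(kw, kw)
  num <- den <- array(0, c(12, 12, 2))
  for (g in groups) for (m in seq_len(nrow(g$match$members))) {
    i0 <- g$match$members[m, 1]; j0 <- g$match$members[m, 2]
    for (t in 1:2) for (i in 1:4) for (j in 1:4) {
      num[i0 + i - 1, j0 + j - 1, t] <-
        num[i0 + i - 1, j0 + j - 1, t] + g$weight * k2[i, j] * g$stack[i, j, t, m]
      den[i0 + i - 1, j0 + j - 1, t] <-
        den[i0 + i - 1, j0 + j - 1, t] + g$weight * k2[i, j]
    }
  }
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("the full denoiser is deterministic and respects degenerate inputs", {
  ## zero sinogram in, zero sinogram out
  z <- stabilized_sinogram(array(0, c(32, 32, 1, 2)))
  expect_true(all(gbm4d_denoise(z)$data == 0))

  ## noiseless piecewise-constant input passes through at tiny sigma
  pc <- array(2, c(48, 48, 1, 3)); pc[10:30, 5:25, , ] <- 6
  stc <- stabilized_sinogram(pc, sigma = 1e-6)
  out <- gbm4d_denoise(stc)
  expect_lt(max(abs(out$data - pc)) / max(pc), 1e-4)

  ## determinism
  st <- random_stab(48, 48, n_frames = 3, seed = 12)
  expect_identical(gbm4d_denoise(st)$data, gbm4d_denoise(st)$data)
})

test_that("denoising raises PSNR on noisy Shepp-Logan sinograms", {
  ph <- shepp_logan_phantom(64)
  clean1 <- forward_project(ph)
  clean <- array(rep(clean1 * 1e5 / sum(clean1), 8), c(64, 64, 1, 8))
  gains <- vapply(1:10, function(s) {
    sino <- add_poisson_noise(clean, sum(clean), seed = s)
    den <- gbm4d_denoise_counts(sino)
    psnr(clean, den) - psnr(clean, sino$counts)
  }, numeric(1))
  expect_true(all(gains > 0))
})

test_that("the Wiener step does not undo the basic estimate's gain", {
  ph <- shepp_logan_phantom(64)
  clean1 <- forward_project(ph)
  clean <- array(rep(clean1 * 1e5 / sum(clean1), 8), c(64, 64, 1, 8))
  cfg1 <- denoise_config(filter = list(steps = 1L))
  cfg2 <- denoise_config()
  p1 <- p2 <- numeric(10)
  for (s in 1:10) {
    sino <- add_poisson_noise(clean, sum(clean), seed = 100 + s)
    p1[s] <- psnr(clean, gbm4d_denoise_counts(sino, cfg1))
    p2[s] <- psnr(clean, gbm4d_denoise_counts(sino, cfg2))
  }
  expect_gte(mean(p2), mean(p1))
})
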