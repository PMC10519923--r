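test_that("guide image is the frame-axis sum of one slice", {
  st <- random_stab(16, 16, n_slices = 2, n_frames = 3, seed = 5)
  g <- build_guide(st, 2)
  oracle <- st$data[, , 2, 1] + st$data[, , 2, 2] + st$data[, , 2, 3]
  expect_equal(unclass(g), oracle, ignore_attr = TRUE)

  one <- stabilized_sinogram(st$data[, , , 1, drop = FALSE])
  expect_equal(unclass(build_guide(one, 1)), st$data[, , 1, 1],
               ignore_attr = TRUE)

  two <- stabilized_sinogram(array(rep(st$data[, , 1, 1], 2), c(16, 16, 1, 2)))
  expect_equal(unclass(build_guide(two, 1)), 2 * st$data[, , 1, 1],
               ignore_attr = TRUE)

  expect_error(build_guide(st, 3), "out of range")
})

test_that("prefiltered distance is a normalized transform-domain distance", {
  g <- gbm4d:::with_seed(8, matrix(rnorm(40 * 40), 40, 40))
  ## identity
  expect_identical(prefiltered_distance(g, c(5, 5), c(5, 5)), 0)
  ## with the prefilter off it equals the plain pixel distance (Parseval)
  b1 <- g[3:10, 4:11]; b2 <- g[20:27, 15:22]
  d <- prefiltered_distance(g, c(3, 4), c(20, 15), prefilter_threshold = 0)
  expect_equal(d, sum((b1 - b2)^2) / 64, tolerance = 1e-12)
  ## symmetry
  expect_equal(prefiltered_distance(g, c(3, 4), c(20, 15), prefilter_threshold = 2),
               prefiltered_distance(g, c(20, 15), c(3, 4), prefilter_threshold = 2))
  expect_error(prefiltered_distance(g, c(1, 1), c(38, 38)), "inside")
})

test_that("matching is exhaustive, thresholded and deterministically ordered", {
  cfg <- denoise_config()$match
  ## constant guide: every candidate at distance 0, raster tie-break, ref first
  gc <- matrix(1, 30, 30)
  ms <- match_blocks(gc, c(10, 10), cfg)
  expect_identical(nrow(ms$members), cfg$max_group)
  expect_identical(ms$members[1, ], c(10L, 10L))
  expect_true(all(ms$distances == 0))
  ## tie-break: candidates in column-major raster order of the window
  expect_identical(ms$members[2, ], c(1L, 1L))
  expect_identical(ms$members[3, ], c(2L, 1L))

  ## constructed duplicate: only the duplicate matches under a tight threshold
  g2 <- gbm4d:::with_seed(9, matrix(rnorm(40 * 40, sd = 10), 40, 40))
  g2[20:27, 20:27] <- g2[5:12, 5:12]
  cfg2 <- cfg; cfg2$tau_match <- 1e-6; cfg2$window <- 39L
  ms2 <- match_blocks(g2, c(5, 5), cfg2, sigma_guide = 1)
  expect_identical(ms2$members, rbind(c(5L, 5L), c(20L, 20L)))

  ## completeness: infinite threshold + large max_group returns the window
  cfg3 <- cfg; cfg3$tau_match <- Inf; cfg3$max_group <- 10000L; cfg3$window <- 9L
  ms3 <- match_blocks(g2, c(10, 10), cfg3)
  expect_identical(nrow(ms3$members), 81L)

  ## determinism
  msa <- match_blocks(g2, c(7, 9), cfg)
  msb <- match_blocks(g2, c(7, 9), cfg)
  expect_identical(msa, msb)
})

test_that("matching agrees with a brute-force window scan", {
  cfg <- denoise_config()$match
  for (seed in 1:5) {
    g <- gbm4d:::with_seed(seed, matrix(rnorm(64 * 64), 64, 64))
    ref <- gbm4d:::with_seed(seed + 100,
                             c(sample(57, 1), sample(57, 1)))
    ms <- match_blocks(g, ref, cfg, sigma_guide = 1)
    bf <- oracle_match(g, ref, cfg$block_size, cfg$window,
                       cfg$tau_match, cfg$max_group,
                       cfg$prefilter_threshold)
    expect_identical(unname(ms$members), unname(bf))
  }
})

test_that("guided matching beats single-frame matching under noise", {
  ## guide = clean + N(0, sigma^2/|T|)-equivalent accumulation vs one frame
  base <- forward_project(array(shepp_logan_phantom(48), c(48, 48, 1)))[, , 1]
  base <- base / max(base) * 40
  cfg <- denoise_config()$match
  cfg$window <- 21L
  refs <- list(c(10, 10), c(20, 25), c(30, 15), c(15, 35))
  Tn <- 8
  overlap <- function(a, b) {
    ka <- paste(a[, 1], a[, 2]); kb <- paste(b[, 1], b[, 2])
    length(intersect(ka, kb)) / length(kb)
  }
  ov_guided <- ov_single <- numeric(50)
  for (s in 1:50) {
    noise <- gbm4d:::with_seed(s, array(rnorm(48 * 48 * Tn), c(48, 48, Tn)))
    guided <- Tn * base + sqrt(Tn) *
      matrix(rowSums(matrix(noise, 48 * 48, Tn)) / sqrt(Tn), 48, 48)
    single <- base + noise[, , 1]
    og <- os <- numeric(length(refs))
    for (k in seq_along(refs)) {
      oracle <- match_blocks(Tn * base, refs[[k]], cfg,
                             sigma_guide = sqrt(Tn))$members
      og[k] <- overlap(match_blocks(guided, refs[[k]], cfg,
                                    sigma_guide = sqrt(Tn))$members, oracle)
      oracle1 <- match_blocks(base, refs[[k]], cfg, sigma_guide = 1)$members
      os[k] <- overlap(match_blocks(single, refs[[k]], cfg,
                                    sigma_guide = 1)$members, oracle1)
    }
    ov_guided[s] <- mean(og); ov_single[s] <- mean(os)
  }
  expect_gt(mean(ov_guided), mean(ov_single))
  expect_lt(t.test(ov_guided, ov_single, paired = TRUE,
                   alternative = "greater")$p.value, 0.01)
})

test_that("group stacking reproduces source voxels exactly", {
  ## counter-valued array: every entry equals its own linear index
  nr <- 20; nc <- 18; Tn <- 3
  arr <- array(seq_len(nr * nc * Tn), c(nr, nc, 1, Tn))
  st <- stabilized_sinogram(arr)
  ms <- match_set(rbind(c(3, 4), c(11, 9)), c(0, 0.5))
  grp <- stack_group(st, ms, block_size = 4, slice_index = 1)
  expect_identical(dim(grp$stack), c(4L, 4L, 3L, 2L))
  for (m in 1:2) for (t in 1:Tn) for (i in 1:4) for (j in 1:4) {
    src <- arr[ms$members[m, 1] + i - 1, ms$members[m, 2] + j - 1, 1, t]
    expect_identical(grp$stack[i, j, t, m], src)
  }

  ## frame-constant input: stack constant along the frame axis
  cst <- stabilized_sinogram(array(rep(arr[, , 1, 1], 2), c(nr, nc, 1, 2)))
  g2 <- stack_group(cst, ms, 4, 1)
  expect_identical(g2$stack[, , 1, ], g2$stack[, , 2, ])

  ## one member, one frame: the raw block
  one <- stabilized_sinogram(arr[, , , 1, drop = FALSE])
  g3 <- stack_group(one, match_set(rbind(c(3, 4)), 0), 4, 1)
  expect_identical(g3$stack[, , 1, 1], arr[3:6, 4:7, 1, 1])

  expect_error(stack_group(st, match_set(rbind(c(18, 1)), 0), 4, 1),
               "out of bounds")
})
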