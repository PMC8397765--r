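degraded_fiber_sub <- function(psf_vox = 1, noise = 0.05, seed = 9) {
  v <- degrade(fix_fiber80(), psf_sigma = psf_vox * 1.63, noise_sigma = noise,
               seed = seed)
  subvolume(v$data[1:64, 1:64, 1:64], 1.63, "fibers")
}

test_that("subvolume labels gate metric legality", {
  s <- subvolume(array(rnorm(16^3), c(16, 16, 16)), 1, "fat_cells")
  expect_error(estimate_resolution(s), "fiber")
  expect_error(uts(s), "fiber")
  sf <- subvolume(array(rnorm(16^3), c(16, 16, 16)), 1, "fibers")
  expect_error(gse(sf), "fat-cell")
})

test_that("pure noise saturates the resolution estimate at the Nyquist period", {
  s <- subvolume(withr::with_seed(2, array(rnorm(64^3), c(64, 64, 64))),
                 1.63, "fibers")
  expect_equal(estimate_resolution(s), 2 * 1.63)
})

test_that("the resolution estimate degrades monotonically with blur", {
  r1 <- estimate_resolution(degraded_fiber_sub(psf_vox = 0.5))
  r2 <- estimate_resolution(degraded_fiber_sub(psf_vox = 2))
  expect_gt(r2, r1)
  expect_gte(r1, 2 * 1.63)   # Nyquist floor
})

test_that("the resolution estimate is invariant to gray offset and scale", {
  s <- degraded_fiber_sub()
  r <- estimate_resolution(s)
  s2 <- subvolume(3.7 * s$data + 11, s$voxel_size, "fibers")
  expect_equal(estimate_resolution(s2), r)
})

test_that("resolution estimation rejects undersized sub-volumes", {
  s <- subvolume(array(rnorm(32^3), c(32, 32, 32)), 1, "fibers")
  expect_error(estimate_resolution(s), ">= 64")
})

test_that("FMCR reproduces the defining arithmetic", {
  # fibers alternating 8/12 (mean 10), matrix alternating 4/8 (mean 6),
  # both with sd -> 2: FMCR -> (10 - 6) / 2 = 2
  n <- 2000L
  d <- array(0, c(20, 20, 10))
  fib <- array(FALSE, dim(d)); mat <- array(FALSE, dim(d))
  fib[, , 1:5] <- TRUE
  mat[, , 6:10] <- TRUE
  d[fib] <- rep(c(8, 12), n / 2)
  d[mat] <- rep(c(4, 8), n / 2)
  s <- subvolume(d, 1, "fibers")
  expect_equal(fmcr(s, fib, mat), 2, tolerance = 1e-3)
  # sign preserved when contrast inverts
  expect_equal(fmcr(s, mat, fib), -2, tolerance = 1e-3)
})

test_that("FMCR is near zero for identically distributed masks", {
  d <- withr::with_seed(1, array(rnorm(64^3), c(64, 64, 64)))
  m1 <- array(FALSE, dim(d)); m2 <- array(FALSE, dim(d))
  m1[, , 1:32] <- TRUE; m2[, , 33:64] <- TRUE
  expect_lt(abs(fmcr(subvolume(d, 1, "fibers"), m1, m2)), 0.05)
})

test_that("FMCR recovers the analytic contrast-to-noise ratio", {
  spec <- phantom_spec(shape = c(128L, 128L, 128L), seed = 2)
  v0 <- make_fiber_phantom(spec)
  vn <- degrade(v0, noise_sigma = spec$noise_sigma, seed = 3)
  fmask <- v0$data == spec$fiber_level
  target <- (spec$fiber_level - spec$matrix_level) / spec$noise_sigma
  f <- fmcr(subvolume(vn$data, 1.63, "fibers"), fmask, !fmask)
  expect_lt(abs(f / target - 1), 0.05)
})

test_that("FMCR validates masks", {
  s <- degraded_fiber_sub()
  m <- array(TRUE, dim(s$data))
  expect_error(fmcr(s, m, m), "overlap")
  small <- array(FALSE, dim(s$data)); small[1:5, 1, 1] <- TRUE
  expect_error(fmcr(s, small, !small), "1000")
  expect_error(fmcr(s, m[1:10, , ], m), "dimensions")
})

test_that("a perfectly bimodal volume has zero segmentation uncertainty", {
  v <- fix_fiber80()
  u <- uts(subvolume(v$data, 1.63, "fibers"))
  expect_identical(u$uts_pct, 0)
  expect_error(uts(subvolume(array(1, c(16, 16, 16)), 1, "fibers")),
               "degenerate")
})

test_that("the three-class Otsu band matches the exhaustive oracle", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, random_mixture())
    h <- tomoqc:::hist_fixed(x, bins = 256L)
    oracle <- oracle_otsu3(h$counts, h$mids)
    s <- subvolume(array(x, c(20, 50, 20)), 1, "fibers")
    u <- uts(s)
    expect_equal(c(u$t_low, u$t_high), h$upper[oracle])
    band <- 100 * sum(x > h$upper[oracle[1]] & x <= h$upper[oracle[2]]) / length(x)
    expect_equal(u$uts_pct, band, tolerance = 1e-9)
  }
})

test_that("two-class Otsu agrees with an independent implementation", {
  x <- withr::with_seed(3, c(rnorm(5000, 0.3, 0.05), rnorm(5000, 0.7, 0.05)))
  t_own <- otsu_thresholds(x, k = 2L, bins = 256L)
  t_ref <- EBImage::otsu(matrix(x, 100), range = range(x), levels = 256L)
  # EBImage assigns the split bin to both classes and averages tied
  # midpoints, so agreement is expected only up to a small convention skew
  expect_lt(abs(t_own - t_ref), 0.03 * diff(range(x)))
  # both thresholds separate the two mixture components
  expect_true(t_own > 0.4 && t_own < 0.6)
})

test_that("prefiltering an already-smooth field barely moves the thresholds", {
  v <- degrade(fix_fiber80(), psf_sigma = 1.63)   # noiseless, smooth
  s <- subvolume(v$data, 1.63, "fibers")
  u0 <- uts(s)
  u1 <- uts(s, prefilter_sigma = 0.5)
  span <- diff(range(v$data))
  expect_lt(abs(u1$t_low - u0$t_low) / span, 0.02)
  expect_lt(abs(u1$t_high - u0$t_high) / span, 0.02)
  expect_lt(abs(u1$uts_pct - u0$uts_pct), 1)
})

test_that("GSE errors on edge-free volumes", {
  expect_error(gse(subvolume(array(5, c(16, 16, 16)), 1, "fat_cells")),
               "no edges")
})

test_that("GSE decreases monotonically with blur and scales with gray gain", {
  f <- fix_fat80()
  g <- vapply(c(0.5, 2), function(s) {
    d <- degrade(f, psf_sigma = s * 1.63, noise_sigma = 0.05, seed = 10)
    gse(subvolume(d$data, 1.63, "fat_cells"))
  }, 0)
  expect_gt(g[1], g[2])
  d <- degrade(f, psf_sigma = 1.63, noise_sigma = 0.05, seed = 10)
  s1 <- subvolume(d$data, 1.63, "fat_cells")
  s2 <- subvolume(5 * d$data + 3, 1.63, "fat_cells")
  expect_equal(gse(s2), 5 * gse(s1), tolerance = 1e-9)
})

test_that("GSE on a sharp sphere equals a brute-force recomputation", {
  spec <- phantom_spec(shape = c(32L, 32L, 32L), voxel_size = 1,
                       sphere_radius_range = c(9, 9), sphere_count = 1L,
                       matrix_level = 0, fiber_level = 2, seed = 4)
  v <- make_fat_cell_phantom(spec)
  # oracle: naive loops, independent Otsu by direct scan over 256 bins
  grads <- c()
  for (k in 1:32) {
    sl <- v$data[, , k]
    for (i in 2:31) for (j in 2:31) {
      gy <- (sl[i + 1, j] - sl[i - 1, j]) / 2
      gx <- (sl[i, j + 1] - sl[i, j - 1]) / 2
      grads <- c(grads, sqrt(gy^2 + gx^2))
    }
  }
  lo <- min(grads); hi <- max(grads)
  cnt <- tabulate(pmin(pmax(floor((grads - lo) / (hi - lo) * 256) + 1, 1), 256),
                  256)
  mids <- lo + (hi - lo) * (seq_len(256) - 0.5) / 256
  p <- cnt / sum(cnt); muT <- sum(p * mids)
  bcv <- vapply(1:255, function(t) {
    w1 <- sum(p[1:t]); if (w1 <= 0 || w1 >= 1) return(-Inf)
    m1 <- sum(p[1:t] * mids[1:t]) / w1
    m2 <- (muT - w1 * m1) / (1 - w1)
    w1 * (1 - w1) * (m1 - m2)^2
  }, 0)
  thr <- lo + (hi - lo) * which.max(bcv) / 256
  oracle <- mean(grads[grads > thr])
  expect_equal(gse(subvolume(v$data, 1, "fat_cells")), oracle, tolerance = 1e-12)
})

test_that("all four metrics are invariant under a gray offset", {
  s <- degraded_fiber_sub()
  spec80 <- phantom_spec(shape = c(80L, 80L, 80L), noise_sigma = 0, seed = 5)
  fmask <- fix_fiber80()$data == spec80$fiber_level
  fmask <- fmask[1:64, 1:64, 1:64]
  f <- fix_fat80()
  fd <- degrade(f, psf_sigma = 1.63, noise_sigma = 0.05, seed = 10)
  sf <- subvolume(fd$data, 1.63, "fat_cells")
  for (off in c(-2, 7)) {
    s2 <- subvolume(s$data + off, 1.63, "fibers")
    sf2 <- subvolume(sf$data + off, 1.63, "fat_cells")
    expect_equal(estimate_resolution(s2), estimate_resolution(s))
    expect_equal(fmcr(s2, fmask, !fmask), fmcr(s, fmask, !fmask))
    expect_equal(uts(s2, 1)$uts_pct, uts(s, 1)$uts_pct)
    expect_equal(gse(sf2), gse(sf))
  }
})

test_that("UTS and FMCR are invariant under multiplicative gray rescale", {
  s <- degraded_fiber_sub()
  spec80 <- phantom_spec(shape = c(80L, 80L, 80L), noise_sigma = 0, seed = 5)
  fmask <- (fix_fiber80()$data == spec80$fiber_level)[1:64, 1:64, 1:64]
  s2 <- subvolume(4 * s$data, 1.63, "fibers")
  expect_equal(uts(s2, 1)$uts_pct, uts(s, 1)$uts_pct, tolerance = 1e-9)
  expect_equal(fmcr(s2, fmask, !fmask), fmcr(s, fmask, !fmask),
               tolerance = 1e-9)
})

test_that("metric summaries follow the sample-statistics definitions", {
  s <- summarize_metric(c(5, 5, 5))
  expect_equal(c(s$mean, s$sd, s$cv), c(5, 0, 0))
  s2 <- summarize_metric(c(4, 6))
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, sqrt(2))
  expect_equal(s2$cv, sqrt(2) / 5, tolerance = 1e-12)
  s3 <- summarize_metric(3 * c(4, 6))
  expect_equal(s3$cv, s2$cv)
  expect_error(summarize_metric(5), ">= 2")
  expect_error(summarize_metric(c(-1, 1)), "mean is zero")
})

test_that("quality_metrics assembles one row per sub-volume", {
  row <- quality_metrics(degraded_fiber_sub(), prefilter_sigma = 1)
  expect_s3_class(row, "quality_result")
  expect_false(anyNA(row[c("resolution_um", "fmcr", "uts_pct")]))
  expect_true(is.na(row$gse))
  fd <- degrade(fix_fat80(), psf_sigma = 1.63, noise_sigma = 0.05, seed = 10)
  rowf <- quality_metrics(subvolume(fd$data, 1.63, "fat_cells"))
  expect_false(is.na(rowf$gse))
  expect_true(is.na(rowf$resolution_um))
})
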