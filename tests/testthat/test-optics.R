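test_that("wavelength and fringe-distance rule match the closed forms", {
  expect_equal(xray_wavelength(15) * 1e10, 0.8266, tolerance = 1e-3)
  # z = (2p)^2 / lambda, homogeneous of degree 2 in p and -1 in lambda
  z <- first_fringe_distance(1.63, 15)
  expect_equal(first_fringe_distance(3.26, 15), 4 * z, tolerance = 1e-12)
  expect_equal(first_fringe_distance(1.63, 30), 2 * z, tolerance = 1e-12)
  expect_error(first_fringe_distance(0, 15), "pixel_size")
  expect_error(first_fringe_distance(1.63, -1), "energy")
})

test_that("skin dose is the product rule", {
  expect_identical(skin_dose(200, 0), 0)
  expect_equal(skin_dose(200, 0.033), 6.6)
  expect_error(skin_dose(-1, 1), "dose_rate")
})

test_that("optics config derives delta from the ratio and validates", {
  opt <- optics_config(delta_beta_ratio = 50)
  expect_equal(opt$delta, 50 * 9.3e-9)
  opt2 <- optics_config(delta = 1e-7)
  expect_equal(opt2$delta, 1e-7)
  expect_error(optics_config(energy = 0), "energy")
  expect_error(optics_config(beta = 0), "beta")
})

test_that("flat/dark correction normalizes, clips and validates", {
  set.seed(1)
  Fb <- matrix(1000 + rnorm(64 * 64, 0, 5), 64)
  Db <- matrix(100, 64, 64)
  opt <- optics_config()
  ps <- projection_set(list(Fb, Db, 0.5 * (Fb - Db) + Db),
                       flats = Fb, darks = Db, optics = opt)
  out <- flat_dark_correct(ps)
  expect_equal(out[[1]], matrix(1, 64, 64))
  expect_true(all(out[[2]] > 0))                       # floored, never zero
  expect_equal(max(out[[2]]), 1e-6 * mean(Fb))
  expect_equal(out[[3]], matrix(0.5, 64, 64))
  bad <- projection_set(Fb, flats = Db, darks = Fb, optics = opt)
  expect_error(flat_dark_correct(bad), "pixel")
})

test_that("projection set rejects mixed shapes and missing frames", {
  opt <- optics_config()
  expect_error(projection_set(matrix(1, 4, 4), matrix(1, 5, 5), matrix(0, 4, 4),
                              opt), "one shape")
  expect_error(projection_set(matrix(1, 4, 4), list(), list(matrix(0, 4, 4)),
                              opt), "at least one")
})

test_that("zero-distance propagation is the pure-absorption image", {
  spec <- phantom_spec(shape = c(32L, 64L, 64L), noise_sigma = 0)
  th <- make_phase_object(spec)
  opt <- optics_config(distance = 0)
  I <- fresnel_propagate(th, opt)
  mu <- 4 * pi * opt$beta / xray_wavelength(opt$energy)
  expect_equal(I, exp(-mu * th * 1e-6), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the Fresnel propagator conserves flux for a pure phase object", {
  spec <- phantom_spec(shape = c(32L, 128L, 128L), noise_sigma = 0)
  th <- make_phase_object(spec, psf_sigma = 1.63)
  opt <- optics_config(distance = 150, beta = 1e-30, delta = 4.65e-7)
  I <- fresnel_propagate(th, opt)
  expect_lt(abs(mean(I) - 1), 1e-3)
})

test_that("the edge overshoot distance scales with sqrt(lambda z)", {
  slab <- matrix(0, 512, 512)
  slab[, 257:512] <- 50
  locate <- function(z) {
    opt <- optics_config(pixel_size = 1, distance = z, delta_beta_ratio = 50)
    prof <- fresnel_propagate(slab, opt)[256, ]
    256 - which.max(prof[1:256])
  }
  d1 <- locate(500)
  d2 <- locate(1000)
  expect_gt(d1, 0)
  # doubling z should scale the distance by sqrt(2); allow pixel quantization
  expect_lt(abs((d2 / d1)^2 - 2), 0.5)
})

test_that("the aliasing guard reports the maximum safe distance", {
  opt <- optics_config(pixel_size = 0.33, distance = 5000)
  expect_error(fresnel_propagate(matrix(0, 64, 64), opt), "maximum safe distance")
})

test_that("Paganin retrieval passes DC unchanged", {
  opt <- optics_config(pixel_size = 1.63, distance = 150)
  mu <- 4 * pi * opt$beta / opt$wavelength
  tu <- paganin_retrieve(matrix(0.8, 32, 32), opt)
  expect_equal(tu, matrix(-log(0.8) / mu * 1e6, 32, 32), tolerance = 1e-10)
})

test_that("Paganin retrieval errors on non-positive filtered intensity", {
  opt <- optics_config(pixel_size = 1.63, distance = 150)
  I <- matrix(1, 32, 32)
  I[10:22, 10:22] <- -1   # a negative patch survives the low-pass filter
  expect_error(paganin_retrieve(I, opt), "non-positive")
})

test_that("forward propagation then retrieval recovers the thickness map", {
  spec <- phantom_spec(shape = c(48L, 256L, 256L), crimp_amplitude = 3,
                       crimp_period = 200, seed = 7)
  th <- make_phase_object(spec, psf_sigma = spec$psf_sigma)
  opt <- optics_config(pixel_size = 1.63, distance = 150, delta_beta_ratio = 50)
  rec <- paganin_retrieve(fresnel_propagate(th, opt), opt)
  rmse <- sqrt(mean((rec - th)^2))
  expect_lt(rmse / max(th), 0.02)
})

test_that("increasing the delta/beta ratio strengthens the low-pass filter", {
  spec <- phantom_spec(shape = c(48L, 128L, 128L), seed = 7)
  th <- make_phase_object(spec, psf_sigma = spec$psf_sigma)
  opt <- optics_config(pixel_size = 1.63, distance = 150)
  I <- fresnel_propagate(th, opt)
  I <- I + withr::with_seed(5, matrix(rnorm(length(I), 0, 0.01), nrow(I)))
  hf_fraction <- function(ratio) {
    t <- paganin_retrieve(I, optics_config(pixel_size = 1.63, distance = 150,
                                           delta_beta_ratio = ratio))
    P <- Mod(stats::fft(t - mean(t)))^2
    n <- nrow(P)
    f <- tomoqc:::fft_freq(n)
    hf <- abs(outer(f, f, function(a, b) pmax(abs(a), abs(b)))) > 0.25
    sum(P[hf]) / sum(P)
  }
  e <- vapply(c(10, 50, 100), hf_fraction, 0)
  expect_true(all(diff(e) < 0))
})

test_that("retrieval at vanishing ratio converges to the absorption-only log", {
  spec <- phantom_spec(shape = c(48L, 128L, 128L), seed = 3)
  th <- make_phase_object(spec, psf_sigma = spec$psf_sigma)
  opt <- optics_config(pixel_size = 1.63, distance = 150, delta_beta_ratio = 50)
  I <- fresnel_propagate(th, opt)
  opt_eps <- optics_config(pixel_size = 1.63, distance = 150,
                           delta_beta_ratio = 1e-6)
  mu <- 4 * pi * opt_eps$beta / opt_eps$wavelength
  t_eps <- paganin_retrieve(I, opt_eps)
  t_abs <- -log(I) / mu * 1e6
  expect_lt(max(abs(t_eps - t_abs)) / max(abs(t_abs)), 1e-6)
})

test_that("round-trip error decreases as noise vanishes", {
  spec <- phantom_spec(shape = c(48L, 128L, 128L), seed = 7)
  th <- make_phase_object(spec, psf_sigma = spec$psf_sigma)
  opt <- optics_config(pixel_size = 1.63, distance = 150, delta_beta_ratio = 50)
  I0 <- fresnel_propagate(th, opt)
  err <- vapply(c(0.02, 0.005, 0), function(s) {
    I <- I0 + withr::with_seed(8, matrix(rnorm(length(I0), 0, s), nrow(I0)))
    sqrt(mean((paganin_retrieve(I, opt) - th)^2))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("line profiles are extracted in order with bounds checking", {
  img <- outer(1:64, 1:300, function(i, j) j)  # ramp along x
  p <- ratio_line_profile(img, start = c(10, 51), direction = "x")
  expect_length(p, 200)
  expect_equal(p, as.numeric(51:250))
  expect_equal(diff(p), rep(1, 199))
  expect_equal(ratio_line_profile(matrix(3, 300, 10), c(5, 5), "y"),
               rep(3, 200))
  expect_error(ratio_line_profile(img, c(10, 200), "x"), "clipped extent")
  expect_error(ratio_line_profile(img, c(70, 1), "x"), "outside")
})
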