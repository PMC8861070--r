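test_that("ROI emission is a plain pixel sum", {
  img <- matrix(0, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[5:9, 5:14] <- TRUE
  expect_equal(emission_at_angle(img, roi), 0)
  img2 <- matrix(3, 20, 20)
  roi2 <- cbind(rep(1:5, each = 10), rep(1:10, 5))    # 50 pixels at value 3
  expect_equal(emission_at_angle(img2, roi2), 150)
  expect_error(emission_at_angle(img, matrix(FALSE, 20, 20)), "empty")
  expect_error(emission_at_angle(img, cbind(25, 1)), "outside")
})

test_that("a rendered cosine-law fiber image reproduces the cos profile", {
  # render-and-measure oracle: a strip of pixels whose intensity follows
  # I0 * cos(angle) with additive rendering granularity
  I0 <- 40
  angles <- c(0, 25, 50, 75)
  measured <- vapply(angles, function(a) {
    img <- matrix(0, 30, 30)
    img[10:19, 10:19] <- I0 * cos(a * pi / 180) / 100   # 100-pixel ROI
    roi <- matrix(FALSE, 30, 30); roi[10:19, 10:19] <- TRUE
    emission_at_angle(img, roi)
  }, numeric(1))
  expect_equal(measured, I0 * cos(angles * pi / 180), tolerance = 1e-10)
})

test_that("Lambertian fit recovers I0 exactly on cosine data", {
  prof <- emission_profile(c(0, 25, 50, 75), 7 * cos(c(0, 25, 50, 75) * pi / 180))
  fit <- fit_lambertian(prof)
  expect_equal(fit$I0, 7)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-12)
  # the model predicts zero emission at 90 degrees
  expect_equal(fit$I0 * cos(90 * pi / 180), 0, tolerance = 1e-12)
  expect_error(fit_lambertian(emission_profile(c(90, 90), c(0, 0))), "2 distinct")
  g <- glance(fit)
  expect_equal(g$I0, 7)
  expect_equal(tidy(fit)$estimate, 7)
})

test_that("Lambertian I0 is recovered within 3% at 5% noise", {
  set.seed(123)
  I0 <- 11
  angles <- seq(0, 75, by = 25)
  est <- replicate(100, {
    y <- pmax(0, I0 * cos(angles * pi / 180) + rnorm(length(angles), sd = 0.05 * I0))
    fit_lambertian(emission_profile(angles, y))$I0
  })
  expect_lt(abs(mean(est) - I0) / I0, 0.03)
})

test_that("cylindrical power density reproduces the printed reference values", {
  # 10 mW over a 2 mm emitting segment
  d1 <- power_density(10, emitting_length = 2, eval_radius = 0.015)
  expect_equal(round(d1$area_mm2, 3), 0.188)
  expect_equal(round(d1$density_mW_mm2), 53)
  d2 <- power_density(10, emitting_length = 2, eval_radius = 0.1)
  expect_equal(round(d2$area_mm2, 2), 1.26)
  expect_equal(round(d2$density_mW_mm2, 2), 7.96)
  expect_equal(power_density(0, 2, 0.015)$density_mW_mm2, 0)
  expect_error(power_density(10, 2, 0.01), "fiber radius")
})

test_that("power density scales homothetically", {
  base <- power_density(10, 2, 0.05)$density_mW_mm2
  expect_equal(power_density(10, 4, 0.05)$density_mW_mm2, base / 2)
  expect_equal(power_density(20, 2, 0.05)$density_mW_mm2, base * 2)
})

test_that("grid addressability counts square-lattice positions", {
  expect_equal(addressable_fibers(0.1, 1), 100L)
  expect_equal(addressable_fibers(1, 1), 1L)
  expect_equal(addressable_fibers(0.5, 1), 4L)   # 2 x 2 grid
  expect_error(addressable_fibers(0, 1), "pitch")
})

test_that("intensity ratio recovers a constructed efficiency gain", {
  # saturating transfer: amplitude = sat * (1 - exp(-slope * I / sat))
  cfg <- synth_config()
  tcourse <- function(amp, nt = 50) amp * c(seq(0.2, 1, length.out = 10), rep(1, nt - 10))
  I_a <- c(5, 10, 20, 60, 120)
  mk_curve <- function(intens) {
    arr <- array(0, dim = c(3, length(intens), 50))
    for (c in 1:3) for (i in seq_along(intens)) {
      arr[c, i, ] <- tcourse(pvr_amplitude(intens[i], cfg) * (0.8 + 0.1 * c))
    }
    pvr_transfer_curve(arr, intens)
  }
  a <- mk_curve(I_a)
  # identical transfer curves: ratio 1 on every channel
  r0 <- intensity_ratio(a, a)
  expect_true(all(abs(r0$per_channel$ratio - 1) < 1e-9))

  # configuration B reaches the same response at 2.3x less intensity:
  # same amplitudes, intensity axis divided by 2.3
  b <- pvr_transfer_curve(a$amplitudes, I_a / 2.3)
  r <- intensity_ratio(a, b)
  expect_equal(r$mean_ratio, 2.3, tolerance = 0.05)

  # a curve never reaching the linear limit falls back to its own maximum
  weak <- mk_curve(I_a / 50)
  r2 <- intensity_ratio(weak, weak)
  expect_true(all(abs(r2$per_channel$ratio - 1) < 1e-9))
})

test_that("intensity ratio is inverse-symmetric on linear transfers", {
  lin <- function(intens, gain) {
    arr <- array(0, dim = c(2, length(intens), 20))
    for (c in 1:2) for (i in seq_along(intens)) {
      arr[c, i, ] <- gain * intens[i] * seq(0.5, 1, length.out = 20)
    }
    pvr_transfer_curve(arr, intens, linear_limit = 1e9)
  }
  # same top amplitude on both sides so each target is bracketed
  a <- lin(c(2, 4, 8, 16), gain = 30)
  b <- lin(c(2, 4, 8, 16) * 0.6, gain = 50)
  rab <- intensity_ratio(a, b)$mean_ratio
  rba <- intensity_ratio(b, a)$mean_ratio
  expect_equal(rab * rba, 1, tolerance = 0.02)
})

test_that("fiber images round-trip through PNG with a polygon ROI", {
  skip_if_not_installed("png")
  img <- matrix(runif(40 * 30), 40, 30)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, f)
  img2 <- read_fiber_image(f)
  expect_equal(dim(img2), c(40, 30))
  expect_equal(img2, img, tolerance = 1 / 255)    # 8-bit quantization

  # rectangle polygon selects exactly the interior pixels
  poly <- cbind(c(9.5, 9.5, 20.5, 20.5), c(4.5, 15.5, 15.5, 4.5))
  roi <- roi_from_polygon(poly, dim(img2))
  expect_equal(sum(roi), 11 * 11)
  expect_true(all(which(roi, arr.ind = TRUE)[, 1] %in% 10:20))
  expect_gt(emission_at_angle(img2, roi), 0)
})
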