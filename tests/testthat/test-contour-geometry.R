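test_that("contours validate, orient CCW and measure arc length", {
  expect_error(nuclear_contour(c(0, 1), c(0, 0)), "at least 3")
  expect_error(nuclear_contour(c(0, 0, 1), c(0, 0, 1)), "distinct")
  cc <- circle_contour(4, 128)
  expect_equal(cc$arc_length, 2 * pi * 4, tolerance = 1e-3)
  # clockwise input is normalised to the same traversal sense
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  cw <- nuclear_contour(4 * cos(-th), 4 * sin(-th))
  expect_equal(osculating_curvature(cw, 1), osculating_curvature(cc, 1))
})

test_that("osculating curvature is exact on circles and straight lines", {
  expect_equal(osculating_curvature(circle_contour(2, 128), 1), 0.5,
               tolerance = 1e-9)
  open <- nuclear_contour(seq(0, 10, by = 0.25), rep(0, 41), closed = FALSE)
  expect_identical(osculating_curvature(open, 20), 0)
  # window wider than half the perimeter is clamped, not an error
  expect_equal(osculating_curvature(circle_contour(0.5, 256), 3,
                                    arc_window = 2), 2, tolerance = 1e-6)
  expect_error(osculating_curvature(circle_contour(2, 128), 1,
                                    arc_window = -1), "positive")
  expect_error(osculating_curvature(nuclear_contour(cos(1:5), sin(1:5)), 1),
               "at least 8")
})

test_that("ellipse pole and side curvatures match the closed forms", {
  ell <- make_contour("ellipse", a = 10, b = 3, n_points = 256)
  # pole a/b^2: window small against the curvature-variation scale
  expect_equal(osculating_curvature(ell, 1, arc_window = 0.4), 10 / 9,
               tolerance = 0.02)
  # side b/a^2 varies slowly; the default 2 um window is fine
  expect_equal(osculating_curvature(ell, 65, arc_window = 2), 3 / 100,
               tolerance = 0.02)
})

test_that("curvature estimates are invariant to rigid motion, scale as 1/s", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  base <- cbind(3 * cos(th) + 0.3 * cos(3 * th), 2.2 * sin(th))
  c1 <- nuclear_contour(base[, 1], base[, 2])
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- base %*% t(R) + matrix(c(5, -2), 128, 2, byrow = TRUE)
  c2 <- nuclear_contour(moved[, 1], moved[, 2])
  c3 <- nuclear_contour(2 * base[, 1], 2 * base[, 2])
  for (i in c(1, 20, 50, 100)) {
    k1 <- osculating_curvature(c1, i)
    expect_equal(osculating_curvature(c2, i), k1, tolerance = 1e-9)
    expect_equal(osculating_curvature(c3, i, arc_window = 4), k1 / 2,
                 tolerance = 1e-9)
  }
})

test_that("concave stretches carry negative sign", {
  # peanut-like closed contour: waist at theta = pi/2 is concave
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 3 + 1.8 * cos(2 * th)
  ct <- nuclear_contour(r * cos(th), r * sin(th))
  i_pole <- 1                       # theta 0: convex bulge
  i_waist <- which.min(abs(th - pi / 2))
  expect_gt(osculating_curvature(ct, i_pole, arc_window = 1), 0)
  expect_lt(osculating_curvature(ct, i_waist, arc_window = 1), 0)
})

test_that("curvature profiles sample at even arc spacing", {
  cc <- circle_contour(4, 256)
  prof <- curvature_profile(cc, spacing = cc$arc_length / 20)
  expect_identical(nrow(prof), 20L)
  expect_equal(prof$kappa_um_inv, rep(0.25, 20), tolerance = 1e-6)
  expect_true(all(prof$regime == "unset"))

  ell <- make_contour("ellipse", a = 10, b = 3, n_points = 256)
  pe <- curvature_profile(ell, spacing = ell$arc_length / 20,
                          arc_window = 0.6)
  expect_equal(max(pe$kappa_um_inv), 10 / 9, tolerance = 0.02)
  expect_equal(min(pe$kappa_um_inv), 3 / 100, tolerance = 0.02)

  expect_error(nuclear_contour(c(0, 1), c(0, 1), closed = FALSE),
               "at least 3")
})

test_that("regime classification partitions curvature with upward bounds", {
  thr <- c(0.3, 0.6)
  expect_identical(classify_regime(0.1, thr), "low")
  expect_identical(classify_regime(0.3, thr), "medium")
  expect_identical(classify_regime(0.6, thr), "high")
  expect_identical(classify_regime(1.0, thr), "high")
  expect_warning(out <- classify_regime(-0.2, thr), "concave")
  expect_identical(out, "low")
  expect_error(classify_regime(0.5, c(0.6, 0.3)), "low_hi < med_hi")
  # every finite kappa maps to exactly one regime
  withr::local_seed(1)
  k <- runif(500, 0, 2)
  reg <- classify_regime(k, thr)
  expect_true(all(reg %in% c("low", "medium", "high")))
  expect_identical(length(reg), 500L)
})

test_that("Gaussian sign distinguishes caps, saddles and cylinders", {
  expect_identical(gaussian_sign(0.5, 0.5), "positive")
  expect_identical(gaussian_sign(-0.5, -0.5), "positive")
  expect_identical(gaussian_sign(0.5, -0.2), "negative")
  expect_identical(gaussian_sign(0.5, 0), "parabolic")
})

test_that("pore curvature is twice the inverse diameter", {
  expect_equal(pore_curvature(8), 0.25)
  expect_equal(pore_curvature(3), 2 / 3)
  expect_identical(pore_curvature(2), 1)
  expect_error(pore_curvature(0), "positive")
  ps <- pore_spec(2.25)
  expect_identical(ps$curvature * ps$diameter_D, 2)
  expect_identical(ps$radius_Rpip, 1.125)
})

test_that("contours round-trip through CSV", {
  cc <- circle_contour(4, 64)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(cc, path)
  back <- read_contours_csv(path)[["1"]]
  expect_equal(back$points, cc$points, ignore_attr = TRUE)
  expect_error(read_contours_csv(write_fit_points(
    tibble::tibble(curvature_um_inv = 1, response = 1),
    withr::local_tempfile(fileext = ".csv"))), "x_um")
})
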