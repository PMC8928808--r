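test_that("parametric contours carry correct curvature metadata", {
  cc <- make_contour("circle", radius = 4, n_points = 64)
  expect_equal(attr(cc, "pole_curvature"), 0.25)
  expect_equal(osculating_curvature(cc, 5), 0.25, tolerance = 1e-6)
  ell <- make_contour("ellipse", a = 10, b = 3)
  expect_equal(attr(ell, "pole_curvature"), 10 / 9)
  expect_equal(attr(ell, "side_curvature"), 3 / 100)
  sp <- make_contour("spindle", pole_radius = 1, length = 12)
  expect_equal(attr(sp, "pole_curvature"), 1)
  expect_equal(sp$arc_length, 2 * pi + 2 * 10, tolerance = 1e-3)
  expect_error(make_contour("circle", radius = -1), "positive")
  expect_error(make_contour("spindle", pole_radius = 2, length = 3),
               "length > 2")
  expect_error(make_contour("circle", n_points = 16), "at least 32")
})

test_that("rendered profiles encode the detachment model exactly", {
  cfg <- generator_config(seed = 7, noise_sd = 0)
  sp <- make_contour("spindle", pole_radius = 1, length = 12,
                     n_points = 256)
  pr <- render_profiles(sp, cfg, strain_rate = 0.5)
  pd <- detach_probability(c(1, 0), cfg$filament)
  i_side <- which.min(abs(pr$laminB$distance_um - 6))
  expect_equal(pr$laminB$value[1] / pr$laminB$value[i_side],
               (1 - pd[1]) / (1 - pd[2]), tolerance = 1e-9)
  # below the critical rate lamin-A stays flat while lamin-B dilutes
  slow <- render_profiles(sp, cfg, strain_rate = 0.1)
  expect_equal(sd(slow$laminA$value), 0)
  expect_gt(max(slow$laminB$value) - min(slow$laminB$value), 0.5)
  # near-zero-curvature contour: flat profiles, phi ~ 0
  big <- make_contour("circle", radius = 20, n_points = 128)
  flat <- render_profiles(big, cfg, strain_rate = 0.1)
  expect_lt(sd(flat$laminB$value), 1e-9)
  tip <- mean(flat$laminB$value[flat$laminB$distance_um <= 1])
  inside <- mean(flat$laminB$value[flat$laminB$distance_um > 10])
  expect_equal(dilution_phi(inside, tip)$phi, 0, tolerance = 1e-9)
  expect_error(render_profiles(circle_contour(4), cfg), "metadata")
})

test_that("migration cohorts follow the independence structure", {
  cfg <- generator_config(seed = 3, pore_diameters = 4,
                          cells_per_pore = 5000)
  expect_identical(max(simulate_migration_cohort(cfg,
                                                 p_override = 0)$n_sites),
                   0L)
  expect_identical(min(simulate_migration_cohort(cfg,
                                                 p_override = 1)$n_sites),
                   3L)
  coh <- simulate_migration_cohort(cfg, p_override = 0.3)
  cd <- count_distribution(coh)
  # P(N >= 2) / P(N >= 1) estimates p1 under the chain model
  expect_equal((cd$fractions[["two"]] + cd$fractions[["three_plus"]]) /
                 cd$overall, 0.3, tolerance = 0.1)
  expect_true(all(vapply(coh$site_curvatures, length, integer(1)) ==
                    coh$n_sites))
  expect_true(all(unlist(coh$site_curvatures) == 0.5))  # 2/4
})

test_that("condition modifiers rescale the rupture probability", {
  cfg <- generator_config(seed = 5, pore_diameters = 3,
                          cells_per_pore = 4000)
  nt <- count_distribution(simulate_migration_cohort(cfg))$overall
  myo <- count_distribution(
    simulate_migration_cohort(cfg, condition = "myosin_inhibited"))$overall
  expect_equal(myo / nt, 0.5, tolerance = 0.12)
  hyp <- count_distribution(
    simulate_migration_cohort(cfg, condition = "hypotonic"))$overall
  expect_lt(hyp, nt)
})

test_that("aspiration traces obey the hinge and elastic laws", {
  cfg <- generator_config(seed = 7, noise_sd = 0)
  rates <- seq(0.05, 0.6, length.out = 30)
  tr <- simulate_aspiration(cfg, rates)
  expect_true(all(tr$projection_length_um ==
                    tr$rate_um_s * tr$time_s))
  phi <- aspiration_phi(tr, at_time = 60)
  slow <- phi[phi$rate_um_s < 0.2, ]
  expect_true(all(abs(slow$phi[slow$channel == "laminA"]) < 1e-9))
  expect_true(all(slow$phi[slow$channel == "laminB"] > 0))
  # round trip: the estimator recovers the configured critical rate
  pa <- phi[phi$channel == "laminA", ]
  h <- estimate_critical_rate(pa$rate_um_s, pa$phi, "laminA")
  expect_equal(h$critical_rate, 0.2, tolerance = 1e-6)
  expect_equal(h$slope_c, 1, tolerance = 1e-6)
  # at long times lamin-A converges toward lamin-B regardless of rate
  late <- aspiration_phi(simulate_aspiration(cfg, 0.1,
                                             times = seq(0, 1200, 60)),
                         at_time = 1200)
  expect_equal(late$phi[late$channel == "laminA"],
               late$phi[late$channel == "laminB"], tolerance = 1e-6)
  # rate zero: no dilution at any time in any channel
  tr0 <- simulate_aspiration(cfg, 0)
  phi0 <- aspiration_phi(tr0, at_time = 120)
  expect_true(all(abs(phi0$phi) < 1e-9))
})

test_that("generators are byte-identical for a fixed config", {
  cfg <- generator_config(seed = 9, pore_diameters = c(3, 8),
                          cells_per_pore = 50)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(simulate_migration_cohort(cfg), f1)
  write_cohort_csv(simulate_migration_cohort(generator_config(
    seed = 9, pore_diameters = c(3, 8), cells_per_pore = 50)), f2)
  expect_identical(readLines(f1), readLines(f2))
  t1 <- simulate_aspiration(cfg, c(0.1, 0.4))
  t2 <- simulate_aspiration(cfg, c(0.1, 0.4))
  expect_identical(t1, t2)
})

test_that("end-to-end: sigmoid refit on a simulated cohort recovers truth", {
  cfg <- generator_config(seed = 17)
  coh <- simulate_migration_cohort(cfg)
  per <- dplyr::summarise(
    dplyr::group_by(coh, pore_diameter_um),
    k = pore_curvature(pore_diameter_um[1]),
    y = 100 * mean(n_sites >= 1), n = dplyr::n(), .groups = "drop")
  ft <- fit_sigmoid(per$k, per$y, n_trials = per$n)
  expect_equal(ft$amplitude_B, 102, tolerance = 0.15)
  expect_equal(ft$epsilon, 4, tolerance = 0.15)
  expect_equal(ft$alpha, 8, tolerance = 0.15)
})

test_that("manifests record config, seed and hash", {
  cfg <- generator_config(seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(cfg, path)
  m <- jsonlite::read_json(path)
  expect_identical(m$seed, 12L)
  expect_identical(m$package, "curvlamina")
  expect_true(nchar(m$config_hash) > 0)
  expect_equal(m$config$laminA_hinge$critical_rate, 0.2)
})
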