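test_that("count distributions partition the cohort", {
  rec <- data.frame(n_sites = c(rep(0, 7), 1, 1, 2))
  cd <- count_distribution(rec)
  expect_equal(unname(cd$fractions),  c(0.7, 0.2, 0.1, 0))
  expect_equal(cd$overall, 0.3)
  expect_identical(cd$n_cells, 10L)
  expect_equal(sum(cd$fractions), 1)
  cd0 <- count_distribution(data.frame(n_sites = rep(0, 5)))
  expect_equal(unname(cd0$fractions), c(1, 0, 0, 0))
  cd3 <- count_distribution(data.frame(n_sites = rep(3, 5)))
  expect_equal(unname(cd3$fractions[4]), 1)
  expect_error(count_distribution(data.frame(n_sites = integer(0))),
               "empty")
  # random cohorts always sum to exactly 1
  withr::local_seed(2)
  for (i in 1:20) {
    cd <- count_distribution(data.frame(n_sites = rpois(50, 1)))
    expect_identical(sum(cd$fractions), 1)
  }
})

test_that("independence prediction is p1^k with the chain property", {
  expect_equal(multisite_prediction(0.3, 2), 0.09)
  expect_equal(multisite_prediction(0.3, 1), 0.3)
  expect_equal(multisite_prediction(0.5, 3), 0.125)
  expect_error(multisite_prediction(1.2, 2), "0, 1")
  expect_error(multisite_prediction(0.3, 0), "positive integer")
  withr::local_seed(4)
  for (i in 1:20) {
    p1 <- runif(1)
    k <- sample(1:5, 1)
    expect_equal(multisite_prediction(p1, k + 1),
                 p1 * multisite_prediction(p1, k), tolerance = 1e-12)
    if (p1 < 1) {
      expect_true(all(diff(multisite_prediction(p1, 1:4)) <= 0))
    }
  }
})

test_that("independence test keeps size under the null and rejects misfit", {
  withr::local_seed(11)
  pv <- vapply(1:100, function(i) {
    independence_test(data.frame(n_sites = draw_null_sites(100, 0.3)),
                      0.3)$p_value
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.90)
  # every ruptured cell with exactly 3 sites is gross misfit to p1 = 0.3
  bad <- data.frame(n_sites = rep(c(0, 3), c(40, 40)))
  expect_lt(independence_test(bad, 0.3)$p_value, 0.01)
  # degenerate p1 with conforming / nonconforming data
  ok0 <- independence_test(data.frame(n_sites = rep(0, 30)), 0)
  expect_identical(ok0$statistic, 0)
  expect_identical(ok0$p_value, 1)
  bad0 <- independence_test(data.frame(n_sites = c(rep(0, 29), 2)), 0)
  expect_identical(bad0$p_value, 0)
  expect_error(independence_test(data.frame(n_sites = rep(0, 10)), 0.3),
               "at least 20")
  # large cohorts switch to the chi-square route
  withr::local_seed(12)
  big <- independence_test(data.frame(n_sites = draw_null_sites(5000, 0.3)),
                           0.3)
  expect_identical(big$method, "chi-square")
  expect_gt(big$p_value, 0.001)
})

test_that("per-pore tests report Holm-adjusted p-values", {
  withr::local_seed(13)
  rec <- dplyr::bind_rows(lapply(c(0.25, 0.5, 0.889), function(k) {
    tibble::tibble(imposed_curvature = k,
                   n_sites = draw_null_sites(120, k / 2))
  }))
  out <- independence_test_by_pore(rec)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$p_adjusted >= out$p_value))
  expect_true(all(out$p_adjusted <= 1))
})

test_that("regime enrichment normalises rupture frequency by occupancy", {
  thr <- c(0.3, 0.6)
  # all ruptures in a high regime occupying 10% of the perimeter
  per <- c(runif(90, 0, 0.29), runif(10, 0.7, 1))
  withr::local_seed(21)
  enr <- regime_enrichment(runif(40, 0.7, 1), per, thr)
  expect_equal(enr$enrichment[enr$regime == "high"], 10)
  expect_equal(enr$enrichment[enr$regime == "low"], 0)
  expect_true(all(enr$flag[enr$perimeter_fraction == 0] == "undefined"))
  expect_true(is.na(enr$enrichment[enr$regime == "medium"]))
  # no ruptures: enrichment 0 where defined
  enr0 <- regime_enrichment(numeric(0), per, thr)
  expect_true(all(enr0$enrichment[enr0$perimeter_fraction > 0] == 0))
  expect_error(regime_enrichment(0.5, numeric(0), thr), "non-empty")
  # duplication of the perimeter list changes nothing: density matters
  withr::local_seed(22)
  per2 <- runif(500, 0, 1)
  rup <- sample(per2, 200, replace = TRUE)
  e1 <- regime_enrichment(rup, per2, thr)
  e2 <- regime_enrichment(rup, c(per2, per2), thr)
  expect_equal(e1$enrichment, e2$enrichment)
  expect_equal(e1$median_curvature, e2$median_curvature)
})

test_that("hinge fits recover slope and breakpoint", {
  r <- seq(0.05, 0.6, length.out = 12)
  h <- estimate_critical_rate(r, pmax(0, r - 0.2), "laminA")
  expect_equal(h$critical_rate, 0.2, tolerance = 1e-6)
  expect_equal(h$slope_c, 1, tolerance = 1e-6)
  expect_lt(h$residual_norm, 1e-6)
  # proportional data through the origin: elastic lamin-B-like case
  h0 <- estimate_critical_rate(r, 0.8 * r, "laminB")
  expect_equal(h0$critical_rate, 0, tolerance = 1e-9)
  expect_equal(h0$slope_c, 0.8, tolerance = 1e-9)
  # noisy recovery
  withr::local_seed(31)
  r30 <- seq(0.02, 0.6, length.out = 30)
  h2 <- estimate_critical_rate(r30, pmax(0, r30 - 0.2) +
                                 rnorm(30, sd = 0.05), "laminA")
  expect_equal(h2$critical_rate, 0.2, tolerance = 0.25)
  # no dilution at all
  hn <- estimate_critical_rate(r, rep(-0.02, 12), "laminA")
  expect_identical(hn$flag, "no dilution detected")
  expect_equal(hn$critical_rate, max(r))
  expect_error(estimate_critical_rate(c(0.1, 0.2, 0.3), c(0, 0, 0.1)),
               "at least 4")
})

test_that("cohorts round-trip through long-format CSV", {
  rec <- rupture_records(tibble::tibble(
    cell_id = sprintf("c%02d", 1:6),
    pore_diameter_um = c(3, 3, 3, 8, 8, 8),
    imposed_curvature = 2 / c(3, 3, 3, 8, 8, 8),
    n_sites = c(0L, 1L, 2L, 0L, 0L, 3L),
    site_curvatures = list(numeric(0), 2 / 3, rep(2 / 3, 2), numeric(0),
                           numeric(0), rep(0.25, 3)),
    condition = "untreated"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  back <- read_cohort_csv(path)
  expect_identical(nrow(back), 6L)
  expect_equal(sort(back$n_sites), sort(rec$n_sites))
  expect_equal(back$n_sites[back$cell_id == "c03"], 2L)
  expect_equal(back$site_curvatures[back$cell_id == "c06"][[1]],
               rep(0.25, 3))
  writeLines("cell_id,n_sites", path)
  expect_error(read_cohort_csv(path), "non-empty")
  expect_error(rupture_records(tibble::tibble(
    n_sites = 2L, site_curvatures = list(0.5))), "length")
})
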