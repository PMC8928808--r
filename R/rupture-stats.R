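# Cohort-level rupture statistics. Multi-site rupture counts on migrated
# nuclei are compared with the independence prediction P(N >= k) = p1^k
# (each additional rupture occurs with the same probability p1 given the
# previous ones); rupture-site curvatures are compared against perimeter
# curvature occupancy; dilution-versus-rate data are fit with a hinge law
# phi = c * max(0, rate - r_crit).

#' Rupture cohort records
#'
#' Construct/validate a cohort tibble with one row per migrated or aspirated
#' cell. Columns: `cell_id`, `imposed_curvature` (1/um; NA for 2-D culture),
#' `n_sites` (blebs/scars, >= 0), `condition` (one of `"untreated"`,
#' `"myosin_inhibited"`, `"hypotonic"`), and optionally `site_curvatures`
#' (list-column of per-site curvatures, length `n_sites`).
#'
#' @param records A data.frame/tibble with at least `n_sites`.
#' @return A validated tibble.
#' @export
rupture_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"n_sites" %in% names(records)) {
    stop("rupture records need an n_sites column", call. = FALSE)
  }
  if (any(records$n_sites < 0) || any(records$n_sites != round(records$n_sites))) {
    stop("n_sites must be non-negative integers", call. = FALSE)
  }
  if (!"cell_id" %in% names(records)) {
    records$cell_id <- sprintf("cell%04d", seq_len(nrow(records)))
  }
  if (!"condition" %in% names(records)) records$condition <- "untreated"
  if ("site_curvatures" %in% names(records)) {
    len <- vapply(records$site_curvatures, length, integer(1))
    if (any(len != records$n_sites)) {
      stop("site_curvatures length must equal n_sites", call. = FALSE)
    }
  }
  records
}

#' Distribution of rupture-site counts in a cohort
#'
#' Fractions of cells with 0, exactly 1, exactly 2 and 3-or-more rupture
#' sites (blebs/scars), plus the overall rupture fraction (any site). The
#' four class fractions sum to 1.
#'
#' @param records Cohort tibble (see [rupture_records()]).
#' @return A list with `fractions` (named: `zero`, `one`, `two`,
#'   `three_plus`), `overall` and `n_cells`.
#' @examples
#' rec <- rupture_records(data.frame(n_sites = c(rep(0, 7), 1, 1, 2)))
#' count_distribution(rec)$overall  # 0.3
#' @export
count_distribution <- function(records) {
  records <- rupture_records(records)
  n <- nrow(records)
  if (n == 0) stop("empty cohort", call. = FALSE)
  ns <- records$n_sites
  fr <- c(zero = mean(ns == 0), one = mean(ns == 1),
          two = mean(ns == 2), three_plus = mean(ns >= 3))
  list(fractions = fr, overall = unname(1 - fr["zero"]), n_cells = n)
}

#' Independence prediction for multi-site rupture
#'
#' If each rupture is an independent event with probability `p1`, the
#' predicted fraction of cells with at least `k` rupture sites is `p1^k`:
#' a k-th rupture occurs with probability `p1` given that k-1 already have.
#'
#' @param p1 Single-rupture probability in \[0, 1\].
#' @param k Number of rupture sites (integer >= 1, vectorised).
#' @return `p1^k`.
#' @examples
#' multisite_prediction(0.3, 2)  # 0.09
#' @export
multisite_prediction <- function(p1, k) {
  if (any(p1 < 0) || any(p1 > 1)) {
    stop("p1 must lie in [0, 1]", call. = FALSE)
  }
  if (any(k < 1) || any(k != round(k))) {
    stop("k must be a positive integer", call. = FALSE)
  }
  p1^k
}

# class probabilities {0, 1, 2, 3+} under P(N >= k) = p1^k
.independence_probs <- function(p1) {
  c(zero = 1 - p1, one = p1 - p1^2, two = p1^2 - p1^3, three_plus = p1^3)
}

# Exact multinomial goodness-of-fit p-value by likelihood ordering:
# P(outcomes with probability <= that of the observed table). Vectorised
# enumeration of compositions; feasible for <= 4 classes and n < 200.
.exact_multinomial_p <- function(obs, probs) {
  n <- sum(obs)
  m <- length(obs)
  comp <- function(n, m) {
    if (m == 1) return(matrix(n, ncol = 1))
    do.call(rbind, lapply(0:n, function(k) cbind(k, comp(n - k, m - 1))))
  }
  X <- comp(n, m)
  logp_terms <- function(x, p) {
    out <- x * log(p)
    out[x == 0] <- 0
    out[x > 0 & p == 0] <- -Inf
    out
  }
  lp <- lgamma(n + 1) - rowSums(lgamma(X + 1)) +
    rowSums(vapply(seq_len(m),
                   function(j) logp_terms(X[, j], probs[j]),
                   numeric(nrow(X))))
  lp_obs <- lgamma(n + 1) - sum(lgamma(obs + 1)) +
    sum(logp_terms(obs, probs))
  sum(exp(lp[lp <= lp_obs + 1e-9]))
}

#' Goodness-of-fit test of the rupture-independence model
#'
#' Tests observed rupture-site-count classes \{0, 1, 2, 3+\} against the
#' independence prediction `P(N >= k) = p1^k`. Classes with expected count
#' below 5 are pooled downward into their lower neighbour. For total counts
#' below 200 the p-value is an exact multinomial tail (likelihood ordering);
#' larger cohorts use Pearson's chi-square. The published analysis judged
#' agreement by overlaying `p1^k` curves on the data; this formal test is an
#' extension of that comparison.
#'
#' @param records Cohort tibble (see [rupture_records()]), >= 20 cells.
#' @param p1 Single-rupture probability of the independence model.
#' @return A list with `statistic` (Pearson X^2 on the pooled classes),
#'   `p_value`, `method`, and `classes` (tibble of class, observed,
#'   expected).
#' @export
independence_test <- function(records, p1) {
  records <- rupture_records(records)
  if (nrow(records) < 20) {
    stop("independence test needs a cohort of at least 20 cells",
         call. = FALSE)
  }
  if (p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]", call. = FALSE)
  ns <- records$n_sites
  obs <- c(zero = sum(ns == 0), one = sum(ns == 1),
           two = sum(ns == 2), three_plus = sum(ns >= 3))
  probs <- .independence_probs(p1)
  n <- sum(obs)

  classes <- tibble::tibble(class = names(obs), observed = as.integer(obs),
                            expected = n * probs)

  if (p1 %in% c(0, 1)) {
    conforming <- all(obs[probs == 0] == 0)
    return(list(statistic = if (conforming) 0 else Inf,
                p_value = if (conforming) 1 else 0,
                method = "degenerate", classes = classes))
  }

  # pool sparse classes downward (3+ into 2, then into 1) until expected >= 5
  po <- obs
  pp <- probs
  while (length(po) > 2 && pp[length(pp)] * n < 5) {
    k <- length(po)
    po[k - 1] <- po[k - 1] + po[k]
    pp[k - 1] <- pp[k - 1] + pp[k]
    po <- po[-k]
    pp <- pp[-k]
  }
  expected <- n * pp
  statistic <- sum((po - expected)^2 / expected)
  if (n < 200) {
    p_value <- .exact_multinomial_p(po, pp)
    method <- "exact multinomial"
  } else {
    p_value <- stats::pchisq(statistic, df = length(po) - 1,
                             lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = statistic, p_value = min(1, p_value), method = method,
       classes = classes)
}

#' Independence tests across pore diameters with Holm correction
#'
#' Runs [independence_test()] separately for each imposed curvature (pore
#' diameter) in a cohort and applies a Holm multiplicity adjustment across
#' the pores. By the published convention, `p1` defaults per pore to the
#' measured fraction of cells with exactly one bleb/scar.
#'
#' @param records Cohort tibble with an `imposed_curvature` column.
#' @param p1 Optional named vector of probabilities (names = curvature
#'   values); defaults to the per-pore one-site fraction.
#' @return Tibble with one row per pore: `imposed_curvature`, `n_cells`,
#'   `p1`, `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
independence_test_by_pore <- function(records, p1 = NULL) {
  records <- rupture_records(records)
  if (!"imposed_curvature" %in% names(records)) {
    stop("records need an imposed_curvature column", call. = FALSE)
  }
  curvs <- sort(unique(records$imposed_curvature))
  rows <- lapply(curvs, function(kc) {
    sub <- records[records$imposed_curvature == kc, ]
    p <- if (is.null(p1)) mean(sub$n_sites == 1) else
      unname(p1[as.character(kc)])
    tst <- independence_test(sub, p)
    tibble::tibble(imposed_curvature = kc, n_cells = nrow(sub), p1 = p,
                   statistic = tst$statistic, p_value = tst$p_value,
                   method = tst$method)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "holm")
  out
}

#' Curvature-regime enrichment of rupture sites
#'
#' For each curvature regime (low/medium/high, see [classify_regime()]),
#' the frequency at which rupture-inducing curvatures fall in the regime is
#' normalised to the frequency at which that regime occurs along the nuclear
#' perimeter. Enrichment 1 means ruptures occur no more often than the
#' regime's perimeter occupancy predicts; the per-regime median perimeter
#' curvature is reported as the natural x-coordinate for plots. Enrichment
#' depends only on the perimeter curvature distribution, not on how many
#' perimeter samples were taken.
#'
#' @param rupture_curvatures Curvatures at rupture sites, 1/um (may be
#'   empty: all enrichments are then 0).
#' @param perimeter_curvatures Curvature samples along nuclear perimeters,
#'   1/um (non-empty).
#' @param thresholds Regime thresholds `c(low_hi, med_hi)`.
#' @return Tibble with columns `regime`, `n_ruptures`, `rupture_fraction`,
#'   `perimeter_fraction`, `enrichment` (NA and `flag = "undefined"` for
#'   regimes with zero perimeter occupancy) and `median_curvature`.
#' @export
regime_enrichment <- function(rupture_curvatures, perimeter_curvatures,
                              thresholds) {
  if (length(perimeter_curvatures) == 0) {
    stop("perimeter curvature samples must be non-empty", call. = FALSE)
  }
  lev <- c("low", "medium", "high")
  per_reg <- factor(classify_regime(perimeter_curvatures, thresholds), lev)
  rup_reg <- factor(classify_regime(rupture_curvatures, thresholds), lev)
  per_frac <- as.numeric(table(per_reg)) / length(perimeter_curvatures)
  n_rup <- as.numeric(table(rup_reg))
  rup_frac <- if (length(rupture_curvatures) == 0) rep(0, 3) else
    n_rup / length(rupture_curvatures)
  enr <- ifelse(per_frac > 0, rup_frac / per_frac, NA_real_)
  med <- vapply(lev, function(r) {
    v <- perimeter_curvatures[per_reg == r]
    if (length(v) == 0) NA_real_ else median(v)
  }, numeric(1))
  tibble::tibble(regime = lev, n_ruptures = as.integer(n_rup),
                 rupture_fraction = rup_frac, perimeter_fraction = per_frac,
                 enrichment = enr,
                 flag = ifelse(per_frac > 0, "", "undefined"),
                 median_curvature = unname(med))
}

#' Hinge fit of dilution versus strain rate
#'
#' Fits `phi = c * max(0, rate - r_crit)`: lamin-A behaves as a viscous
#' layer that only flows, and hence dilutes at the nuclear tip, above a
#' critical extension rate; lamin-B (elastic, membrane-bound) dilutes in
#' proportion to rate from rate zero, so its fitted `r_crit` is ~0. The
#' breakpoint is found by a deterministic coarse grid over the observed rate
#' range (the slope has a closed-form solution at fixed breakpoint) refined
#' by local optimisation, which avoids the local minima of the piecewise
#' objective.
#'
#' @param rate Nuclear extension rates dL/t, um/s (>= 4 values spanning the
#'   putative hinge).
#' @param phi Dilution measures (see [dilution_phi()]), same length.
#' @param channel Channel label carried into the fit.
#' @return An object of class `hinge_fit`: `slope_c` (dilution per um/s),
#'   `critical_rate` (um/s), `channel`, `residual_norm`, `flag`
#'   (`"no dilution detected"` when all phi <= 0), `n_points`.
#' @examples
#' r <- seq(0.05, 0.6, length.out = 12)
#' estimate_critical_rate(r, pmax(0, r - 0.2), "laminA")
#' @export
estimate_critical_rate <- function(rate, phi,
                                   channel = c("laminA", "laminB", "DNA")) {
  channel <- match.arg(channel)
  stopifnot(length(rate) == length(phi))
  keep <- is.finite(rate) & is.finite(phi)
  rate <- rate[keep]
  phi <- phi[keep]
  if (length(rate) < 4) {
    stop("hinge fit needs at least 4 (rate, phi) pairs", call. = FALSE)
  }
  mk_fit <- function(slope, rc, flag = "") {
    pred <- slope * pmax(0, rate - rc)
    denom <- sqrt(sum(phi^2))
    structure(list(slope_c = slope, critical_rate = rc, channel = channel,
                   residual_norm = if (denom == 0) 0 else
                     sqrt(sum((phi - pred)^2)) / denom,
                   flag = flag, n_points = length(rate)),
              class = "hinge_fit")
  }
  if (all(phi <= 0)) {
    return(mk_fit(0, max(rate), flag = "no dilution detected"))
  }
  rss_at <- function(rc) {
    h <- pmax(0, rate - rc)
    s2 <- sum(h^2)
    if (s2 == 0) return(c(rss = sum(phi^2), slope = 0))
    slope <- sum(phi * h) / s2
    c(rss = sum((phi - slope * h)^2), slope = slope)
  }
  grid <- seq(0, max(rate) * (1 - 1e-9), length.out = 201)
  rss <- vapply(grid, function(g) rss_at(g)["rss"], numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(g) rss_at(g)["rss"], c(lo, hi),
                  tol = .Machine$double.eps^0.5)
  # keep whichever of grid optimum / refined optimum is better
  rc <- if (opt$objective <= rss[i]) opt$minimum else grid[i]
  res <- rss_at(rc)
  mk_fit(unname(res["slope"]), rc)
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat(sprintf(
    "Hinge fit (%s): phi = %.4g * max(0, rate - %.4g um/s)%s\n",
    x$channel, x$slope_c, x$critical_rate,
    if (nzchar(x$flag)) paste0("  [", x$flag, "]") else ""))
  cat(sprintf("  residual norm = %.3g over %d points\n",
              x$residual_norm, x$n_points))
  invisible(x)
}

#' Rupture cohort CSV round trips
#'
#' Long-format cohort CSV: columns `cell_id`, `pore_diameter_um`,
#' `n_sites`, `condition`, optional `site_curvature_um_inv` (one row per
#' site; cells with zero sites keep one row with NA).
#'
#' @param records Cohort tibble from [rupture_records()] /
#'   [simulate_migration_cohort()].
#' @param path File path.
#' @return `read_cohort_csv()` returns a cohort tibble (one row per cell,
#'   `site_curvatures` as a list-column); the writer returns `path`
#'   invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_cohort_csv <- function(records, path) {
  records <- rupture_records(records)
  has_sites <- "site_curvatures" %in% names(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sc <- if (has_sites && r$n_sites[[1]] > 0) unlist(r$site_curvatures)
          else NA_real_
    tibble::tibble(cell_id = r$cell_id,
                   pore_diameter_um = if ("pore_diameter_um" %in% names(r))
                     r$pore_diameter_um else NA_real_,
                   n_sites = r$n_sites, condition = r$condition,
                   site_curvature_um_inv = sc)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "n_sites")
  if (nrow(df) == 0 || !all(need %in% names(df))) {
    stop("cohort CSV must be non-empty with columns cell_id, n_sites",
         call. = FALSE)
  }
  grouped <- dplyr::group_by(df, .data$cell_id)
  out <- dplyr::summarise(
    grouped,
    pore_diameter_um = if ("pore_diameter_um" %in% names(df))
      dplyr::first(.data$pore_diameter_um) else NA_real_,
    n_sites = dplyr::first(.data$n_sites),
    condition = if ("condition" %in% names(df))
      dplyr::first(.data$condition) else "untreated",
    site_curvatures = if ("site_curvature_um_inv" %in% names(df))
      list(stats::na.omit(.data$site_curvature_um_inv)) else list(numeric(0)),
    .groups = "drop")
  out$site_curvatures <- lapply(out$site_curvatures, as.numeric)
  # tolerate cohorts without recorded site curvatures
  len <- vapply(out$site_curvatures, length, integer(1))
  if (all(len == 0)) out$site_curvatures <- NULL
  if ("imposed_curvature" %in% names(df)) {
    out$imposed_curvature <- df$imposed_curvature[match(out$cell_id, df$cell_id)]
  } else if (!all(is.na(out$pore_diameter_um))) {
    out$imposed_curvature <- ifelse(is.na(out$pore_diameter_um), NA_real_,
                                    2 / out$pore_diameter_um)
  }
  rupture_records(out)
}
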