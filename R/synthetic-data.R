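# Seeded generators that emulate every input class the analysis consumes:
# parametric nuclear contours with known pole curvature, intensity profiles
# rendered from the detachment model, migration cohorts with
# P(N >= k) = p^k multi-site structure, and aspiration traces obeying the
# lamin-A hinge law. All randomness flows from GeneratorConfig$seed, so a
# fixed config reproduces outputs byte for byte.

#' Synthetic-data generator configuration
#'
#' Collects the model constants and cohort settings used by all generators.
#' Defaults encode the study conditions the generators emulate: six pore
#' diameters spanning 2.25-8 um (curvatures 0.25-0.89 1/um), 500 cells per
#' pore, a percent-scale sigmoid amplitude B = 102 with midpoint
#' eps/alpha = 0.5 1/um (the pipette curvature, central in the pore range),
#' a lamin-A hinge with critical rate 0.2 um/s and unit slope, and additive
#' Gaussian intensity noise with sd 0.05.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param filament [filament_params()] used to render lamin-B dilution.
#' @param sigmoid [sigmoid_fit()] whose response (converted to a
#'   probability; divided by 100 when `B > 1`, i.e. percent scale) drives
#'   rupture simulation.
#' @param noise_sd Additive Gaussian intensity noise sd, a.u. (>= 0).
#'   Additive (not Poisson) because profiles emulate background-subtracted
#'   averages over many pixels.
#' @param laminA_hinge Named numeric `c(slope_c, critical_rate)`: dilution
#'   per (um/s) and critical extension rate (um/s).
#' @param laminB_rate_slope Lamin-B dilution per (um/s); lamin-B responds
#'   elastically, proportional to rate with no threshold.
#' @param pore_diameters Pore diameters, um.
#' @param cells_per_pore Cells per pore cohort.
#' @param candidate_rate_range `c(min, max)` aspiration rates, um/s.
#' @param relax_onset,relax_tau Long-time lamin-A relaxation: beyond
#'   `relax_onset` seconds the lamin-A dilution converges exponentially
#'   (time constant `relax_tau`, s) toward lamin-B's, emulating the
#'   observed slow creep; neither constant is experimentally quantified,
#'   they are explicit configuration.
#' @param myosin_p_factor Multiplier on rupture probability under myosin-II
#'   inhibition (default 0.5, an approximation knob for the roughly
#'   two-fold suppression, not a fitted constant).
#' @param hypotonic_p_factor Multiplier under hypotonic stress, standing in
#'   for its slowing of migration rate.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             filament = filament_params(4, 8),
                             sigmoid = sigmoid_fit(102, 4, 8, mode = "full"),
                             noise_sd = 0.05,
                             laminA_hinge = c(slope_c = 1, critical_rate = 0.2),
                             laminB_rate_slope = 1,
                             pore_diameters = c(2.25, 3, 4, 5, 6, 8),
                             cells_per_pore = 500L,
                             candidate_rate_range = c(0.05, 1),
                             relax_onset = 60, relax_tau = 60,
                             myosin_p_factor = 0.5,
                             hypotonic_p_factor = 0.7) {
  stopifnot(inherits(filament, "filament_params"),
            inherits(sigmoid, "sigmoid_fit"),
            noise_sd >= 0, length(laminA_hinge) == 2,
            all(pore_diameters > 0), cells_per_pore >= 1,
            candidate_rate_range[1] > 0,
            candidate_rate_range[2] >= candidate_rate_range[1])
  structure(list(seed = as.integer(seed), filament = filament,
                 sigmoid = sigmoid, noise_sd = noise_sd,
                 laminA_hinge = c(slope_c = unname(laminA_hinge[1]),
                                  critical_rate = unname(laminA_hinge[2])),
                 laminB_rate_slope = laminB_rate_slope,
                 pore_diameters = pore_diameters,
                 cells_per_pore = as.integer(cells_per_pore),
                 candidate_rate_range = candidate_rate_range,
                 relax_onset = relax_onset, relax_tau = relax_tau,
                 myosin_p_factor = myosin_p_factor,
                 hypotonic_p_factor = hypotonic_p_factor),
            class = "generator_config")
}

#' Parametric nuclear contour with known curvature
#'
#' Generates closed contours whose curvature is analytically known, for
#' validating the osculating-circle estimator and for rendering synthetic
#' intensity profiles: a circle (uniform curvature `1/r`), an ellipse (pole
#' curvature `a/b^2`, side curvature `b/a^2`), or a spindle - the stably
#' elongated nuclear shape of spindle-shaped clones - built as two circular
#' caps of given pole radius joined by straight (zero-curvature) sides.
#' The first contour point is always the pole at `(x_max, 0)` and analytic
#' per-point curvature is attached as metadata.
#'
#' @param shape `"circle"`, `"ellipse"` or `"spindle"`.
#' @param radius Circle radius, um.
#' @param a,b Ellipse semi-axes, um (a >= b for a pole on the x axis).
#' @param pole_radius Spindle cap radius, um.
#' @param length Spindle total length, um (> 2 * pole_radius).
#' @param n_points Number of contour points (>= 32).
#' @return A [nuclear_contour()] with attributes `pole_curvature`,
#'   `side_curvature` and `kappa_analytic` (per point, 1/um).
#' @examples
#' sp <- make_contour("spindle", pole_radius = 1, length = 12)
#' attr(sp, "pole_curvature")  # 1
#' @export
make_contour <- function(shape = c("circle", "ellipse", "spindle"),
                         radius = 4, a = 10, b = 3,
                         pole_radius = 1, length = 12, n_points = 128L) {
  shape <- match.arg(shape)
  n_points <- as.integer(n_points)
  if (n_points < 32) stop("n_points must be at least 32", call. = FALSE)
  if (shape == "circle") {
    if (radius <= 0) stop("radius must be positive", call. = FALSE)
    th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    ct <- nuclear_contour(radius * cos(th), radius * sin(th))
    attr(ct, "pole_curvature") <- 1 / radius
    attr(ct, "side_curvature") <- 1 / radius
    attr(ct, "kappa_analytic") <- rep(1 / radius, n_points)
  } else if (shape == "ellipse") {
    if (a <= 0 || b <= 0 || b > a) {
      stop("ellipse needs 0 < b <= a", call. = FALSE)
    }
    # equal arc-length sampling starting at the pole (theta = 0), so poles
    # and sides fall exactly on samples and spacing is uniform
    fine <- seq(0, 2 * pi, length.out = 20001)
    speed <- sqrt(a^2 * sin(fine)^2 + b^2 * cos(fine)^2)
    s_fine <- c(0, cumsum((speed[-1] + speed[-20001]) / 2 * diff(fine)))
    s_tgt <- seq(0, s_fine[20001], length.out = n_points + 1)[-(n_points + 1)]
    th <- stats::approx(s_fine, fine, xout = s_tgt)$y
    ct <- nuclear_contour(a * cos(th), b * sin(th))
    attr(ct, "pole_curvature") <- a / b^2
    attr(ct, "side_curvature") <- b / a^2
    attr(ct, "kappa_analytic") <-
      a * b / (a^2 * sin(th)^2 + b^2 * cos(th)^2)^1.5
  } else {
    r <- pole_radius
    if (r <= 0 || length <= 2 * r) {
      stop("spindle needs pole_radius > 0 and length > 2 * pole_radius",
           call. = FALSE)
    }
    side <- length - 2 * r
    cap_len <- pi * r
    total <- 2 * cap_len + 2 * side
    n_cap <- max(8L, round(n_points * cap_len / total))
    n_side <- max(4L, round(n_points * side / total))
    cx <- length / 2 - r
    # CCW from the right apex: upper right quarter-cap, top side, left cap,
    # bottom side, lower right quarter-cap
    th_ur <- seq(0, pi / 2, length.out = ceiling(n_cap / 2) + 1)
    top_x <- seq(cx, -cx, length.out = n_side + 1)[-1]
    th_l <- seq(pi / 2, 3 * pi / 2, length.out = n_cap + 1)[-1]
    bot_x <- seq(-cx, cx, length.out = n_side + 1)[-1]
    th_lr <- seq(-pi / 2, 0, length.out = ceiling(n_cap / 2) + 1)[-1]
    x <- c(cx + r * cos(th_ur), top_x, -cx + r * cos(th_l), bot_x,
           cx + r * cos(th_lr))
    y <- c(r * sin(th_ur), rep(r, base::length(top_x)), r * sin(th_l),
           rep(-r, base::length(bot_x)), r * sin(th_lr))
    kappa <- c(rep(1 / r, base::length(th_ur)),
               rep(0, base::length(top_x)),
               rep(1 / r, base::length(th_l)),
               rep(0, base::length(bot_x)),
               rep(1 / r, base::length(th_lr)))
    # drop the duplicated closing point if the lower cap lands on the apex
    if (x[base::length(x)] == x[1] && y[base::length(y)] == y[1]) {
      x <- x[-base::length(x)]
      y <- y[-base::length(y)]
      kappa <- kappa[-base::length(kappa)]
    }
    ct <- nuclear_contour(x, y)
    attr(ct, "pole_curvature") <- 1 / r
    attr(ct, "side_curvature") <- 0
    attr(ct, "kappa_analytic") <- kappa
  }
  ct
}

# hinge reduction factor in [0, 1] applied to the lamin-A channel
.hinge_factor <- function(rate, hinge) {
  pmin(1, hinge[["slope_c"]] * pmax(0, rate - hinge[["critical_rate"]]))
}

#' Render model intensity profiles along the major axis of a contour
#'
#' Produces per-channel intensity profiles from the pole (`distance 0`)
#' toward the nuclear centre, with values set by the detachment model:
#' lamin-B intensity is proportional to the attached fraction
#' `1 - P_detached(kappa)`; lamin-A is reduced by the same detachment shape
#' scaled by the hinge factor of the strain rate (zero reduction below the
#' critical rate); DNA mirrors lamin-B with independent noise. The mapping
#' from detachment probability to fractional intensity loss assumes simple
#' proportionality (single filament standing in for meshwork density).
#' Additive Gaussian noise (sd `config$noise_sd`) is applied, seeded.
#'
#' @param contour A contour from [make_contour()] (needs `kappa_analytic`).
#' @param config A [generator_config()].
#' @param strain_rate Imposed strain rate, um/s.
#' @return Named list of [intensity_profile()]s (`laminB`, `laminA`,
#'   `DNA`).
#' @export
render_profiles <- function(contour, config, strain_rate = 0) {
  stopifnot(inherits(contour, "nuclear_contour"),
            inherits(config, "generator_config"))
  kappa <- attr(contour, "kappa_analytic")
  if (is.null(kappa)) {
    stop("contour lacks analytic curvature metadata; use make_contour()",
         call. = FALSE)
  }
  pts <- contour$points
  upper <- pts[, 2] >= 0
  x <- pts[upper, 1]
  k <- pmax(0, kappa[upper])
  ord <- order(-x)
  x <- x[ord]
  k <- k[ord]
  dist <- x[1] - x
  inc <- c(TRUE, diff(dist) > 0)
  dist <- dist[inc]
  k <- k[inc]
  p_det <- detach_probability(k, config$filament)
  fA <- .hinge_factor(strain_rate, config$laminA_hinge)
  base <- list(laminB = 1 - p_det, laminA = 1 - fA * p_det,
               DNA = 1 - p_det)
  withr::with_seed(config$seed + 101L, {
    out <- lapply(names(base), function(ch) {
      v <- base[[ch]] + rnorm(length(dist), sd = config$noise_sd)
      intensity_profile(dist, pmax(0, v), channel = ch)
    })
  })
  names(out) <- names(base)
  out
}

#' Simulate a pore-migration rupture cohort
#'
#' For each pore diameter, the per-cell rupture probability is the sigmoid
#' response at the pore curvature `2/D`, converted to a probability (divided
#' by 100 when the amplitude is on the percent scale, i.e. `B > 1`). The
#' number of rupture sites per cell follows the independence model
#' `P(N >= k) = p^k` (sequential Bernoulli trials), capped at the `3+`
#' class; each site inherits the imposed pore curvature. Condition
#' modifiers rescale `p`: myosin inhibition by `myosin_p_factor`, hypotonic
#' stress by `hypotonic_p_factor`; a modified `p` outside \[0, 1\] is
#' clipped with a warning.
#'
#' @param config A [generator_config()].
#' @param condition `"untreated"`, `"myosin_inhibited"` or `"hypotonic"`.
#' @param p_override Optional fixed probability replacing the sigmoid for
#'   every pore (used for calibration studies).
#' @return A cohort tibble (see [rupture_records()]) with columns
#'   `cell_id`, `pore_diameter_um`, `imposed_curvature`, `n_sites`,
#'   `site_curvatures`, `condition`.
#' @export
simulate_migration_cohort <- function(config,
                                      condition = c("untreated",
                                                    "myosin_inhibited",
                                                    "hypotonic"),
                                      p_override = NULL) {
  stopifnot(inherits(config, "generator_config"))
  condition <- match.arg(condition)
  B <- config$sigmoid$amplitude_B
  percent_scale <- B > 1
  mod <- switch(condition, untreated = 1,
                myosin_inhibited = config$myosin_p_factor,
                hypotonic = config$hypotonic_p_factor)
  withr::with_seed(config$seed + 202L, {
    rows <- lapply(config$pore_diameters, function(D) {
      kappa <- pore_curvature(D)
      p <- if (!is.null(p_override)) p_override else {
        resp <- sigmoid_response(kappa, config$sigmoid)
        if (percent_scale) resp / 100 else resp
      }
      p <- p * mod
      if (p < 0 || p > 1) {
        warning(sprintf(
          "rupture probability %.3g outside [0, 1] after condition modifier; clipped",
          p))
        p <- min(1, max(0, p))
      }
      n <- config$cells_per_pore
      # sequential Bernoulli: N >= k iff the first k trials all succeed
      b <- matrix(runif(3 * n) < p, nrow = n)
      n_sites <- b[, 1] + (b[, 1] & b[, 2]) + (b[, 1] & b[, 2] & b[, 3])
      tibble::tibble(pore_diameter_um = D, imposed_curvature = kappa,
                     n_sites = as.integer(n_sites),
                     site_curvatures = lapply(n_sites, function(k)
                       rep(kappa, k)),
                     condition = condition)
    })
  })
  out <- dplyr::bind_rows(rows)
  out$cell_id <- sprintf("cell%05d", seq_len(nrow(out)))
  rupture_records(out)
}

#' Simulate micropipette aspiration traces
#'
#' Generates time courses of nuclear projection length and tip/inside
#' intensities for aspiration into a pipette of curvature 0.5 1/um at the
#' given rates. Projection length grows linearly, `dL = rate * t`. Lamin-B
#' tip dilution is instantaneous and proportional to rate (elastic
#' response); lamin-A follows the hinge law (no dilution below the critical
#' rate) until `relax_onset`, after which it relaxes exponentially (time
#' constant `relax_tau`) toward the lamin-B level, emulating the long-time
#' creep of the viscous lamin-A layer; DNA dilutes like lamin-B. Gaussian
#' noise (sd `config$noise_sd`) is added to intensities, seeded.
#'
#' @param config A [generator_config()].
#' @param rates Aspiration rates dL/t, um/s (>= 0; 0 produces a no-dilution
#'   control trace).
#' @param times Sampling times, s.
#' @param pressure_kPa Aspiration pressure recorded as metadata, kPa.
#' @return Tidy tibble: `trace_id`, `rate_um_s`, `time_s`,
#'   `projection_length_um`, `channel`, `tip_intensity`,
#'   `inside_intensity`, `pipette_curvature`, `pressure_kPa`.
#' @export
simulate_aspiration <- function(config, rates, times = seq(0, 120, by = 15),
                                pressure_kPa = 3) {
  stopifnot(inherits(config, "generator_config"), all(rates >= 0))
  hinge <- config$laminA_hinge
  withr::with_seed(config$seed + 303L, {
    rows <- lapply(seq_along(rates), function(i) {
      rate <- rates[i]
      phiB <- config$laminB_rate_slope * rate
      phiA0 <- hinge[["slope_c"]] * max(0, rate - hinge[["critical_rate"]])
      relax <- 1 - exp(-pmax(0, times - config$relax_onset) /
                         config$relax_tau)
      phi <- list(laminB = rep(phiB, length(times)),
                  laminA = phiA0 + (phiB - phiA0) * relax,
                  DNA = rep(phiB, length(times)))
      per_ch <- lapply(names(phi), function(ch) {
        inside <- 1 + rnorm(length(times), sd = config$noise_sd)
        tip <- 1 / (1 + phi[[ch]]) +
          rnorm(length(times), sd = config$noise_sd)
        tibble::tibble(trace_id = sprintf("trace%03d", i),
                       rate_um_s = rate, time_s = times,
                       projection_length_um = rate * times,
                       channel = ch,
                       tip_intensity = pmax(1e-6, tip),
                       inside_intensity = pmax(1e-6, inside),
                       pipette_curvature = 0.5,
                       pressure_kPa = pressure_kPa)
      })
      dplyr::bind_rows(per_ch)
    })
  })
  dplyr::bind_rows(rows)
}

#' Tip dilution phi from aspiration traces at a timepoint
#'
#' Computes `phi = inside/tip - 1` per trace and channel at the sampling
#' time closest to `at_time` (the experimental readout used t = 60 s).
#'
#' @param traces Tibble from [simulate_aspiration()] (or CSV round trip).
#' @param at_time Readout time, s.
#' @return Tibble: `trace_id`, `rate_um_s`, `channel`, `phi`.
#' @export
aspiration_phi <- function(traces, at_time = 60) {
  grouped <- dplyr::group_by(traces, .data$trace_id, .data$channel)
  dplyr::summarise(
    grouped,
    rate_um_s = dplyr::first(.data$rate_um_s),
    phi = {
      j <- which.min(abs(.data$time_s - at_time))
      .data$inside_intensity[j] / .data$tip_intensity[j] - 1
    },
    .groups = "drop")
}

#' Write a generator/run manifest
#'
#' Records the full configuration, seed, a config hash and the package
#' version next to generated outputs, for provenance.
#'
#' @param config A [generator_config()] (or any serialisable list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (!is.null(names(x))) return(as.list(x))  # keep names as JSON keys
    x
  }
  ser <- strip(config)
  obj <- list(config = ser, seed = config$seed,
              config_hash = rlang::hash(ser),
              package = "curvlamina",
              version = as.character(packageVersion("curvlamina")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Aspiration-trace CSV round trips
#'
#' @param traces Tibble from [simulate_aspiration()].
#' @param path File path.
#' @return `read_traces_csv()` returns the traces tibble; the writer
#'   returns `path` invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_traces_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("trace_id", "rate_um_s", "time_s", "channel",
            "tip_intensity", "inside_intensity")
  if (!all(need %in% names(df))) {
    stop("trace CSV missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}
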