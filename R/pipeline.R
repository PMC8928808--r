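# Orchestration: configuration, manifests and the simulate -> measure ->
# fit -> rupture-stats -> report chain over the CSV schemas the analysis
# modules read and write. A thin command-line wrapper over run_pipeline()
# ships in inst/scripts/lamina-pipeline.R.

#' Read a pipeline run configuration
#'
#' Run configuration is a hierarchical YAML file mirroring
#' [generator_config()] plus analysis thresholds; values given directly to
#' [run_pipeline()] override file values.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

# assemble a generator_config from the (possibly partial) config list
.build_generator <- function(cfg) {
  g <- cfg$generator %||% list()
  fil <- g$filament %||% list()
  sig <- g$sigmoid %||% list()
  eps <- sig$epsilon %||% cfg$eps %||% 4
  alp <- sig$alpha %||% cfg$alpha %||% 8
  generator_config(
    seed = cfg$seed %||% 1L,
    filament = filament_params(
      binding_energy_E = fil$binding_energy_E %||% eps,
      contact_coeff_a = fil$contact_coeff_a %||% alp),
    sigmoid = sigmoid_fit(sig$amplitude_B %||% 102, eps, alp,
                          mode = "full"),
    noise_sd = g$noise_sd %||% 0.05,
    laminA_hinge = c(slope_c = g$hinge_slope %||% 1,
                     critical_rate = g$critical_rate %||% 0.2),
    pore_diameters = unlist(g$pore_diameters %||%
                              c(2.25, 3, 4, 5, 6, 8)),
    cells_per_pore = g$cells_per_pore %||% 500L,
    candidate_rate_range = unlist(g$candidate_rate_range %||% c(0.05, 1)))
}

#' Run the analysis pipeline
#'
#' Executes one subcommand of the generation -> measurement -> fitting ->
#' reporting chain. Every run writes a `manifest.json` (configuration,
#' seed, config hash, package version) next to its outputs, and outputs are
#' deterministic for a fixed configuration and seed.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{Generate a migration cohort (`cohort.csv`), aspiration
#'     traces (`traces.csv`) and model intensity profiles (`profiles.csv`)
#'     from the generator configuration.}
#'   \item{measure}{Compute dilution measures: per-trace `phi` at the
#'     readout time from `traces.csv` (`measures.csv`).}
#'   \item{fit}{Fit the rupture-frequency sigmoid to per-pore rupture
#'     percentages from `cohort.csv` (`fit_points.csv`, `sigmoid_fit.json`).}
#'   \item{rupture-stats}{Per-pore count distributions and independence
#'     tests with Holm adjustment (`independence.csv`,
#'     `count_distribution.csv`).}
#'   \item{report}{Collect fit and test outputs into `summary.json` and
#'     diagnostic plots (`report.pdf`): response vs curvature with the
#'     fitted sigmoid, observed vs predicted multi-site fractions, and phi
#'     vs rate with the hinge fit.}
#' }
#'
#' @param config Named list (or result of [read_run_config()]) with at
#'   least `subcommand` and `out_dir`; `in_dir` defaults to `out_dir`.
#'   Optional entries: `seed`, `generator` (a list mirroring
#'   [generator_config()] fields),
#'   `eps`, `alpha`, `fit_mode`, `thresholds` (`c(low_hi, med_hi)`),
#'   `readout_time_s`.
#' @param ... Individual overrides merged over `config`.
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config = list(), ...) {
  config <- modifyList(config, list(...))
  sub <- config$subcommand %||% stop("config$subcommand is required",
                                     call. = FALSE)
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  in_dir <- config$in_dir %||% out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(
    sub,
    simulate = .pipe_simulate(config, out_dir),
    measure = .pipe_measure(config, in_dir, out_dir),
    fit = .pipe_fit(config, in_dir, out_dir),
    `rupture-stats` = .pipe_rupture_stats(config, in_dir, out_dir),
    report = .pipe_report(config, in_dir, out_dir),
    stop("unknown subcommand: ", sub, call. = FALSE))
  gen <- .build_generator(config)
  manifest <- file.path(out_dir, "manifest.json")
  write_manifest(gen, manifest)
  invisible(c(paths, manifest = manifest))
}

.pipe_simulate <- function(cfg, out_dir) {
  gen <- .build_generator(cfg)
  cohort <- simulate_migration_cohort(gen)
  rates <- seq(gen$candidate_rate_range[1], gen$candidate_rate_range[2],
               length.out = cfg$n_traces %||% 12)
  traces <- simulate_aspiration(gen, rates)
  profs <- render_profiles(make_contour("spindle", pole_radius = 1,
                                        length = 12, n_points = 256),
                           gen, strain_rate = 0.5)
  p <- c(cohort = file.path(out_dir, "cohort.csv"),
         traces = file.path(out_dir, "traces.csv"),
         profiles = file.path(out_dir, "profiles.csv"))
  write_cohort_csv(cohort, p[["cohort"]])
  write_traces_csv(traces, p[["traces"]])
  write_profiles_csv(profs, p[["profiles"]])
  p
}

.pipe_measure <- function(cfg, in_dir, out_dir) {
  traces <- read_traces_csv(file.path(in_dir, "traces.csv"))
  if (nrow(traces) == 0) stop("traces.csv contains no rows", call. = FALSE)
  phi <- aspiration_phi(traces, at_time = cfg$readout_time_s %||% 60)
  out <- file.path(out_dir, "measures.csv")
  readr::write_csv(phi, out)
  c(measures = out)
}

.pipe_fit <- function(cfg, in_dir, out_dir) {
  cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
  per_pore <- dplyr::summarise(
    dplyr::group_by(cohort, .data$pore_diameter_um),
    curvature_um_inv = pore_curvature(dplyr::first(.data$pore_diameter_um)),
    response = 100 * mean(.data$n_sites >= 1),
    n_trials = dplyr::n(), .groups = "drop")
  mode <- cfg$fit_mode %||% "full"
  fixed <- if (!is.null(cfg$eps) && !is.null(cfg$alpha))
    c(cfg$eps, cfg$alpha) else NULL
  fit <- fit_sigmoid(per_pore$curvature_um_inv, per_pore$response,
                     n_trials = per_pore$n_trials, mode = mode,
                     fixed_eps_alpha = fixed,
                     seed = cfg$seed %||% 1L)
  p <- c(points = file.path(out_dir, "fit_points.csv"),
         fit = file.path(out_dir, "sigmoid_fit.json"))
  write_fit_points(per_pore, p[["points"]])
  write_sigmoid_fit(fit, p[["fit"]])
  p
}

.pipe_rupture_stats <- function(cfg, in_dir, out_dir) {
  cohort <- read_cohort_csv(file.path(in_dir, "cohort.csv"))
  tests <- independence_test_by_pore(cohort)
  per_pore <- dplyr::group_by(cohort, .data$pore_diameter_um)
  counts <- dplyr::summarise(
    per_pore,
    n_cells = dplyr::n(),
    frac_zero = mean(.data$n_sites == 0),
    frac_one = mean(.data$n_sites == 1),
    frac_two = mean(.data$n_sites == 2),
    frac_three_plus = mean(.data$n_sites >= 3),
    overall = mean(.data$n_sites >= 1), .groups = "drop")
  p <- c(independence = file.path(out_dir, "independence.csv"),
         counts = file.path(out_dir, "count_distribution.csv"))
  readr::write_csv(tests, p[["independence"]])
  readr::write_csv(counts, p[["counts"]])
  p
}

.pipe_report <- function(cfg, in_dir, out_dir) {
  points <- read_fit_points(file.path(in_dir, "fit_points.csv"))
  fit <- read_sigmoid_fit(file.path(in_dir, "sigmoid_fit.json"))
  counts <- readr::read_csv(file.path(in_dir, "count_distribution.csv"),
                            show_col_types = FALSE)
  tests <- readr::read_csv(file.path(in_dir, "independence.csv"),
                           show_col_types = FALSE)
  measures <- file.path(in_dir, "measures.csv")
  phi <- if (file.exists(measures))
    readr::read_csv(measures, show_col_types = FALSE) else NULL

  summary <- list(
    sigmoid_fit = unclass(fit),
    per_pore = counts,
    independence = tests)

  hinge <- NULL
  if (!is.null(phi)) {
    phiA <- phi[phi$channel == "laminA", ]
    if (nrow(phiA) >= 4) {
      hinge <- estimate_critical_rate(phiA$rate_um_s, phiA$phi, "laminA")
      summary$laminA_hinge <- unclass(hinge)
    }
  }
  p_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  p_pdf <- file.path(out_dir, "report.pdf")
  grDevices::pdf(p_pdf, width = 6, height = 4.5)
  on.exit(grDevices::dev.off(), add = TRUE)
  xg <- seq(0, max(points$curvature_um_inv) * 1.1, length.out = 200)
  print(
    ggplot2::ggplot(points,
                    ggplot2::aes(x = .data$curvature_um_inv,
                                 y = .data$response)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_line(
        data = tibble::tibble(curvature_um_inv = xg,
                              response = sigmoid_response(xg, fit)),
        colour = "steelblue") +
      ggplot2::labs(x = "pore curvature (1/um)",
                    y = "% cells with rupture",
                    title = "Rupture frequency vs pore curvature") +
      ggplot2::theme_minimal())
  p1 <- counts$frac_one
  pred <- tibble::tibble(
    pore_diameter_um = rep(counts$pore_diameter_um, 2),
    class = rep(c("two", "three_plus"), each = nrow(counts)),
    observed = c(counts$frac_two, counts$frac_three_plus),
    predicted = c(counts$overall^2, counts$overall^3))
  print(
    ggplot2::ggplot(pred, ggplot2::aes(x = .data$observed,
                                       y = .data$predicted,
                                       colour = .data$class)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = "observed fraction", y = "independence prediction",
                    title = "Multi-site rupture vs P^k prediction") +
      ggplot2::theme_minimal())
  if (!is.null(hinge)) {
    phiA <- phi[phi$channel == "laminA", ]
    xr <- seq(0, max(phiA$rate_um_s), length.out = 100)
    print(
      ggplot2::ggplot(phiA, ggplot2::aes(x = .data$rate_um_s,
                                         y = .data$phi)) +
        ggplot2::geom_point() +
        ggplot2::geom_line(
          data = tibble::tibble(
            rate_um_s = xr,
            phi = hinge$slope_c * pmax(0, xr - hinge$critical_rate)),
          colour = "firebrick") +
        ggplot2::labs(x = "extension rate dL/t (um/s)",
                      y = "lamin-A dilution phi",
                      title = "Critical-rate hinge fit") +
        ggplot2::theme_minimal())
  }
  c(summary = p_json, report = p_pdf)
}
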