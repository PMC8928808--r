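# Intensity-derived statistics: min-max normalised line profiles from
# nuclear poles, pole-window means, lamin-B-to-A ratios, and the dilution
# measure phi used for aspirated nuclei and spindle-shaped nuclear poles.

#' Intensity line profile
#'
#' A line scan of fluorescence intensity versus distance from an origin at
#' a nuclear pole or aspirated tip, one channel per profile. Background is
#' assumed already subtracted where the measurement procedure requires it
#' (pipette measurements); the profile only records that note as metadata.
#'
#' @param distance_um Strictly increasing distances from the origin, um.
#' @param value Non-negative intensities (arbitrary units), same length
#'   (>= 2 samples).
#' @param channel One of `"laminA"`, `"laminB"`, `"DNA"`.
#' @param note Optional free-text metadata (e.g. line width used for pixel
#'   averaging).
#' @return An object of class `intensity_profile` (a tibble with attributes).
#' @export
intensity_profile <- function(distance_um, value,
                              channel = c("laminB", "laminA", "DNA"),
                              note = NULL) {
  channel <- match.arg(channel)
  stopifnot(length(distance_um) == length(value))
  if (length(value) < 2) {
    stop("an intensity profile needs at least 2 samples", call. = FALSE)
  }
  if (any(diff(distance_um) <= 0)) {
    stop("profile distances must be strictly increasing", call. = FALSE)
  }
  if (any(value < 0)) stop("intensities must be non-negative", call. = FALSE)
  out <- tibble::tibble(distance_um = as.numeric(distance_um),
                        value = as.numeric(value))
  attr(out, "channel") <- channel
  attr(out, "note") <- note
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Min-max normalise an intensity profile
#'
#' Maps intensities to `(v - min) / (max - min)`, the normalisation applied
#' to every experimental line profile before pole means are taken. Distances
#' are unchanged; the result attains 0 and 1. Invariant under affine
#' rescaling `v -> s v + c` (s > 0) of the raw profile.
#'
#' @param profile An [intensity_profile()].
#' @return The normalised [intensity_profile()].
#' @examples
#' p <- intensity_profile(0:2, c(0, 5, 10))
#' minmax_normalize(p)$value  # 0, 0.5, 1
#' @export
minmax_normalize <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  rng <- range(profile$value)
  if (rng[1] == rng[2]) {
    stop("cannot min-max normalise a constant profile", call. = FALSE)
  }
  profile$value <- (profile$value - rng[1]) / (rng[2] - rng[1])
  profile
}

# trapezoidal integral of y over x
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Mean intensity within a window of the pole
#'
#' Average intensity over the first `window` micrometres of a profile
#' (distance origin = the pole or tip). Averaging over a window rather than
#' taking a single-point value suppresses noise. The average is the
#' trapezoidal integral divided by the window width, which is robust to
#' non-uniform sampling; the profile is linearly interpolated at the window
#' boundary when no sample falls exactly there.
#'
#' @param profile An [intensity_profile()].
#' @param window Window width from the profile origin, um (> 0). Default
#'   1.0, the experimental choice.
#' @return Mean intensity (a.u.).
#' @examples
#' ramp <- intensity_profile(c(0, 2), c(0, 2))
#' pole_mean(ramp, window = 1)  # 0.5
#' @export
pole_mean <- function(profile, window = 1.0) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  d <- profile$distance_um
  v <- profile$value
  d0 <- d[1]
  hi <- d0 + window
  if (hi >= d[length(d)]) {
    if (hi > d[length(d)]) {
      warning("window extends beyond the profile; using the whole profile")
    }
    hi <- d[length(d)]
  }
  if (!any(d <= hi)) stop("no profile samples within the window",
                          call. = FALSE)
  inside <- d <= hi
  dd <- d[inside]
  vv <- v[inside]
  if (dd[length(dd)] < hi) {
    dd <- c(dd, hi)
    vv <- c(vv, stats::approx(d, v, xout = hi)$y)
  }
  if (length(dd) < 2) return(vv[1])
  .trapz(dd, vv) / (dd[length(dd)] - dd[1])
}

#' Lamin-B to lamin-A pole intensity ratio
#'
#' Ratio of pole-window mean lamin-B to lamin-A intensity, from two
#' min-max-normalised profiles sharing the same origin (a nuclear pole along
#' the major axis, or a nuclear side along the minor axis). Paired with a
#' curvature value upstream, these ratios trace the sigmoidal
#' curvature-response curve.
#'
#' @param profile_B,profile_A Min-max normalised [intensity_profile()]s
#'   (channels laminB and laminA).
#' @param window Pole window, um. Default 1.0.
#' @return Dimensionless ratio.
#' @export
laminB_to_A_ratio <- function(profile_B, profile_A, window = 1.0) {
  for (p in list(profile_B, profile_A)) {
    rng <- range(p$value)
    if (rng[1] < 0 || rng[2] > 1 + 1e-9) {
      warning("profile values outside [0, 1]; did you min-max normalise?")
    }
  }
  mA <- pole_mean(profile_A, window)
  if (mA == 0) {
    stop("lamin-A pole mean is zero; B/A ratio undefined", call. = FALSE)
  }
  pole_mean(profile_B, window) / mA
}

#' Dilution measure phi
#'
#' `phi = inside / tip - 1`, where `tip` is the mean background-subtracted
#' intensity at the leading tip of an aspirated nucleus (or a nuclear pole)
#' and `inside` the mean intensity of the interior (or nuclear centre).
#' `phi = 0` means no local depletion of the channel at the tip; `phi > 0`
#' means the tip is diluted. Measurement boxes approximate the pipette
#' radius squared for aspiration, or 2 x 2 um at spindle-nucleus poles.
#'
#' @param inside Interior/centre mean intensity, a.u. (background
#'   subtracted).
#' @param tip Tip/pole mean intensity, a.u. (> 0, background subtracted).
#' @param channel One of `"laminA"`, `"laminB"`, `"DNA"`.
#' @param geometry `"pipette_tip"` or `"spindle_pole"` (the latter maps
#'   centre -> inside and pole -> tip).
#' @return An object of class `dilution_measure`: list with `phi`,
#'   `tip_intensity`, `inside_intensity`, `channel`, `geometry`.
#' @examples
#' dilution_phi(1.5, 1.0)$phi  # 0.5: tip diluted
#' @export
dilution_phi <- function(inside, tip,
                         channel = c("laminB", "laminA", "DNA"),
                         geometry = c("pipette_tip", "spindle_pole")) {
  channel <- match.arg(channel)
  geometry <- match.arg(geometry)
  if (any(tip <= 0)) {
    stop("tip intensity must be positive to define phi", call. = FALSE)
  }
  structure(list(phi = inside / tip - 1, tip_intensity = tip,
                 inside_intensity = inside, channel = channel,
                 geometry = geometry),
            class = "dilution_measure")
}

#' Relative tip intensity
#'
#' `tip / inside`, the complementary way of reporting tip depletion
#' ("relative LMNB1"); algebraically `1 / (1 + phi)`.
#'
#' @param tip Tip mean intensity, a.u.
#' @param inside Interior mean intensity, a.u. (> 0).
#' @return Dimensionless ratio (vectorised).
#' @export
relative_tip_intensity <- function(tip, inside) {
  if (any(inside <= 0)) {
    stop("inside intensity must be positive", call. = FALSE)
  }
  tip / inside
}

#' Profile and dilution-measure CSV round trips
#'
#' Profile CSV columns: `distance_um`, `value`, `channel`, `cell_id`.
#' Dilution measures export as tidy CSV: `cell_id`, `channel`, `geometry`,
#' `phi`.
#'
#' @param path File path.
#' @return `read_profiles_csv()` returns a tibble (one row per sample);
#'   writers return `path` invisibly.
#' @name intensity_io
NULL

#' @param profiles Named list of [intensity_profile()]s, or a tibble already
#'   in the CSV schema.
#' @param cell_id Cell identifier recorded with each profile.
#' @rdname intensity_io
#' @export
write_profiles_csv <- function(profiles, path, cell_id = "cell1") {
  if (inherits(profiles, "data.frame")) {
    readr::write_csv(profiles, path)
    return(invisible(path))
  }
  rows <- lapply(profiles, function(p) {
    tibble::tibble(distance_um = p$distance_um, value = p$value,
                   channel = attr(p, "channel"), cell_id = cell_id)
  })
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' @rdname intensity_io
#' @export
read_profiles_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("distance_um", "value", "channel")
  if (!all(need %in% names(df))) {
    stop("profile CSV must have columns distance_um, value, channel",
         call. = FALSE)
  }
  if (!"cell_id" %in% names(df)) df$cell_id <- "cell1"
  df
}

#' @param measures List of `dilution_measure` objects or tibble with
#'   columns `cell_id`, `channel`, `geometry`, `phi`.
#' @rdname intensity_io
#' @export
write_measures_csv <- function(measures, path) {
  if (!inherits(measures, "data.frame")) {
    measures <- dplyr::bind_rows(lapply(measures, function(m) {
      tibble::tibble(cell_id = m$cell_id %||% NA_character_,
                     channel = m$channel, geometry = m$geometry,
                     phi = m$phi)
    }))
  }
  readr::write_csv(measures, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
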