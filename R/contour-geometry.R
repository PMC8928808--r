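# Curvature estimation on nuclear contours. The experimental procedure fits
# an osculating circle ("circle of best fit") over a 2 um stretch of the
# nuclear surface and reports 1/R; pore and pipette curvatures are the
# inverse of their radius. Contours are ordered 2-D point lists in um.

#' Nuclear contour
#'
#' An ordered list of boundary points (um). Closed contours are normalised
#' to counter-clockwise orientation so that the outward-convexity sign
#' convention of [osculating_curvature()] is well defined.
#'
#' @param x,y Numeric coordinate vectors (um), equal length.
#' @param closed Is the contour closed (a full perimeter)? Default TRUE.
#' @return An object of class `nuclear_contour` with fields `points`
#'   (n x 2 matrix), `closed`, `arc_length` (total, um) and `arc_pos`
#'   (per-vertex arc position, um).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- nuclear_contour(4 * cos(th), 4 * sin(th))
#' circ$arc_length  # ~ 2 pi 4
#' @export
nuclear_contour <- function(x, y, closed = TRUE) {
  stopifnot(length(x) == length(y))
  pts <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (nrow(pts) < 3) stop("a contour needs at least 3 points", call. = FALSE)
  if (any(!is.finite(pts))) stop("contour coordinates must be finite",
                                 call. = FALSE)
  seg <- diff(rbind(pts, if (closed) pts[1, , drop = FALSE]))
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0)) {
    stop("consecutive contour points must be distinct", call. = FALSE)
  }
  if (closed) {
    # shoelace signed area; reverse traversal if clockwise
    xs <- pts[, 1]; ys <- pts[, 2]
    area <- 0.5 * sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
    if (area < 0) {
      pts <- pts[c(1, nrow(pts):2), , drop = FALSE]
      seg <- diff(rbind(pts, pts[1, , drop = FALSE]))
      seglen <- sqrt(rowSums(seg^2))
    }
  }
  arc_pos <- c(0, cumsum(seglen))
  total <- arc_pos[length(arc_pos)]
  structure(list(points = pts, closed = closed,
                 arc_length = if (closed) total else arc_pos[nrow(pts)],
                 arc_pos = arc_pos[seq_len(nrow(pts))]),
            class = "nuclear_contour")
}

#' @export
print.nuclear_contour <- function(x, ...) {
  cat(sprintf("Nuclear contour: %d points, %s, arc length %.3g um\n",
              nrow(x$points), if (x$closed) "closed (CCW)" else "open",
              x$arc_length))
  invisible(x)
}

# Vertices within a centred arc window (total width `window`) around arc
# position s0, wrapping for closed contours. Returns an index vector in
# traversal order with the window's entry point first.
.window_indices <- function(contour, s0, window) {
  h <- window / 2
  s <- contour$arc_pos
  if (contour$closed) {
    L <- contour$arc_length
    d <- (s - s0) %% L
    d <- pmin(d, L - d) # circular arc distance
    idx <- which(d <= h + 1e-12)
    # order along traversal starting from the rear edge of the window
    rel <- ((s[idx] - s0 + h) %% L)
    idx[order(rel)]
  } else {
    which(abs(s - s0) <= h + 1e-12)
  }
}

# Algebraic (Kasa) circle fit, refined by one geometric Gauss-Newton step.
# Returns list(center, radius) or NULL when the points are collinear.
.fit_circle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  qrA <- qr(A)
  if (qrA$rank < 3) return(NULL)
  sol <- qr.coef(qrA, b)
  cx <- sol[1]; cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  r <- sqrt(r2)
  # one geometric refinement step on (cx, cy, r)
  for (it in 1) {
    dx <- u - cx; dy <- v - cy
    d <- sqrt(dx^2 + dy^2)
    if (any(d == 0)) break
    res <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, -res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  if (!is.finite(r) || r <= 0) return(NULL)
  list(center = c(cx + mx, cy + my), radius = r)
}

#' Osculating-circle curvature at a contour point
#'
#' Reproduces the osculating-circle measurement: a least-squares circle is
#' fitted to all contour points within an arc-length window (total width
#' `arc_window`, centred on the query point) and the signed curvature
#' `1/R` is returned. The sign is positive where the contour bulges outward
#' (convex, circle centre on the interior side) and negative at concave
#' sites; exactly straight stretches return 0 (infinite radius).
#'
#' For closed contours whose total arc length is shorter than twice the
#' requested window (very small nuclei), the window is clamped to half the
#' perimeter so the fit never wraps onto itself.
#'
#' @param contour A [nuclear_contour()].
#' @param index Vertex index (1-based) at which to evaluate.
#' @param arc_window Total arc-length extent of the fitting window, um.
#'   Default 2.0, the experimental choice; use a window small relative to
#'   the scale over which curvature varies when resolving sharp extrema.
#' @return Signed curvature in 1/um.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 129)[-129]
#' circ <- nuclear_contour(2 * cos(th), 2 * sin(th))
#' osculating_curvature(circ, 1)  # 0.5
#' @export
osculating_curvature <- function(contour, index, arc_window = 2.0) {
  stopifnot(inherits(contour, "nuclear_contour"))
  if (arc_window <= 0) stop("arc_window must be positive", call. = FALSE)
  if (nrow(contour$points) < 8) {
    stop("curvature estimation needs a contour with at least 8 points",
         call. = FALSE)
  }
  if (index < 1 || index > nrow(contour$points)) {
    stop("index out of range", call. = FALSE)
  }
  .curvature_at(contour, contour$arc_pos[index], arc_window)
}

# curvature at an arbitrary arc position (shared by osculating_curvature
# and curvature_profile)
.curvature_at <- function(contour, s0, arc_window) {
  if (contour$closed && arc_window > contour$arc_length / 2) {
    arc_window <- contour$arc_length / 2
  }
  if (!contour$closed && arc_window > contour$arc_length) {
    arc_window <- contour$arc_length
  }
  idx <- .window_indices(contour, s0, arc_window)
  if (length(idx) < 3) {
    stop(sprintf(
      "osculating window of %.3g um around arc position %.3g um contains %d point(s); need >= 3",
      arc_window, s0, length(idx)), call. = FALSE)
  }
  pts <- contour$points[idx, , drop = FALSE]
  fit <- .fit_circle(pts)
  if (is.null(fit) || fit$radius > 1e8) return(0)
  # sign: interior (left of CCW travel) side holds the centre where convex
  tangent <- pts[nrow(pts), ] - pts[1, ]
  tl <- sqrt(sum(tangent^2))
  if (tl == 0) return(0)
  normal <- c(-tangent[2], tangent[1]) / tl
  p0 <- pts[ceiling(nrow(pts) / 2), ]
  sgn <- if (sum((fit$center - p0) * normal) >= 0) 1 else -1
  sgn / fit$radius
}

#' Curvature profile along a contour
#'
#' Samples signed osculating-circle curvature at equal arc-length spacing
#' around a contour, emulating curvature measurement at ~20 locations around
#' the nuclear perimeter. Sampling starts at arc position 0 (the first
#' contour vertex), so contours built by [make_contour()] yield a sample
#' exactly at the pole.
#'
#' @inheritParams osculating_curvature
#' @param spacing Arc-length distance between samples, um (> 0).
#' @return A tibble with columns `arc_position_um`, `kappa_um_inv` and
#'   `regime` (initialised `"unset"`; see [classify_regime()]).
#' @export
curvature_profile <- function(contour, spacing, arc_window = 2.0) {
  stopifnot(inherits(contour, "nuclear_contour"))
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  L <- contour$arc_length
  s <- if (contour$closed) {
    seq(0, L - spacing / 2, by = spacing)
  } else {
    seq(0, L, by = spacing)
  }
  kappa <- vapply(s, function(si) .curvature_at(contour, si, arc_window),
                  numeric(1))
  tibble::tibble(arc_position_um = s, kappa_um_inv = kappa,
                 regime = "unset")
}

#' Classify curvature into low / medium / high regimes
#'
#' Partitions signed curvature by two thresholds; boundaries are assigned
#' upward (`kappa == low_hi` is medium, `kappa == med_hi` is high). The
#' regime boundaries are analysis configuration, not model constants.
#' Negative (concave/saddle) curvatures are classified `low` with a
#' warning, since the detachment model applies to positive Gaussian
#' curvature only.
#'
#' @param kappa Numeric curvature(s), 1/um.
#' @param thresholds Length-2 numeric `c(low_hi, med_hi)`, 0 < low_hi <
#'   med_hi.
#' @return Character vector in `c("low", "medium", "high")`.
#' @examples
#' classify_regime(c(0.1, 0.3, 1.0), c(0.3, 0.6))
#' @export
classify_regime <- function(kappa, thresholds) {
  if (length(thresholds) != 2 || thresholds[1] <= 0 ||
      thresholds[2] <= thresholds[1]) {
    stop("thresholds must satisfy 0 < low_hi < med_hi", call. = FALSE)
  }
  if (any(kappa < 0, na.rm = TRUE)) {
    warning("negative (concave) curvatures classified as 'low'; ",
            "the detachment model applies to positive Gaussian curvature")
  }
  out <- ifelse(kappa < thresholds[1], "low",
                ifelse(kappa < thresholds[2], "medium", "high"))
  out[kappa < 0] <- "low"
  out
}

#' Sign of the Gaussian curvature from two principal curvatures
#'
#' Gaussian curvature is the product of the two principal curvatures.
#' Rupture-prone sites (nuclear poles, pipette tips) have both principal
#' curvatures of the same sign (`"positive"`); the cusp where a pipette wall
#' meets the nuclear surface is a saddle (`"negative"`), where neither lamin
#' dilutes; a cylinder side with one zero principal curvature is
#' `"parabolic"`. A 2-D contour supplies only one principal curvature; the
#' second must be supplied (or assumed equal at a rotationally symmetric
#' pole).
#'
#' @param kappa1,kappa2 Principal curvatures, 1/um (vectorised).
#' @return Character vector in `c("positive", "negative", "parabolic")`.
#' @examples
#' gaussian_sign(0.5, 0.5)   # "positive" - pole/tip
#' gaussian_sign(0.5, -0.2)  # "negative" - pipette-wall cusp
#' @export
gaussian_sign <- function(kappa1, kappa2) {
  prod <- kappa1 * kappa2
  ifelse(prod > 0, "positive", ifelse(prod < 0, "negative", "parabolic"))
}

#' Curvature imposed by a pore or pipette
#'
#' The curvature imposed on a nucleus by a constricting pore or micropipette
#' is the inverse of the pore/pipette radius, i.e. `2 / diameter`.
#'
#' @param diameter Pore or pipette diameter, um (> 0; vectorised).
#' @return Curvature in 1/um.
#' @examples
#' pore_curvature(8)  # 0.25
#' pore_curvature(3)  # 0.667
#' @export
pore_curvature <- function(diameter) {
  if (any(diameter <= 0)) stop("pore diameter must be positive",
                               call. = FALSE)
  2 / diameter
}

#' Pore/pipette specification
#'
#' @param diameter_D Pore diameter, um (> 0).
#' @return A list with `diameter_D`, `radius_Rpip = D/2` and
#'   `curvature = 2/D` (so `curvature * diameter_D == 2` exactly).
#' @export
pore_spec <- function(diameter_D) {
  if (diameter_D <= 0) stop("pore diameter must be positive", call. = FALSE)
  structure(list(diameter_D = diameter_D, radius_Rpip = diameter_D / 2,
                 curvature = 2 / diameter_D),
            class = "pore_spec")
}

#' Contour and curvature CSV round trips
#'
#' Contour CSV has columns `x_um`, `y_um` and optional `contour_id`;
#' curvature CSV has `arc_position_um`, `kappa_um_inv`, `regime`.
#'
#' @param path File path.
#' @param contour A [nuclear_contour()] (single) for writing.
#' @param closed Passed to [nuclear_contour()] when reading.
#' @return `read_contours_csv()` returns a named list of contours (one per
#'   `contour_id`, `"1"` when absent); writers return `path` invisibly.
#' @name contour_io
NULL

#' @rdname contour_io
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "nuclear_contour"))
  readr::write_csv(tibble::tibble(x_um = contour$points[, 1],
                                  y_um = contour$points[, 2]), path)
  invisible(path)
}

#' @rdname contour_io
#' @export
read_contours_csv <- function(path, closed = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df))) {
    stop("contour CSV must have columns x_um, y_um", call. = FALSE)
  }
  if (!"contour_id" %in% names(df)) df$contour_id <- "1"
  ids <- unique(df$contour_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$contour_id == id, ]
    nuclear_contour(sub$x_um, sub$y_um, closed = closed)
  })
  names(out) <- as.character(ids)
  out
}

#' @param profile Curvature tibble from [curvature_profile()] for writing.
#' @rdname contour_io
#' @export
write_curvature_csv <- function(profile, path) {
  readr::write_csv(profile, path)
  invisible(path)
}
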