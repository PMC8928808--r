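# Least-squares fitting of the curvature-response sigmoid
# y = B / (1 + exp(eps - alpha x)). Two modes mirror how the model is used:
# B_only rescales a response curve whose shape (eps, alpha) was determined
# previously; full mode estimates all three parameters.

#' Fit the sigmoidal curvature-response model
#'
#' Fits `y = B / (1 + exp(epsilon - alpha * x))` to (curvature, response)
#' points by least squares.
#'
#' In `"B_only"` mode `epsilon` and `alpha` are fixed (they must be supplied
#' via `fixed_eps_alpha`; the model prints no default values) and the
#' amplitude has the closed-form weighted solution
#' `B = sum(w s y) / sum(w s^2)` with `s = 1/(1 + exp(eps - alpha x))`.
#'
#' In `"full"` mode all three parameters are estimated by
#' Levenberg-Marquardt nonlinear least squares
#' (\code{\link[minpack.lm]{nlsLM}}) from five deterministic multi-starts
#' with log-spaced initial `alpha`; the best residual wins, ties broken by
#' the smallest `alpha`. The fit is scale-equivariant in the response:
#' scaling all responses by `s > 0` scales the fitted `B` by `s` and leaves
#' `epsilon`, `alpha` unchanged.
#'
#' @param curvature Numeric vector of curvatures (1/um).
#' @param response Numeric vector of responses (probabilities, percentages,
#'   intensity ratios, ...), same length.
#' @param n_trials Optional per-point trial counts. When supplied, points are
#'   weighted proportionally to `n_trials` (binomial-style precision
#'   weighting); whether the original cohort fits were weighted is not
#'   documented, so both routes are exposed.
#' @param mode `"full"` (default) or `"B_only"`.
#' @param fixed_eps_alpha Length-2 numeric `c(epsilon, alpha)`; required in
#'   `"B_only"` mode, used as an extra start in `"full"` mode if given.
#' @param seed Integer seed; the multi-start schedule is deterministic given
#'   the data, the seed only perturbs starts on retry of degenerate fits.
#' @return A [sigmoid_fit()] object.
#' @examples
#' fit0 <- sigmoid_fit(50, 4, 8, mode = "full")
#' x <- c(0.25, 0.33, 0.4, 0.5, 0.67, 0.89)
#' y <- sigmoid_response(x, fit0)
#' fit_sigmoid(x, y)  # recovers B = 50, eps = 4, alpha = 8
#' @export
fit_sigmoid <- function(curvature, response, n_trials = NULL,
                        mode = c("full", "B_only"),
                        fixed_eps_alpha = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(curvature) == length(response))
  keep <- is.finite(curvature) & is.finite(response)
  x <- curvature[keep]
  y <- response[keep]
  w <- if (is.null(n_trials)) rep(1, length(x)) else as.numeric(n_trials[keep])
  if (any(w <= 0)) stop("n_trials must be positive", call. = FALSE)
  w <- w / mean(w)

  n_min <- if (mode == "B_only") 1L else 3L
  if (length(x) < n_min) {
    stop(sprintf("need at least %d finite points for %s-mode fitting",
                 n_min, mode), call. = FALSE)
  }

  resid_norm <- function(fitted) {
    denom <- sqrt(sum(w * y^2))
    if (denom == 0) return(0)
    sqrt(sum(w * (y - fitted)^2)) / denom
  }

  if (all(y == 0)) {
    ea <- if (is.null(fixed_eps_alpha)) c(0, 0) else fixed_eps_alpha
    return(sigmoid_fit(0, ea[1], ea[2], mode = mode, residual_norm = 0,
                       n_points = length(x)))
  }

  if (mode == "B_only") {
    if (is.null(fixed_eps_alpha) || length(fixed_eps_alpha) != 2) {
      stop("B_only mode requires fixed_eps_alpha = c(epsilon, alpha)",
           call. = FALSE)
    }
    eps <- fixed_eps_alpha[1]
    alpha <- fixed_eps_alpha[2]
    s <- 1 / (1 + exp(.clip_exp(eps - alpha * x)))
    B <- max(0, sum(w * s * y) / sum(w * s^2))
    return(sigmoid_fit(B, eps, alpha, mode = "B_only",
                       residual_norm = resid_norm(B * s),
                       n_points = length(x)))
  }

  # full mode: deterministic multi-starts with log-spaced alpha
  xspan <- max(abs(x))
  if (xspan == 0) stop("curvatures are all zero; cannot fit full mode",
                       call. = FALSE)
  alpha_starts <- 10^seq(-1, 2, length.out = 5) / xspan
  x_mid <- stats::weighted.mean(x, w * y) # crude half-rise location
  starts <- lapply(alpha_starts, function(a0) {
    list(B = max(y) * 1.05, eps = a0 * x_mid, alpha = a0)
  })
  if (!is.null(fixed_eps_alpha)) {
    starts <- c(starts, list(list(B = max(y) * 1.05,
                                  eps = fixed_eps_alpha[1],
                                  alpha = fixed_eps_alpha[2])))
  }

  df <- data.frame(x = x, y = y)
  fits <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ B / (1 + exp(pmin(pmax(eps - alpha * x, -700), 700))),
        data = df, start = st, weights = w,
        lower = c(B = 0, eps = -Inf, alpha = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("sigmoid fit failed to converge from all starts", call. = FALSE)
  }
  rss <- vapply(fits, function(f) sum(w * stats::resid(f)^2), numeric(1))
  alph <- vapply(fits, function(f) unname(coef(f)["alpha"]), numeric(1))
  # best residual; ties (within numerical noise) broken by smallest alpha
  best_rss <- min(rss)
  tol <- max(best_rss * 1e-8, 1e-300)
  cand <- which(rss <= best_rss + tol)
  best <- cand[which.min(alph[cand])]
  cf <- coef(fits[[best]])
  s <- 1 / (1 + exp(.clip_exp(cf["eps"] - cf["alpha"] * x)))
  sigmoid_fit(unname(cf["B"]), unname(cf["eps"]), unname(cf["alpha"]),
              mode = "full",
              residual_norm = resid_norm(unname(cf["B"]) * s),
              n_points = length(x))
}

#' Read and write sigmoid-fit inputs and results
#'
#' Fit inputs round-trip through CSV with columns `curvature_um_inv`,
#' `response` and optional `n_trials`; [sigmoid_fit()] objects round-trip
#' through JSON.
#'
#' @param path File path.
#' @return `read_fit_points()` returns a tibble; `read_sigmoid_fit()` a
#'   [sigmoid_fit()] object; the writers return `path` invisibly.
#' @name sigmoid_io
NULL

#' @param points Tibble/data.frame with columns `curvature_um_inv`,
#'   `response`, optional `n_trials`.
#' @rdname sigmoid_io
#' @export
write_fit_points <- function(points, path) {
  stopifnot(all(c("curvature_um_inv", "response") %in% names(points)))
  readr::write_csv(points, path)
  invisible(path)
}

#' @rdname sigmoid_io
#' @export
read_fit_points <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("curvature_um_inv", "response") %in% names(pts))) {
    stop("fit-points CSV must have columns curvature_um_inv, response",
         call. = FALSE)
  }
  pts
}

#' @param fit A [sigmoid_fit()] object.
#' @rdname sigmoid_io
#' @export
write_sigmoid_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname sigmoid_io
#' @export
read_sigmoid_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigmoid_fit(obj$amplitude_B, obj$epsilon, obj$alpha, mode = obj$mode,
              residual_norm = obj$residual_norm, n_points = obj$n_points)
}
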