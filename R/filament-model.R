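# Two-state Boltzmann model of a single lamin-B filament that is either
# attached to or detached from the inner nuclear membrane. The detached
# state is the reference (E_detached = 0); the attached-state energy rises
# with membrane curvature through a contact-area term and a bending term,
# so detachment probability is logistic in curvature. Energies are in kBT
# units throughout; temperature never appears explicitly.

#' Filament model parameters
#'
#' Bundle the energetic and geometric constants of the single-filament
#' detachment model. All energies are in units of kBT, lengths in um.
#'
#' @param binding_energy_E Binding energy `E` (kBT, >= 0) favouring filament
#'   attachment to a flat membrane.
#' @param contact_coeff_a Contact coefficient `a` (kBT um, >= 0) capturing the
#'   curvature-induced loss of filament-membrane contact area; contributes
#'   `a / R` to the attached-state energy.
#' @param bending_k Filament bending constant `k` (kBT um^2, >= 0),
#'   contributing `k / (2 R^2)`. If omitted it is derived as
#'   `persistence_length_lp * filament_length_Lfil`.
#' @param persistence_length_lp Filament persistence length (um, > 0).
#'   Lamin filaments have a median persistence length of about 0.5 um
#'   (up to ~3 um).
#' @param filament_length_Lfil In-situ filament length (um, > 0), about
#'   0.38 um.
#'
#' @return An object of class `filament_params`.
#' @examples
#' p <- filament_params(binding_energy_E = 4, contact_coeff_a = 8)
#' p$bending_k  # 0.5 * 0.38 = 0.19 kBT um^2
#' @seealso [bending_constant()], [detach_probability()]
#' @export
filament_params <- function(binding_energy_E,
                            contact_coeff_a,
                            bending_k = NULL,
                            persistence_length_lp = 0.5,
                            filament_length_Lfil = 0.38) {
  if (persistence_length_lp <= 0 || filament_length_Lfil <= 0) {
    stop("persistence length and filament length must be positive",
         call. = FALSE)
  }
  if (is.null(bending_k)) {
    bending_k <- bending_constant(persistence_length_lp, filament_length_Lfil)
  }
  fields <- c(binding_energy_E = binding_energy_E,
              contact_coeff_a = contact_coeff_a,
              bending_k = bending_k,
              persistence_length_lp = persistence_length_lp,
              filament_length_Lfil = filament_length_Lfil)
  if (any(!is.finite(fields)) || any(fields < 0)) {
    stop("all filament parameters must be finite and non-negative",
         call. = FALSE)
  }
  structure(as.list(fields), class = "filament_params")
}

#' @export
print.filament_params <- function(x, ...) {
  cat("Single-filament detachment model parameters (energies in kBT):\n")
  cat(sprintf("  binding energy E      = %.4g kBT\n", x$binding_energy_E))
  cat(sprintf("  contact coefficient a = %.4g kBT um\n", x$contact_coeff_a))
  cat(sprintf("  bending constant k    = %.4g kBT um^2 (lp = %.3g um, Lfil = %.3g um)\n",
              x$bending_k, x$persistence_length_lp, x$filament_length_Lfil))
  invisible(x)
}

#' Filament bending constant from persistence length
#'
#' The bending constant of a semiflexible filament confined to a curved
#' membrane is its bending stiffness `lp * kBT` integrated over the in-situ
#' filament length: `k = lp * Lfil` in units of kBT um^2. With the measured
#' lamin filament geometry (lp = 0.5 um, Lfil = 0.38 um) this gives
#' 0.19 kBT um^2.
#'
#' @param lp Persistence length in um (> 0).
#' @param Lfil In-situ filament length in um (> 0).
#' @return Bending constant in kBT um^2.
#' @examples
#' bending_constant(0.5, 0.38)  # 0.19
#' @export
bending_constant <- function(lp, Lfil) {
  if (any(lp <= 0) || any(Lfil <= 0)) {
    stop("persistence length and filament length must be positive",
         call. = FALSE)
  }
  lp * Lfil
}

#' Attached-state energy of a filament on a curved membrane
#'
#' Energy (kBT) of the attached state as a function of membrane curvature
#' `1/R`: `E_attached = -E + a * (1/R) + k/2 * (1/R)^2`. The detached state
#' has energy zero, so on a flat membrane attachment is favoured by `-E`;
#' the contact and bending terms raise the attached-state energy with
#' curvature.
#'
#' @param inv_R Curvature magnitude in 1/um (>= 0). Signed (Gaussian)
#'   classification of sites belongs upstream; see [gaussian_sign()].
#' @param params A [filament_params()] object.
#' @return Energy in kBT (vectorised over `inv_R`).
#' @examples
#' p <- filament_params(5, 10)
#' attached_energy(0, p)  # -5: flat-membrane limit
#' @export
attached_energy <- function(inv_R, params) {
  stopifnot(inherits(params, "filament_params"))
  if (any(inv_R < 0)) {
    stop("curvature magnitude inv_R must be non-negative", call. = FALSE)
  }
  -params$binding_energy_E + params$contact_coeff_a * inv_R +
    0.5 * params$bending_k * inv_R^2
}

# Exponent clip for the logistic: exp(+-700) is the double-precision edge;
# saturated probabilities (0 or 1) are physically meaningful limits.
.clip_exp <- function(x) pmin(pmax(x, -700), 700)

#' Probability that a filament is detached from the membrane
#'
#' Boltzmann two-state occupancy of the detached state:
#' `P_detached = 1 / (1 + exp(E - a * inv_R - k/2 * inv_R^2))`
#' (energies already in kBT). Monotone non-decreasing in curvature; tends to
#' `1/(1 + e^E)` (about 0 for E >> kBT) on a flat membrane and to 1 at high
#' curvature. The bending term has almost no effect at physiological
#' curvatures, so it can be dropped with `include_bending = FALSE`.
#'
#' @inheritParams attached_energy
#' @param include_bending Keep the `k/2 * inv_R^2` bending term? Default TRUE.
#' @return Detachment probability in (0, 1), vectorised over `inv_R`.
#' @examples
#' p <- filament_params(binding_energy_E = 4, contact_coeff_a = 8)
#' detach_probability(c(0, 0.5, 1), p)
#' @export
detach_probability <- function(inv_R, params, include_bending = TRUE) {
  stopifnot(inherits(params, "filament_params"))
  if (any(inv_R < 0)) {
    stop("curvature magnitude inv_R must be non-negative", call. = FALSE)
  }
  expo <- params$binding_energy_E - params$contact_coeff_a * inv_R
  if (include_bending) {
    expo <- expo - 0.5 * params$bending_k * inv_R^2
  }
  1 / (1 + exp(.clip_exp(expo)))
}

#' Sigmoid fit container
#'
#' Holds the parameters of the curvature-response sigmoid
#' `y = B / (1 + exp(epsilon - alpha * x))`: `B` is the amplitude
#' (asymptote, same units as the response), `epsilon` a binding energy (kBT)
#' and `alpha` an interaction energy per curvature (kBT um).
#'
#' @param amplitude_B Amplitude/asymptote (>= 0).
#' @param epsilon Binding energy (kBT).
#' @param alpha Interaction energy (kBT um).
#' @param mode `"B_only"` (epsilon, alpha fixed) or `"full"`.
#' @param residual_norm Dimensionless residual norm `||r|| / ||y||`.
#' @param n_points Number of fitted points.
#' @return An object of class `sigmoid_fit`.
#' @seealso [fit_sigmoid()], [sigmoid_response()]
#' @export
sigmoid_fit <- function(amplitude_B, epsilon, alpha,
                        mode = c("B_only", "full"),
                        residual_norm = NA_real_, n_points = NA_integer_) {
  mode <- match.arg(mode)
  if (!is.finite(amplitude_B) || amplitude_B < 0) {
    stop("amplitude_B must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(epsilon) || !is.finite(alpha)) {
    stop("epsilon and alpha must be finite", call. = FALSE)
  }
  structure(list(amplitude_B = amplitude_B, epsilon = epsilon, alpha = alpha,
                 mode = mode, residual_norm = residual_norm,
                 n_points = as.integer(n_points)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoidal curvature response y = B / (1 + exp(eps - alpha x))  [%s fit]\n",
    x$mode))
  cat(sprintf("  B = %.6g   eps = %.6g kBT   alpha = %.6g kBT um\n",
              x$amplitude_B, x$epsilon, x$alpha))
  cat(sprintf("  residual norm = %.3g over %d points\n",
              x$residual_norm, x$n_points))
  invisible(x)
}

#' Evaluate the sigmoidal curvature response
#'
#' `y(x) = B / (1 + exp(epsilon - alpha * x))`. With `B = 1`,
#' `epsilon = E` and `alpha = a` this is exactly [detach_probability()]
#' without the bending term; the asymptote as `x -> Inf` is `B` and the
#' half-maximum sits at `x = epsilon / alpha`.
#'
#' @param x Curvature in 1/um (vectorised).
#' @param fit A [sigmoid_fit()] object.
#' @return Response values, same units as the fitted amplitude.
#' @export
sigmoid_response <- function(x, fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  fit$amplitude_B / (1 + exp(.clip_exp(fit$epsilon - fit$alpha * x)))
}
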