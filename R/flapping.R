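#' Flapping-stroke kinematics
#'
#' The sinusoidal stroke of a wing or fin modelled as a thin plate:
#' amplitude `A` (half the peak-to-peak tip displacement, consistent with
#' the plate speed `V(t) = A * 2*pi*f * exp(i 2 pi f t)`), frequency `f`,
#' chord half-length `c` (the plate half-width) and span `L` (wing span or
#' fin length).
#'
#' @param A Stroke amplitude (m).
#' @param f Stroke frequency (Hz).
#' @param c Chord half-length (m).
#' @param L Span (m).
#' @return An object of class `flapping_kinematics`.
#' @examples
#' flapping_kinematics(A = 0.1, f = 2, c = 0.025, L = 0.3)
#' @export
flapping_kinematics <- function(A, f, c, L) {
  vals <- c(A = A, f = f, c = c, L = L)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("flapping kinematics A, f, c, L must all be positive", call. = FALSE)
  }
  structure(list(A = A, f = f, c = c, L = L), class = "flapping_kinematics")
}

#' Chord half-length from wing area
#'
#' Practical estimate when only planform data are tabulated: the mean
#' chord is wing area over span, and the plate half-width is half of that,
#' `c = area / span / 2`.
#'
#' @param area Wing (or fin) planform area (m^2).
#' @param span Wing span or fin length (m).
#' @return Chord half-length (m).
#' @export
chord_half_from_area <- function(area, span) {
  stopifnot(is.numeric(area), is.numeric(span))
  if (any(area <= 0) || any(span <= 0)) {
    stop("area and span must be positive", call. = FALSE)
  }
  area / span / 2
}

#' Thrust oscillation amplitude of a flapping plate
#'
#' A plate oscillating as `V(t) = A (2 pi f) exp(i 2 pi f t)` produces a
#' sinusoidal pressure force per unit span of amplitude
#' `rho * pi * c^2 * A * (2 pi f)^2` (the added mass times the peak
#' acceleration). The dimensional scaling form `rho c^2 A f^2` differs
#' from the full amplitude by the constant `4 pi^3`, returned explicitly.
#' The period-averaged force of a purely sinusoidal stroke is zero; real
#' strokes break up/down symmetry, absorbed into a fitted prefactor (see
#' [fit_prefactor()]), so no mean thrust is predicted from first
#' principles here.
#'
#' @param kin A [flapping_kinematics()] object.
#' @param rho Fluid density (kg/m^3).
#' @return A one-row tibble with `amplitude` (N/m), `scaling_form`
#'   (`rho c^2 A f^2`, N/m) and `constant` (`4 pi^3`).
#' @examples
#' thrust_amplitude_per_span(flapping_kinematics(1, 1, 1, 1), rho = 1)
#' @export
thrust_amplitude_per_span <- function(kin, rho) {
  stopifnot(inherits(kin, "flapping_kinematics"),
            is.numeric(rho), length(rho) == 1L, rho > 0)
  scaling <- rho * kin$c^2 * kin$A * kin$f^2
  tibble::tibble(amplitude = rho * pi * kin$c^2 * kin$A * (2 * pi * kin$f)^2,
                 scaling_form = scaling,
                 constant = 4 * pi^3)
}

#' Weight a flier must lift
#'
#' @param mass Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @return Weight (N), vectorised over `mass`.
#' @export
lift_required <- function(mass, g = 9.81) {
  stopifnot(is.numeric(mass), all(mass > 0), is.numeric(g), g > 0)
  mass * g
}

#' Predicted lift of a flapping flier
#'
#' The total flapping force over the wing scales as
#' `prefactor * rho * c^2 * A * f^2 * L`; for a cruising flier it balances
#' the weight `mass * g`. The prefactor absorbs the stroke asymmetry and
#' the `4 pi^3` constant and is fitted per group (bats and birds carry
#' different values, their flight having evolved independently).
#'
#' @param kin A [flapping_kinematics()] object.
#' @param rho Air density (kg/m^3).
#' @param prefactor Fitted dimensionless group constant.
#' @return Predicted lift force (N).
#' @seealso [fit_prefactor()] to estimate the prefactor from data.
#' @export
predicted_lift <- function(kin, rho = medium_air()$rho, prefactor = 1) {
  stopifnot(inherits(kin, "flapping_kinematics"),
            is.numeric(rho), rho > 0, is.numeric(prefactor), prefactor > 0)
  prefactor * rho * kin$c^2 * kin$A * kin$f^2 * kin$L
}

#' Lift-balance residual
#'
#' `predicted_lift - mass * g`: zero for a flier whose flapping exactly
#' supports its weight.
#'
#' @inheritParams predicted_lift
#' @param mass Body mass (kg).
#' @param g Gravitational acceleration (m/s^2).
#' @return Residual force (N).
#' @export
lift_balance_residual <- function(kin, mass, rho = medium_air()$rho,
                                  prefactor = 1, g = 9.81) {
  predicted_lift(kin, rho, prefactor) - lift_required(mass, g)
}

#' Swimming speed from thrust-drag balance
#'
#' Balancing the flapping thrust `rho c^2 A f^2 L` against drag gives the
#' cruise speed. In the form-drag regime (Reynolds number above a few
#' thousand) the balance yields `U = prefactor * f * sqrt(A c)`: speed
#' proportional to frequency times the geometric-mean stroke length. In
#' the skin-drag regime (small larvae) the Blasius drag gives
#' `U = prefactor * (A c)^(2/3) * f^(4/3) * L^(1/3) * nu^(-1/3)`.
#' `regime = "auto"` picks by the Reynolds number of the form-drag
#' estimate against `re_threshold`.
#'
#' @param kin A [flapping_kinematics()] object; its `L` is used as the
#'   body length unless `body_length` is given.
#' @param body_length Body length (m) for the Reynolds number.
#' @param medium A [fluid_medium()] or medium name.
#' @param regime `"form_drag"`, `"skin_drag"` or `"auto"`.
#' @param prefactor Dimensionless fitted constant (the inverse of the
#'   cruise Strouhal number in the form-drag regime).
#' @param re_threshold Reynolds number at which `"auto"` switches from
#'   skin to form drag. Default 5000.
#' @return A one-row tibble with `U_swim` (m/s), `Re`, `St` and the
#'   `regime` actually used.
#' @examples
#' kin <- flapping_kinematics(A = 0.1, f = 2, c = 0.025, L = 0.3)
#' swim_speed(kin, prefactor = 1 / 0.3)
#' @export
swim_speed <- function(kin, body_length = kin$L,
                       medium = medium_freshwater(),
                       regime = c("auto", "form_drag", "skin_drag"),
                       prefactor = 1, re_threshold = 5000) {
  stopifnot(inherits(kin, "flapping_kinematics"),
            is.numeric(body_length), length(body_length) == 1L,
            body_length > 0,
            is.numeric(prefactor), prefactor > 0)
  regime <- match.arg(regime)
  medium <- as_medium(medium)
  u_form <- prefactor * kin$f * sqrt(kin$A * kin$c)
  if (regime == "auto") {
    regime <- if (reynolds(u_form, body_length, medium$nu) >= re_threshold) {
      "form_drag"
    } else {
      "skin_drag"
    }
  }
  U <- if (regime == "form_drag") {
    u_form
  } else {
    prefactor * (kin$A * kin$c)^(2 / 3) * kin$f^(4 / 3) *
      body_length^(1 / 3) * medium$nu^(-1 / 3)
  }
  tibble::tibble(U_swim = U,
                 Re = reynolds(U, body_length, medium$nu),
                 St = strouhal(kin, U),
                 regime = regime)
}

#' Strouhal number of a flapping swimmer
#'
#' `St = f * sqrt(A c) / U`: the ratio of unsteady flapping inertia to
#' steady forward inertia, using the geometric-mean stroke length
#' `sqrt(A c)`. Cruising animals cluster around a common value.
#'
#' @param kin A [flapping_kinematics()] object.
#' @param U_swim Forward speed (m/s), positive.
#' @return Dimensionless Strouhal number.
#' @export
strouhal <- function(kin, U_swim) {
  stopifnot(inherits(kin, "flapping_kinematics"), is.numeric(U_swim))
  if (any(U_swim <= 0)) {
    stop("Strouhal number requires a positive swimming speed", call. = FALSE)
  }
  kin$f * sqrt(kin$A * kin$c) / U_swim
}

#' Reynolds number
#'
#' `Re = U L / nu`, with the body length as the characteristic length.
#'
#' @param U Speed (m/s).
#' @param L Body length (m).
#' @param nu Kinematic viscosity (m^2/s).
#' @return Dimensionless Reynolds number, vectorised.
#' @examples
#' reynolds(1, 0.1, 1e-6)  # 1e5
#' @export
reynolds <- function(U, L, nu) {
  stopifnot(is.numeric(U), is.numeric(L), is.numeric(nu))
  if (any(U <= 0) || any(L <= 0) || any(nu <= 0)) {
    stop("Reynolds number requires positive U, L, nu", call. = FALSE)
  }
  U * L / nu
}

#' Fit a group prefactor on the log-log scale
#'
#' Estimates the dimensionless prefactor of a power-law prediction
#' `observed = prefactor * predicted` by ordinary least squares on
#' `log10(observed)` vs `log10(predicted)`: the returned object's
#' prefactor is `10^intercept` and its slope should be near 1 when the
#' scaling holds. Used for the flier lift balance (observed weight vs
#' `rho c^2 A f^2 L`) and the swimmer speed law (observed speed vs
#' `f sqrt(A c)`).
#'
#' @param data A data frame.
#' @param observed,predicted Unquoted column names (tidy evaluation) of
#'   the observed quantity and the model's unscaled prediction.
#' @param mass_cutoff Optional: drop rows whose `mass` column is below
#'   this value before fitting (small fliers deviate from the balance).
#' @return A [loglog_fit()] object.
#' @examples
#' pop <- generate_population(population_spec("flier", n = 30, seed = 2,
#'                                            prefactor = 5))
#' fit <- fit_prefactor(pop, observed = weight,
#'                      predicted = rho_c2_A_f2_L(pop))
#' glance(fit)$prefactor  # ~5
#' @export
fit_prefactor <- function(data, observed, predicted, mass_cutoff = NULL) {
  stopifnot(is.data.frame(data))
  obs <- rlang::eval_tidy(rlang::enquo(observed), data)
  pred <- rlang::eval_tidy(rlang::enquo(predicted), data)
  if (!is.null(mass_cutoff)) {
    stopifnot("mass" %in% names(data))
    keep <- data$mass >= mass_cutoff
    obs <- obs[keep]
    pred <- pred[keep]
  }
  loglog_fit(pred, obs)
}

#' Flier thrust-scaling predictor column
#'
#' Convenience: `rho * chord_half^2 * A * f^2 * span` evaluated rowwise on
#' an animal table, the unscaled lift prediction the flier prefactor
#' multiplies.
#'
#' @param data A data frame with columns `chord_half`, `A`, `f`, `span`.
#' @param rho Air density (kg/m^3).
#' @return Numeric vector (N before the prefactor).
#' @export
rho_c2_A_f2_L <- function(data, rho = medium_air()$rho) {
  stopifnot(is.data.frame(data),
            all(c("chord_half", "A", "f", "span") %in% names(data)))
  rho * data$chord_half^2 * data$A * data$f^2 * data$span
}
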