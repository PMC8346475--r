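#' Prolate spheroid geometry
#'
#' A body of revolution with semi-major axis `a` along the symmetry axis
#' and semi-minor axis `b`, the shape all diving bodies are approximated
#' by. The eccentricity `e = sqrt(1 - b^2/a^2)` is derived; `a = b` is a
#' sphere (`e = 0`).
#'
#' @param a Semi-major axis (m), `a >= b`.
#' @param b Semi-minor axis (m), positive.
#' @return An object of class `spheroid_body` with fields `a`, `b`, `e`.
#' @examples
#' spheroid_body(a = 0.2, b = 0.1)$e  # 0.866
#' @export
spheroid_body <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) {
    stop("invalid geometry: need semi-axes a >= b > 0", call. = FALSE)
  }
  structure(list(a = a, b = b, e = sqrt(1 - b^2 / a^2)),
            class = "spheroid_body")
}

#' @export
print.spheroid_body <- function(x, ...) {
  cat(sprintf("<spheroid_body> a = %g m, b = %g m, e = %.4f\n", x$a, x$b, x$e))
  invisible(x)
}

#' Added mass of a 2D flat plate
#'
#' A thin plate of half-width `c` accelerating normal to itself carries an
#' added mass per unit span of `rho * pi * c^2`, the mass of the fluid
#' cylinder circumscribing the plate. This also equals
#' `rho * integral(phi_- - phi_+) dx / V`, the face-potential jump
#' integrated over the plate.
#'
#' @param c Plate half-width (m).
#' @param rho Fluid density (kg/m^3).
#' @return Added mass per unit span (kg/m).
#' @examples
#' plate_added_mass_2d(c = 1, rho = 1)  # pi
#' @export
plate_added_mass_2d <- function(c, rho) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0 ||
      !is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("invalid geometry: need c > 0 and rho > 0", call. = FALSE)
  }
  rho * pi * c^2
}

# Lamb's inertia coefficients for a prolate spheroid. The closed forms
#   alpha0 = [(1-e^2)/e^3] [ln((1+e)/(1-e)) - 2e]
#   beta0  = [(1-e^2)/e^3] [e/(1-e^2) - (1/2) ln((1+e)/(1-e))]
# are 0/0 at e = 0; below e = 0.05 their Maclaurin series (through e^8,
# truncation error < 1e-14 there) keep the sphere limit alpha0 = beta0 = 2/3
# exact and the two branches continuous to better than 1e-12.
lamb_alpha0 <- function(e) {
  small <- e < 0.05
  out <- numeric(length(e))
  if (any(small)) {
    e2 <- e[small]^2
    out[small] <- 2 / 3 - (4 / 15) * e2 - (4 / 35) * e2^2 -
      (4 / 63) * e2^3 - (4 / 99) * e2^4
  }
  if (any(!small)) {
    eb <- e[!small]
    out[!small] <- ((1 - eb^2) / eb^3) *
      ((log1p(eb) - log1p(-eb)) - 2 * eb)
  }
  out
}

lamb_beta0 <- function(e) {
  small <- e < 0.05
  out <- numeric(length(e))
  if (any(small)) {
    e2 <- e[small]^2
    out[small] <- 2 / 3 + (2 / 15) * e2 + (2 / 35) * e2^2 +
      (2 / 63) * e2^3 + (2 / 99) * e2^4
  }
  if (any(!small)) {
    eb <- e[!small]
    out[!small] <- ((1 - eb^2) / eb^3) *
      (eb / (1 - eb^2) - 0.5 * (log1p(eb) - log1p(-eb)))
  }
  out
}

#' Added-mass coefficients of a prolate spheroid
#'
#' Lamb's inertia coefficients `alpha0(e)` and `beta0(e)` and the derived
#' shape coefficients `K_axial = alpha0/(2 - alpha0)` and
#' `K_lateral = beta0/(2 - beta0)` for motion along the major and minor
#' axes. At `e = 0` (sphere) both equal 1/2; as the body elongates, axial
#' motion entrains ever less fluid while lateral motion entrains more, so
#' `K_lateral > K_axial` for every `e > 0`.
#'
#' @param body A [spheroid_body()], or a numeric eccentricity in `[0, 1)`.
#' @return A tibble with columns `e`, `alpha0`, `beta0`, `K_axial`,
#'   `K_lateral`.
#' @examples
#' spheroid_coefficients(spheroid_body(2, 1))  # K_axial ~ 0.210
#' @export
spheroid_coefficients <- function(body) {
  e <- if (inherits(body, "spheroid_body")) body$e else body
  stopifnot(is.numeric(e))
  if (any(e < 0 | e >= 1)) {
    stop("eccentricity must lie in [0, 1): e = 1 is a degenerate needle",
         call. = FALSE)
  }
  a0 <- lamb_alpha0(e)
  b0 <- lamb_beta0(e)
  tibble::tibble(e = e, alpha0 = a0, beta0 = b0,
                 K_axial = a0 / (2 - a0),
                 K_lateral = b0 / (2 - b0))
}

#' Added mass of a prolate spheroid
#'
#' `M_added = K_i * (4/3) * pi * rho * a * b^2`, where `K_i` is the axial
#' or lateral shape coefficient from [spheroid_coefficients()]. The sphere
#' limit is half the displaced fluid mass in either direction.
#'
#' @param body A [spheroid_body()].
#' @param rho Fluid density (kg/m^3).
#' @param direction `"axial"` (along the major axis) or `"lateral"`.
#' @return Added mass (kg).
#' @examples
#' spheroid_added_mass(spheroid_body(0.2, 0.1), rho = 1000, "axial")
#' @export
spheroid_added_mass <- function(body, rho, direction = c("axial", "lateral")) {
  stopifnot(inherits(body, "spheroid_body"),
            is.numeric(rho), length(rho) == 1L, rho > 0)
  direction <- match.arg(direction)
  co <- spheroid_coefficients(body)
  K <- if (direction == "axial") co$K_axial else co$K_lateral
  K * (4 / 3) * pi * rho * body$a * body$b^2
}

#' Added mass of an elliptical disc in broadside motion
#'
#' For a flat elliptical disc with semi-axes `a >= b` moving normal to its
#' plane, the shape coefficient is the reciprocal of the complete elliptic
#' integral of the second kind, `K = 1 / E(e)` with
#' `E(e) = integral_0^{pi/2} sqrt(1 - e^2 sin^2 th) dth`, applied to the
#' base `(4/3) * pi * rho * a * b^2`. The circular-disc limit `e = 0`
#' gives `K = 2/pi` and the classical `M = (8/3) rho a^3`.
#'
#' @param a Semi-major axis (m), `a >= b`.
#' @param b Semi-minor axis (m).
#' @param rho Fluid density (kg/m^3).
#' @return A tibble with columns `e`, `K`, `m_added`.
#' @examples
#' elliptical_disc_added_mass(a = 1, b = 1, rho = 1)$m_added  # 8/3
#' @export
elliptical_disc_added_mass <- function(a, b, rho) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      b <= 0 || a < b) {
    stop("invalid geometry: elliptical disc requires a >= b > 0", call. = FALSE)
  }
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0)
  e <- sqrt(1 - b^2 / a^2)
  # pracma::ellipke takes the parameter m = e^2 and returns E(m)
  E <- pracma::ellipke(e^2)$e
  K <- 1 / E
  tibble::tibble(e = e, K = K, m_added = K * (4 / 3) * pi * rho * a * b^2)
}

#' Added mass of a sphere
#'
#' Half the displaced fluid mass, `(2/3) * pi * rho * r^3`: the `e = 0`
#' limit of the prolate spheroid in either direction.
#'
#' @param r Radius (m).
#' @param rho Fluid density (kg/m^3).
#' @return Added mass (kg).
#' @export
sphere_added_mass <- function(r, rho) {
  stopifnot(is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0)
  spheroid_added_mass(spheroid_body(r, r), rho, "axial")
}
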