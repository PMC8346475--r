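#' Kinematic state of a moving thin plate
#'
#' Bundles the instantaneous state of a rigid thin plate of half-width `c`
#' translating normal to itself at speed `V`. The sign convention is an
#' upward `y` axis, so `V < 0` means downward motion. `dc_dt` and `dV_dt`
#' carry the time derivatives needed by the unsteady pressure terms; a
#' growing half-width (`dc_dt > 0`) is how water entry is modelled, the
#' wetted width increasing until the body's maximum section.
#'
#' @param c Plate half-width (m). Must be positive.
#' @param V Plate normal speed (m/s); negative is downward.
#' @param dc_dt Rate of change of the half-width (m/s). Default 0.
#' @param dV_dt Plate acceleration (m/s^2). Default 0.
#'
#' @return An object of class `plate_kinematics`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = -2)
#' pl$c
#' @export
plate_kinematics <- function(c, V, dc_dt = 0, dV_dt = 0) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("invalid geometry: plate half-width `c` must be a positive number",
         call. = FALSE)
  }
  stopifnot(is.numeric(V), length(V) == 1L,
            is.numeric(dc_dt), length(dc_dt) == 1L,
            is.numeric(dV_dt), length(dV_dt) == 1L)
  structure(list(c = c, V = V, dc_dt = dc_dt, dV_dt = dV_dt),
            class = "plate_kinematics")
}

#' @export
print.plate_kinematics <- function(x, ...) {
  cat(sprintf("<plate_kinematics> c = %g m, V = %g m/s, dc/dt = %g, dV/dt = %g\n",
              x$c, x$V, x$dc_dt, x$dV_dt))
  invisible(x)
}

#' Fluid properties
#'
#' Density, kinematic viscosity, reference pressure and gravity, with
#' presets for the three media the locomotion models use. Freshwater has
#' `nu = 1.00e-6` m^2/s and seawater `1.05e-6` m^2/s at 20 C; the densities
#' 1000 and 1025 kg/m^3 are the usual reference values.
#'
#' @param rho Density (kg/m^3).
#' @param nu Kinematic viscosity (m^2/s).
#' @param p0 Reference pressure (Pa): atmospheric for fliers, hydrostatic
#'   for submerged swimmers. Default 0 (only pressure differences matter).
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `fluid_medium`.
#' @examples
#' medium_seawater()$nu
#' @export
fluid_medium <- function(rho, nu, p0 = 0, g = 9.81) {
  stopifnot(is.numeric(rho), length(rho) == 1L, rho > 0,
            is.numeric(nu), length(nu) == 1L, nu > 0,
            is.numeric(p0), length(p0) == 1L,
            is.numeric(g), length(g) == 1L, g > 0)
  structure(list(rho = rho, nu = nu, p0 = p0, g = g), class = "fluid_medium")
}

#' @rdname fluid_medium
#' @export
medium_freshwater <- function() fluid_medium(rho = 1000, nu = 1.00e-6)

#' @rdname fluid_medium
#' @export
medium_seawater <- function() fluid_medium(rho = 1025, nu = 1.05e-6)

#' @rdname fluid_medium
#' @export
medium_air <- function() fluid_medium(rho = 1.225, nu = 1.5e-5)

as_medium <- function(medium) {
  if (inherits(medium, "fluid_medium")) return(medium)
  if (is.character(medium) && length(medium) == 1L) {
    return(switch(medium,
                  freshwater = medium_freshwater(),
                  seawater   = medium_seawater(),
                  air        = medium_air(),
                  stop("unknown medium: ", medium, call. = FALSE)))
  }
  stop("`medium` must be a fluid_medium or one of 'freshwater', 'seawater', 'air'",
       call. = FALSE)
}

# Branch of (z^2 - c^2)^(1/2) as the product of the principal square roots
# of (z - c) and (z + c). This places the only branch cut on the plate
# segment [-c, c] itself: in elliptical coordinates z - c = r1 e^{i th1},
# z + c = r2 e^{i th2} with th in (-pi, pi], it equals
# sqrt(r1 r2) e^{i (th1 + th2)/2}. The naive principal root of (z^2 - c^2)
# would instead cut the horizon |x| > c and break the equipotential
# free-surface condition there.
sqrt_zc <- function(z, c) {
  sqrt(z - c) * sqrt(z + c)
}

on_plate_segment <- function(z, c) {
  Im(z) == 0 & abs(Re(z)) < c
}

#' Complex potential of a moving thin plate
#'
#' Evaluates `Phi = -iVz + iV (z^2 - c^2)^(1/2)` for a plate of half-width
#' `c` moving normal to itself at speed `V`. The real part is the velocity
#' potential `phi`, the imaginary part the streamfunction `psi`. The square
#' root is taken on the branch whose only cut is the plate segment, so the
#' horizon `y = 0, |x| > c` is the equipotential `phi = 0` and the
#' disturbance decays at infinity.
#'
#' Points exactly on the open plate segment are ambiguous (the two faces
#' carry different potentials); use [face_potential()] with an explicit
#' side instead.
#'
#' @param z Complex location(s) `x + iy`.
#' @param plate A [plate_kinematics()] object.
#' @return Complex vector of potential values, same length as `z`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = 1)
#' complex_potential(2 + 0i, pl)   # phi = 0 on the horizon
#' @seealso [complex_velocity()], [face_potential()], [plate_field()]
#' @export
complex_potential <- function(z, plate) {
  stopifnot(inherits(plate, "plate_kinematics"))
  z <- as.complex(z)
  if (any(on_plate_segment(z, plate$c))) {
    stop("point lies on the open plate segment; use face_potential() with an explicit side",
         call. = FALSE)
  }
  -1i * plate$V * z + 1i * plate$V * sqrt_zc(z, plate$c)
}

#' Velocity field of a moving thin plate
#'
#' The complex velocity is `dPhi/dz = u - iv = -iV + iV z / (z^2 - c^2)^(1/2)`
#' on the plate-cut branch. On either plate face the normal velocity equals
#' the plate speed (`v = V`, the kinematic boundary condition) while the
#' tangential slip is `u = +/- V x / (c^2 - x^2)^(1/2)`; on the horizon
#' `y = 0, |x| > c` the horizontal velocity vanishes.
#'
#' @inheritParams complex_potential
#' @return A [tibble::tibble()] with columns `u` and `v`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = 1)
#' complex_velocity(1.5 + 0i, pl)  # u = 0 on the horizon
#' @export
complex_velocity <- function(z, plate) {
  stopifnot(inherits(plate, "plate_kinematics"))
  z <- as.complex(z)
  c <- plate$c
  if (any(Im(z) == 0 & abs(Re(z)) == c)) {
    stop("on-edge singularity: velocity is unbounded at the plate tips |x| = c",
         call. = FALSE)
  }
  if (any(on_plate_segment(z, c))) {
    stop("point lies on the open plate segment; use face_velocity() with an explicit side",
         call. = FALSE)
  }
  w <- -1i * plate$V + 1i * plate$V * z / sqrt_zc(z, c)
  tibble::tibble(u = Re(w), v = -Im(w))
}

check_side <- function(side) {
  side <- match.arg(side, c("top", "bottom"))
  if (side == "top") +1 else -1
}

#' Velocity potential on the plate faces
#'
#' On the top face (approached from `y = 0+`) the potential is
#' `phi_+ = -V (c^2 - x^2)^(1/2)`; on the bottom face it is
#' `phi_- = +V (c^2 - x^2)^(1/2)`. The jump `phi_- - phi_+` is what the
#' unsteady pressure difference and the plate's added mass integrate.
#' Floating point cannot distinguish `y = +0` from `y = -0`, so the side is
#' an explicit argument.
#'
#' @param x Position(s) along the plate, `|x| <= c`.
#' @param side `"top"` or `"bottom"`.
#' @param plate A [plate_kinematics()] object.
#' @return Numeric vector of potential values at `y = 0`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = 2)
#' face_potential(0, "bottom", pl) - face_potential(0, "top", pl)  # jump 2Vc = 4
#' @export
face_potential <- function(x, side = c("top", "bottom"), plate) {
  stopifnot(inherits(plate, "plate_kinematics"))
  sgn <- check_side(side)
  if (any(abs(x) > plate$c)) {
    stop("out of plate: face_potential() requires |x| <= c", call. = FALSE)
  }
  -sgn * plate$V * sqrt(plate$c^2 - x^2)
}

#' Slip velocity on the plate faces
#'
#' The tangential velocity on the faces, `u_+/- = +/- V x / (c^2 - x^2)^(1/2)`,
#' and the normal velocity `v = V` (both faces). The slip diverges at the
#' plate tips, an integrable edge singularity.
#'
#' @inheritParams face_potential
#' @return A tibble with columns `u` and `v`.
#' @export
face_velocity <- function(x, side = c("top", "bottom"), plate) {
  stopifnot(inherits(plate, "plate_kinematics"))
  sgn <- check_side(side)
  if (any(abs(x) >= plate$c)) {
    stop("face_velocity() requires |x| < c (the tips are singular)", call. = FALSE)
  }
  tibble::tibble(u = sgn * plate$V * x / sqrt(plate$c^2 - x^2),
                 v = rep(plate$V, length(x)))
}

#' Circulation shed from one plate edge
#'
#' The vorticity bound in the slip-velocity jump integrates, over the right
#' half of the plate, to `Gamma_right = -2Vc`; the left edge carries the
#' opposite `+2Vc`, so the total circulation vanishes (Kelvin's theorem).
#' The `"quadrature"` method integrates `-(u_+ - u_-)` numerically with the
#' substitution `x = c sin(theta)`, which removes the integrable edge
#' singularity; it is the independent check on the closed form.
#'
#' @param plate A [plate_kinematics()] object.
#' @param side `"right"` or `"left"` edge.
#' @param method `"analytic"` (closed form) or `"quadrature"`.
#' @return Signed circulation (m^2/s).
#' @examples
#' pl <- plate_kinematics(c = 1, V = 1)
#' edge_circulation(pl, "right")                        # -2
#' edge_circulation(pl, "right", method = "quadrature") # -2 numerically
#' @export
edge_circulation <- function(plate, side = c("right", "left"),
                             method = c("analytic", "quadrature")) {
  stopifnot(inherits(plate, "plate_kinematics"))
  side <- match.arg(side)
  method <- match.arg(method)
  c <- plate$c
  V <- plate$V
  gamma_right <- if (method == "analytic") {
    -2 * V * c
  } else {
    # Gamma_right = -2V int_0^c x / sqrt(c^2 - x^2) dx; with x = c sin(th)
    # the integrand becomes c sin(th), bounded on [0, pi/2].
    q <- stats::integrate(function(th) c * sin(th), 0, pi / 2,
                          rel.tol = 1e-12)
    -2 * V * q$value
  }
  if (side == "right") gamma_right else -gamma_right
}

#' Pressure jump across a fully submerged plate
#'
#' From the unsteady Bernoulli equation the pressure difference across the
#' plate is purely unsteady:
#' `p_- - p_+ = -2 rho d/dt [ V (c^2 - x^2)^(1/2) ]`.
#' The quadratic `|grad phi|^2` term is identical on the two faces and
#' drops out of the jump. Expanding the time derivative with the supplied
#' `dV_dt` and `dc_dt`:
#' `dp = -2 rho [ dV_dt sqrt(c^2 - x^2) + V dc_dt c / sqrt(c^2 - x^2) ]`.
#'
#' @param x Position(s) on the plate, `|x| < c`.
#' @param plate A [plate_kinematics()] object (its `dc_dt`, `dV_dt` drive
#'   the unsteady term).
#' @param medium A [fluid_medium()] or one of `"freshwater"`, `"seawater"`,
#'   `"air"`.
#' @return Pressure difference `p_- - p_+` (Pa), vectorised over `x`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = 0, dV_dt = 1)
#' pressure_jump_submerged(0, pl, fluid_medium(rho = 1, nu = 1e-6))  # -2
#' @export
pressure_jump_submerged <- function(x, plate, medium = medium_freshwater()) {
  stopifnot(inherits(plate, "plate_kinematics"))
  medium <- as_medium(medium)
  if (any(abs(x) >= plate$c)) {
    stop("out of plate: pressure jump is defined for |x| < c", call. = FALSE)
  }
  root <- sqrt(plate$c^2 - x^2)
  -2 * medium$rho * (plate$dV_dt * root +
                       plate$V * plate$dc_dt * plate$c / root)
}

#' Water-side pressure during water entry
#'
#' For a plate impacting a free surface the air side stays at the reference
#' pressure, and the water-side load is
#' `(p_- - p0)/rho = -d/dt [ V (c^2 - x^2)^(1/2) ] - (1/2) V^2 c^2/(c^2 - x^2)`.
#' The quadratic term is singular at the plate tips; by default it is
#' omitted (`include_singular_term = FALSE`), keeping only the unsteady
#' slamming term that the impact-force integral uses. With the term
#' included, values at the tips overflow to `-Inf` rather than raising an
#' error.
#'
#' @inheritParams pressure_jump_submerged
#' @param include_singular_term Include the `-(1/2) V^2 c^2/(c^2 - x^2)`
#'   steady-inertia term? Default `FALSE`.
#' @return `p_- - p0` (Pa), vectorised over `x`.
#' @export
pressure_water_entry <- function(x, plate, medium = medium_freshwater(),
                                 include_singular_term = FALSE) {
  stopifnot(inherits(plate, "plate_kinematics"))
  medium <- as_medium(medium)
  if (any(abs(x) > plate$c)) {
    stop("out of plate: water-entry pressure is defined for |x| <= c",
         call. = FALSE)
  }
  root2 <- plate$c^2 - x^2
  p <- -medium$rho * (plate$dV_dt * sqrt(root2) +
                        plate$V * plate$dc_dt * plate$c / sqrt(root2))
  if (include_singular_term) {
    p <- p - 0.5 * medium$rho * plate$V^2 * plate$c^2 / root2
  }
  p
}

#' Sample the flow field on a grid
#'
#' Evaluates potential, streamfunction and velocity of the moving plate on
#' a rectangular grid, skipping points on the plate cut (returned as `NA`).
#'
#' @param plate A [plate_kinematics()] object.
#' @param x,y Numeric vectors of grid coordinates.
#' @return A tibble with columns `x`, `y`, `phi`, `psi`, `u`, `v`.
#' @examples
#' pl <- plate_kinematics(c = 1, V = -1)
#' fld <- plate_field(pl, x = seq(-2, 2, 0.5), y = seq(-1, 1, 0.5))
#' head(fld)
#' @export
plate_field <- function(plate, x, y) {
  stopifnot(inherits(plate, "plate_kinematics"))
  grid <- tidyr::expand_grid(x = x, y = y)
  z <- complex(real = grid$x, imaginary = grid$y)
  bad <- on_plate_segment(z, plate$c) |
    (Im(z) == 0 & abs(Re(z)) == plate$c)
  Phi <- complex_potential(z[!bad], plate)
  vel <- complex_velocity(z[!bad], plate)
  out <- tibble::tibble(x = grid$x, y = grid$y,
                        phi = NA_real_, psi = NA_real_,
                        u = NA_real_, v = NA_real_)
  out$phi[!bad] <- Re(Phi)
  out$psi[!bad] <- Im(Phi)
  out$u[!bad] <- vel$u
  out$v[!bad] <- vel$v
  out
}

#' Plate-face profiles
#'
#' Slip velocities on both faces and the submerged pressure jump along the
#' plate, the quantities the circulation, added-mass and thrust integrals
#' are built from.
#'
#' @inheritParams pressure_jump_submerged
#' @param n Number of interior sample points. Default 101.
#' @return A tibble with columns `x`, `u_plus`, `u_minus`, `phi_plus`,
#'   `phi_minus`, `dp`.
#' @export
plate_face_profile <- function(plate, medium = medium_freshwater(), n = 101) {
  stopifnot(inherits(plate, "plate_kinematics"))
  x <- seq(-plate$c, plate$c, length.out = n + 2L)[-c(1L, n + 2L)]
  tibble::tibble(
    x = x,
    u_plus = face_velocity(x, "top", plate)$u,
    u_minus = face_velocity(x, "bottom", plate)$u,
    phi_plus = face_potential(x, "top", plate),
    phi_minus = face_potential(x, "bottom", plate),
    dp = pressure_jump_submerged(x, plate, medium)
  )
}
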