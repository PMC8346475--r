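#' A water-entry event for a diving body
#'
#' Describes one dive: the spheroidal body, its entry orientation and
#' impact speed. Head-first entry is motion along the major axis (the
#' axial added-mass coefficient applies and the wetted axial extent grows
#' during entry); belly-first is motion along the minor axis. If the speed
#' is not given it is derived from the jump height via `V^2 = 2 g H`, free
#' fall from rest.
#'
#' @param body A [spheroid_body()].
#' @param orientation `"head_first"` or `"belly_first"`.
#' @param H Jump height (m), used when `V` is missing.
#' @param V Impact speed magnitude (m/s). Overrides `H` if given.
#' @param medium A [fluid_medium()] or medium name; the water entered.
#' @return An object of class `dive_event`.
#' @examples
#' dv <- dive_event(spheroid_body(0.2, 0.1), "head_first", H = 1)
#' dv$V  # sqrt(2 * 9.81 * 1)
#' @export
dive_event <- function(body, orientation = c("head_first", "belly_first"),
                       H = NULL, V = NULL, medium = medium_freshwater()) {
  stopifnot(inherits(body, "spheroid_body"))
  orientation <- match.arg(orientation)
  medium <- as_medium(medium)
  if (is.null(V)) {
    if (is.null(H)) stop("supply either jump height H or impact speed V",
                         call. = FALSE)
    V <- impact_speed_from_height(H, medium$g)
  } else {
    stopifnot(is.numeric(V), length(V) == 1L, V >= 0)
    if (is.null(H)) H <- V^2 / (2 * medium$g)
  }
  structure(list(body = body, orientation = orientation, H = H, V = V,
                 medium = medium),
            class = "dive_event")
}

#' Impact speed from jump height
#'
#' Free-fall conversion `V = sqrt(2 g H)`: a body leaving the water and
#' re-entering from height `H` hits the surface at this speed.
#'
#' @param H Jump height (m), non-negative.
#' @param g Gravitational acceleration (m/s^2).
#' @return Speed (m/s), vectorised over `H`.
#' @examples
#' impact_speed_from_height(1)  # 4.429 m/s
#' @export
impact_speed_from_height <- function(H, g = 9.81) {
  stopifnot(is.numeric(H), is.numeric(g), length(g) == 1L, g > 0)
  if (any(H < 0)) stop("jump height H must be non-negative", call. = FALSE)
  sqrt(2 * g * H)
}

#' Peak water-entry impact force
#'
#' The slamming force peaks when the immersed cross-section reaches the
#' body's maximum section. For a prolate spheroid,
#' head-first: `F = K_axial * (2/3) * pi * rho * b^2 * V^2`;
#' belly-first: `F = K_lateral * (4/3) * pi * rho * a * b * V^2`.
#' By default the magnitude is returned; `signed = TRUE` restores the
#' negative sign of a force opposing the motion.
#'
#' @param dive A [dive_event()].
#' @param signed Return the signed (negative, decelerating) value?
#' @return Peak impact force (N).
#' @examples
#' max_impact_force(dive_event(spheroid_body(0.2, 0.1), "head_first", H = 1))
#' @export
max_impact_force <- function(dive, signed = FALSE) {
  stopifnot(inherits(dive, "dive_event"))
  body <- dive$body
  co <- spheroid_coefficients(body)
  rho <- dive$medium$rho
  F <- if (dive$orientation == "head_first") {
    co$K_axial * (2 / 3) * pi * rho * body$b^2 * dive$V^2
  } else {
    co$K_lateral * (4 / 3) * pi * rho * body$a * body$b * dive$V^2
  }
  if (signed) -F else F
}

#' Wetted area of a half-immersed spheroid
#'
#' At peak impact force half the body is in contact with water; the wetted
#' area is half the spheroid's surface,
#' `pi b^2 (1 + a/(b e) * asin(e))` with `e = sqrt(1 - b^2/a^2)`.
#' The sphere limit (`asin(e)/e -> 1`) is `2 pi r^2`, evaluated by series
#' for small `e` to avoid 0/0.
#'
#' @param body A [spheroid_body()].
#' @return Wetted area (m^2).
#' @examples
#' wetted_area_half_spheroid(spheroid_body(1, 1))  # 2 * pi
#' @export
wetted_area_half_spheroid <- function(body) {
  stopifnot(inherits(body, "spheroid_body"))
  e <- body$e
  # asin(e)/e = 1 + e^2/6 + 3 e^4/40 + 15 e^6/336 for small e
  ratio <- if (e < 1e-4) {
    1 + e^2 / 6 + 3 * e^4 / 40
  } else {
    asin(e) / e
  }
  pi * body$b^2 * (1 + (body$a / body$b) * ratio)
}

#' Peak impact pressure
#'
#' Peak force divided by the wetted area at peak load (half the spheroid
#' surface). Head-first:
#' `P = K_axial * (2/3) * rho * (1 + a/(be) asin e)^(-1) * V^2`;
#' belly-first carries `K_lateral * (4/3) * (a/b)` instead. Computed as
#' the exact quotient [max_impact_force()] / [wetted_area_half_spheroid()].
#'
#' @inheritParams max_impact_force
#' @return Pressure (Pa).
#' @export
impact_pressure <- function(dive, signed = FALSE) {
  max_impact_force(dive, signed = signed) /
    wetted_area_half_spheroid(dive$body)
}

#' Summarise one dive
#'
#' @param dive A [dive_event()].
#' @return A one-row tibble with `orientation`, `V`, `F_max`, `S_wet`, `P`.
#' @export
dive_summary <- function(dive) {
  stopifnot(inherits(dive, "dive_event"))
  F <- max_impact_force(dive)
  S <- wetted_area_half_spheroid(dive$body)
  tibble::tibble(orientation = dive$orientation, V = dive$V,
                 F_max = F, S_wet = S, P = F / S)
}

#' Time-resolved water-entry force
#'
#' The 2D slamming force per unit span from the growing added mass
#' `M(t) = rho pi c(t)^2`:
#' `F(t) = -V d(M/2)/dt - (M/2) dV/dt`.
#' With constant entry speed only the first (slamming) term survives.
#' Schedules may be functions of time or sampled vectors; derivatives of
#' sampled schedules use central finite differences. A non-monotone
#' half-width schedule (an exit phase) is not part of the entry model and
#' is flagged with a warning.
#'
#' @param t Time sample points (s), increasing.
#' @param c_of_t Wetted half-width schedule: function of `t` or numeric
#'   vector along `t`.
#' @param V_of_t Speed schedule: function of `t`, numeric vector, or a
#'   single number for constant speed.
#' @param rho Fluid density (kg/m^3).
#' @return A tibble with columns `t`, `c`, `V`, `m_added`, `F` (signed:
#'   negative opposes downward-growing momentum flux for `V > 0`).
#' @examples
#' tr <- time_resolved_entry_force(seq(0, 1, 0.1),
#'                                 c_of_t = function(t) 0.5 * t,
#'                                 V_of_t = 1, rho = 1000)
#' @export
time_resolved_entry_force <- function(t, c_of_t, V_of_t, rho = 1000) {
  stopifnot(is.numeric(t), length(t) >= 2L, !is.unsorted(t),
            is.numeric(rho), length(rho) == 1L, rho > 0)
  eval_sched <- function(s, name) {
    if (is.function(s)) return(s(t))
    if (is.numeric(s) && length(s) == 1L) return(rep(s, length(t)))
    if (is.numeric(s) && length(s) == length(t)) return(s)
    stop(name, " must be a function of t, a vector along t, or a scalar",
         call. = FALSE)
  }
  cc <- eval_sched(c_of_t, "c_of_t")
  V <- eval_sched(V_of_t, "V_of_t")
  if (any(diff(cc) < 0)) {
    warning("non-monotone half-width schedule: the exit phase is outside the entry model",
            call. = FALSE)
  }
  # derivatives: analytic schedules get a small central step, sampled ones
  # gradient over the supplied grid
  if (is.function(c_of_t)) {
    h <- pmax(1e-6 * max(abs(t), 1), 1e-9)
    dc <- (c_of_t(t + h) - c_of_t(t - h)) / (2 * h)
  } else {
    dc <- pracma::gradient(cc, t)
  }
  if (is.function(V_of_t)) {
    h <- pmax(1e-6 * max(abs(t), 1), 1e-9)
    dV <- (V_of_t(t + h) - V_of_t(t - h)) / (2 * h)
  } else if (length(V_of_t) == 1L) {
    dV <- rep(0, length(t))
  } else {
    dV <- pracma::gradient(V, t)
  }
  m_added <- rho * pi * cc^2
  # d(M/2)/dt = rho pi c dc/dt
  F <- -V * rho * pi * cc * dc - (m_added / 2) * dV
  tibble::tibble(t = t, c = cc, V = V, m_added = m_added, F = F)
}

#' Allometric scaling exponents for diving impact
#'
#' Composes the scaling chain of the impact survey: jump height
#' `H ~ L^h`, body mass `M ~ L^m`, body (and wetted) area `S ~ L^s`.
#' Impact force scales as `F ~ V^2 L^s ~ H L^s ~ L^(h + s)`, so in terms
#' of mass `F ~ M^((h + s)/m)`; pressure is force over area,
#' `P ~ M^((h + s)/m - s/m)`. The defaults `h = 2/3`, `m = 3`, `s = 2`
#' give `F ~ M^(8/9)` and `P ~ M^(2/9) ~ M^0.22`: impact force grows
#' almost linearly with mass while impact pressure is nearly
#' size-independent.
#'
#' @param height_vs_length Exponent of jump height vs body length
#'   (default 2/3).
#' @param mass_vs_length Exponent of mass vs length (default 3, isometry).
#' @param area_vs_length Exponent of area vs length (default 2).
#' @return A one-row tibble with the three inputs plus `force_vs_mass`
#'   and `pressure_vs_mass`.
#' @examples
#' allometric_exponents()  # force_vs_mass = 8/9, pressure_vs_mass = 2/9
#' @export
allometric_exponents <- function(height_vs_length = 2 / 3,
                                 mass_vs_length = 3,
                                 area_vs_length = 2) {
  stopifnot(is.numeric(height_vs_length), is.numeric(mass_vs_length),
            is.numeric(area_vs_length))
  if (any(mass_vs_length == 0)) {
    stop("mass_vs_length exponent must be non-zero", call. = FALSE)
  }
  force <- (height_vs_length + area_vs_length) / mass_vs_length
  tibble::tibble(
    height_vs_length = height_vs_length,
    mass_vs_length = mass_vs_length,
    area_vs_length = area_vs_length,
    force_vs_mass = force,
    pressure_vs_mass = force - area_vs_length / mass_vs_length
  )
}

#' Impact survey over a table of diving animals
#'
#' Applies the peak-force and peak-pressure model to each row of a
#' comparative table (columns `mass`, `a`, `b`, and `H` or `V`;
#' `orientation` optional, default head-first) and fits log-log
#' ordinary-least-squares slopes of force and pressure against mass.
#' Rows with missing required fields are dropped with a warning.
#'
#' @param records A data frame of diving animals, e.g. from
#'   [generate_population()] or [read_animal_records()].
#' @param medium A [fluid_medium()] or medium name.
#' @return A tibble with one row per usable animal (`species`, `mass`,
#'   `a`, `b`, `V`, `F_max`, `S_wet`, `P`), carrying the two log-log fits
#'   as attributes `fit_force` and `fit_pressure` (class [loglog_fit()];
#'   `NULL` when fewer than two animals). [glance()] on the result
#'   summarises the fitted slopes.
#' @examples
#' pop <- generate_population(population_spec("diver", n = 50, seed = 1))
#' sv <- dive_survey(pop)
#' glance(sv)
#' @export
dive_survey <- function(records, medium = medium_freshwater()) {
  stopifnot(is.data.frame(records))
  medium <- as_medium(medium)
  records <- tibble::as_tibble(records)
  if (!nrow(records)) {
    warning("empty input: no animals to survey", call. = FALSE)
    out <- tibble::tibble(species = character(), mass = double(),
                          a = double(), b = double(), V = double(),
                          F_max = double(), S_wet = double(), P = double())
    return(structure(out, fit_force = NULL, fit_pressure = NULL,
                     class = c("dive_survey", class(out))))
  }
  if (!"species" %in% names(records)) {
    records$species <- sprintf("animal_%d", seq_len(nrow(records)))
  }
  if (!"orientation" %in% names(records)) records$orientation <- "head_first"
  if (!"V" %in% names(records)) records$V <- NA_real_
  if (!"H" %in% names(records)) records$H <- NA_real_
  need <- c("mass", "a", "b")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  usable <- stats::complete.cases(records[need]) &
    (!is.na(records$V) | !is.na(records$H)) &
    records$a >= records$b & records$b > 0
  if (any(!usable)) {
    warning(sum(!usable), " row(s) skipped: missing mass/a/b/H-or-V or invalid geometry",
            call. = FALSE)
  }
  rec <- records[usable, , drop = FALSE]
  rows <- purrr::pmap(
    list(rec$a, rec$b, rec$H, rec$V, rec$orientation),
    function(a, b, H, V, orientation) {
      dv <- dive_event(spheroid_body(a, b), orientation,
                       H = if (is.na(H)) NULL else H,
                       V = if (is.na(V)) NULL else V,
                       medium = medium)
      dive_summary(dv)
    }
  )
  res <- dplyr::bind_rows(rows)
  out <- tibble::tibble(species = rec$species, mass = rec$mass,
                        a = rec$a, b = rec$b,
                        orientation = res$orientation, V = res$V,
                        F_max = res$F_max, S_wet = res$S_wet, P = res$P)
  fit_f <- fit_p <- NULL
  if (nrow(out) >= 2L) {
    fit_f <- loglog_fit(out$mass, out$F_max)
    fit_p <- loglog_fit(out$mass, out$P)
  }
  structure(out, fit_force = fit_f, fit_pressure = fit_p,
            class = c("dive_survey", class(out)))
}

#' @exportS3Method generics::glance
glance.dive_survey <- function(x, ...) {
  ff <- attr(x, "fit_force")
  fp <- attr(x, "fit_pressure")
  tibble::tibble(
    n = nrow(x),
    force_vs_mass_slope = if (is.null(ff)) NA_real_ else glance(ff)$slope,
    pressure_vs_mass_slope = if (is.null(fp)) NA_real_ else glance(fp)$slope
  )
}
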