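#' Specification of a synthetic animal population
#'
#' Describes a seeded synthetic population of one locomotor group, used to
#' exercise every scaling analysis without external data. Body lengths are
#' sampled log-uniformly over `L_range`; all other traits follow the
#' group's scaling law times multiplicative lognormal noise
#' `exp(N(0, noise_sigma^2))`:
#'
#' * **diver** - prolate spheroid with `a = L/2`, `b = a / aspect`; mass
#'   from body volume times `body_density` (so mass is an exact `L^3` law
#'   when `aspect` is a single number); jump height
#'   `H = height_coef * L^height_vs_length`. An `aspect` of length 2 is a
#'   uniform sampling range; note that a sampled aspect makes the
#'   population non-isometric, so exponent-recovery analyses should fix it.
#' * **flier** - wing geometry proportional to span, frequency falling
#'   with size, and mass set by the lift balance
#'   `mass * g = prefactor * rho_air * c^2 A f^2 L`.
#' * **swimmer** - fin geometry proportional to body length and cruise
#'   speed `U = f * sqrt(A c) / st_target`, i.e. a population holding the
#'   target Strouhal number.
#'
#' Identical seeds give identical populations; the generator never touches
#' the global RNG stream.
#'
#' @param group `"diver"`, `"flier"` or `"swimmer"`.
#' @param n Number of animals.
#' @param L_range Body-length (diver, swimmer) or span (flier) range (m).
#' @param noise_sigma Lognormal noise scale on the scaling relations.
#' @param seed Integer RNG seed.
#' @param height_vs_length,height_coef Diver jump-height law
#'   `H = height_coef * L^height_vs_length` (m).
#' @param aspect Diver fineness ratio `a/b`: a single number for an
#'   isometric population or a length-2 range sampled uniformly.
#' @param body_density Diver tissue density (kg/m^3).
#' @param orientation Diver entry orientation.
#' @param prefactor Flier lift prefactor or swimmer speed prefactor.
#' @param st_target Swimmer target Strouhal number (overrides `prefactor`
#'   as `prefactor = 1/st_target`).
#' @return An object of class `population_spec`.
#' @examples
#' population_spec("swimmer", n = 100, seed = 7, st_target = 0.3)
#' @export
population_spec <- function(group = c("diver", "flier", "swimmer"),
                            n,
                            L_range = NULL,
                            noise_sigma = 0,
                            seed = 1L,
                            height_vs_length = 2 / 3,
                            height_coef = 1,
                            aspect = c(1, 6),
                            body_density = 1000,
                            orientation = c("head_first", "belly_first"),
                            prefactor = 5,
                            st_target = NULL) {
  group <- match.arg(group)
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(noise_sigma), noise_sigma >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (is.null(L_range)) {
    L_range <- switch(group,
                      diver = c(0.1, 10),     # goldfish to whale
                      flier = c(0.25, 1.5),   # small bat to large bird span
                      swimmer = c(0.02, 2))   # larva to large fish
  }
  stopifnot(length(L_range) == 2L, all(L_range > 0), L_range[1] <= L_range[2])
  stopifnot(length(aspect) %in% c(1L, 2L), all(aspect >= 1))
  if (!is.null(st_target)) {
    stopifnot(is.numeric(st_target), st_target > 0)
    prefactor <- 1 / st_target
  }
  structure(list(group = group, n = as.integer(n), L_range = L_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 height_vs_length = height_vs_length,
                 height_coef = height_coef,
                 aspect = aspect, body_density = body_density,
                 orientation = orientation, prefactor = prefactor,
                 st_target = st_target),
            class = "population_spec")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic animal population
#'
#' Draws the population described by a [population_spec()]. All groups
#' share one tabular schema (see [animal_record_schema()]); fields not
#' applicable to a group are `NA`.
#'
#' @param spec A [population_spec()].
#' @return A tibble with columns `species`, `group`, `mass`, `a`, `b`,
#'   `H`, `orientation`, `A`, `f`, `chord_half`, `span`, `body_length`,
#'   `U_swim`, `weight`, `medium`.
#' @examples
#' pop <- generate_population(population_spec("diver", n = 5, seed = 42))
#' pop[c("species", "mass", "a", "b", "H")]
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n
    L <- exp(stats::runif(n, log(spec$L_range[1]), log(spec$L_range[2])))
    noise <- function() exp(stats::rnorm(n, 0, spec$noise_sigma))
    base <- tibble::tibble(
      species = sprintf("%s_%03d", spec$group, seq_len(n)),
      group = spec$group,
      mass = NA_real_, a = NA_real_, b = NA_real_, H = NA_real_,
      orientation = NA_character_,
      A = NA_real_, f = NA_real_, chord_half = NA_real_, span = NA_real_,
      body_length = L, U_swim = NA_real_, weight = NA_real_,
      medium = NA_character_
    )
    if (spec$group == "diver") {
      aspect <- if (length(spec$aspect) == 2L) {
        stats::runif(n, spec$aspect[1], spec$aspect[2])
      } else {
        rep(spec$aspect, n)
      }
      base$a <- L / 2
      base$b <- base$a / aspect
      base$mass <- spec$body_density * (4 / 3) * pi * base$a * base$b^2 * noise()
      base$H <- spec$height_coef * L^spec$height_vs_length * noise()
      base$orientation <- spec$orientation
      base$medium <- "seawater"
    } else if (spec$group == "flier") {
      rho <- medium_air()$rho
      base$span <- L
      base$chord_half <- L / 12
      base$A <- 0.35 * L
      base$f <- 4 / sqrt(L)
      base$weight <- spec$prefactor * rho * base$chord_half^2 * base$A *
        base$f^2 * base$span * noise()
      base$mass <- base$weight / 9.81
      base$medium <- "air"
    } else {
      base$chord_half <- 0.1 * L
      base$A <- 0.2 * L
      base$f <- 2 / sqrt(L)
      base$span <- L
      base$U_swim <- spec$prefactor * base$f *
        sqrt(base$A * base$chord_half) * noise()
      base$mass <- 1000 * 0.01 * L^3
      base$medium <- "freshwater"
    }
    base
  })
}

#' Column schema of the comparative animal table
#'
#' The frozen CSV layout shared by the generator, the readers and the
#' survey/fit pipelines, with units. Shipped as plain text in
#' `inst/extdata/animal_record_schema.csv`.
#'
#' @return A tibble with columns `column`, `unit`, `description`.
#' @export
animal_record_schema <- function() {
  path <- system.file("extdata", "animal_record_schema.csv",
                      package = "potflow", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write comparative animal tables
#'
#' CSV round-trip for animal records in the schema of
#' [animal_record_schema()]. Unknown columns are preserved; missing
#' required fields do not fail at read time (the consuming analysis skips
#' and warns row-wise).
#'
#' @param path File path.
#' @param records A data frame of animal records.
#' @return `read_animal_records()` a tibble; `write_animal_records()` the
#'   records, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' pop <- generate_population(population_spec("swimmer", n = 3, seed = 1))
#' write_animal_records(pop, tmp)
#' identical(dim(read_animal_records(tmp)), dim(pop))
#' @export
read_animal_records <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  schema <- animal_record_schema()
  numeric_cols <- setdiff(schema$column,
                          c("species", "group", "orientation", "medium"))
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!ncol(out)) stop("malformed header in ", path, call. = FALSE)
  for (col in intersect(names(out), numeric_cols)) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

#' @rdname read_animal_records
#' @export
write_animal_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(records, path)
  invisible(records)
}

#' Power-law fit on the log-log scale
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`: the slope is the
#' power-law exponent and `10^intercept` the prefactor. This is how the
#' comparative scalings (impact force and pressure vs mass, lift vs
#' weight, speed vs flapping speed) are quantified; no weighting or
#' errors-in-variables correction is applied.
#'
#' @param x,y Positive numeric vectors of equal length, `n >= 2`.
#' @return An object of class `loglog_fit`. Use [tidy()] for the
#'   coefficient table, [glance()] for the one-row summary (`slope`,
#'   `slope_se`, `slope_conf_low`/`high` at 95%, `prefactor`,
#'   `r_squared`, `n`), and [ggplot2::autoplot()] to draw it.
#' @examples
#' f <- loglog_fit(1:20, 3 * (1:20)^2)
#' glance(f)[c("slope", "prefactor")]  # 2 and 3
#' @export
loglog_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) {
    stop("log-log fit needs at least two points", call. = FALSE)
  }
  bad <- which(!(x > 0) | !(y > 0) | !is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("non-positive or non-finite values at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(lx = log10(x), ly = log10(y))
  model <- stats::lm(ly ~ lx, data = dat)
  structure(list(model = model, n = length(x), data = dat),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<loglog_fit> n = %d: y = %.4g * x^%.4f (R^2 = %.4f)\n",
              g$n, g$prefactor, g$slope, g$r_squared))
  invisible(x)
}

# summary.lm warns on zero-residual fits; exact power laws are a designed
# use here (noise-free generators), so that specific warning is muffled.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.loglog_fit <- function(x, conf.level = 0.95, ...) {
  s <- quiet_perfect_fit(summary(x$model))$coefficients
  ci <- quiet_perfect_fit(stats::confint(x$model, level = conf.level))
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p.value = unname(s[, 4]),
                 conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]))
}

#' @exportS3Method generics::glance
glance.loglog_fit <- function(x, ...) {
  td <- tidy(x)
  sl <- td[td$term == "slope", ]
  ic <- td$estimate[td$term == "intercept"]
  tibble::tibble(slope = sl$estimate,
                 slope_se = sl$std.error,
                 slope_conf_low = sl$conf.low,
                 slope_conf_high = sl$conf.high,
                 intercept = ic,
                 prefactor = 10^ic,
                 r_squared = quiet_perfect_fit(summary(x$model))$r.squared,
                 n = x$n)
}
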