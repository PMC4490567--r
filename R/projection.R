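#' Fit the historical consumption-versus-population relationship
#'
#' Ordinary least squares of total annual seafood consumption (tonnes) on
#' global population (persons) — a Gaussian identity-link model. The fitted
#' line is the engine of the demand projection.
#'
#' @param population,consumption Paired per-year numeric vectors (>= 3
#'   years; population strictly positive and non-constant).
#' @return A list of class `consumption_fit`: `intercept` (tonnes), `slope`
#'   (tonnes/person), `sigma` (residual s.d.), `slope_se`, `n`.
#' @export
fit_consumption_model <- function(population, consumption) {
  if (length(population) != length(consumption) || length(population) < 3) {
    stop("need >= 3 paired years", call. = FALSE)
  }
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (stats::sd(population) == 0) {
    stop("constant population: slope unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(consumption ~ population)
  # noiseless input is legitimate here; silence the perfect-fit warning
  s <- suppressWarnings(summary(fit))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 sigma = s$sigma,
                 slope_se = s$coefficients["population", "Std. Error"],
                 n = length(population)),
            class = "consumption_fit")
}

#' @export
print.consumption_fit <- function(x, ...) {
  cat(sprintf(
    "<consumption_fit> intercept %.4g t, slope %.4g t/person (n = %d)\n",
    x$intercept, x$slope, x$n))
  invisible(x)
}

#' Project seafood demand along population scenarios
#'
#' Evaluates the fitted consumption line on each scenario's population
#' path, year by year, up to the horizon.
#'
#' @param fit A [fit_consumption_model()] result.
#' @param scenarios An `of_scenarios` (or a tibble with `scenario`, `year`,
#'   `population`).
#' @param horizon Last projected year (default 2100); must not precede the
#'   scenarios' first year.
#' @return Tibble with `scenario`, `year`, `population`,
#'   `projected_tonnes`.
#' @export
project_consumption <- function(fit, scenarios, horizon = 2100) {
  stopifnot(inherits(fit, "consumption_fit"))
  sc <- if (inherits(scenarios, "of_scenarios")) scenarios$scenarios else
    as_tibble(scenarios)
  if (horizon < min(sc$year)) {
    stop("horizon precedes the scenario window", call. = FALSE)
  }
  sc <- sc[sc$year <= horizon, ]
  sc$projected_tonnes <- fit$intercept + fit$slope * sc$population
  sc
}

#' First year a projection exceeds a supply limit
#'
#' Strict exceedance on annual points, no sub-year interpolation. The
#' crossing year is monotone non-decreasing in the limit.
#'
#' @param projection A [project_consumption()] table (one or more
#'   scenarios).
#' @param limit Supply limit in the same units as `projected_tonnes`
#'   (> 0).
#' @return Tibble with `scenario` and `crossing_year` (`NA` when the limit
#'   is never exceeded).
#' @export
limit_crossing_year <- function(projection, limit) {
  assert_scalar_number(limit, "limit", lower = 0, strict_lower = TRUE)
  if (nrow(projection) == 0) stop("empty projection", call. = FALSE)
  bind_rows(lapply(split(projection, projection$scenario), function(p) {
    p <- p[order(p$year), ]
    hit <- which(p$projected_tonnes > limit)
    tibble(scenario = p$scenario[1],
           crossing_year = if (length(hit)) p$year[hit[1]] else NA_integer_)
  }))
}
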