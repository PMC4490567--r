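#' Generate global population scenarios and historical consumption
#'
#' Builds a historical global population series with a linearly linked
#' seafood-consumption record (consumption = intercept + slope x population
#' + Gaussian noise), then three projection scenarios (low / median / high
#' fecundity) that share the historical path and diverge only after the
#' last historical year, growing at their respective rates.
#'
#' @param base_pop Population in the first historical year, persons.
#' @param growth_rates Named list or vector with `low`, `median`, `high`
#'   annual growth rates; must satisfy `high >= median >= low`. The median
#'   rate drives the historical window.
#' @param consumption_intercept Tonnes.
#' @param consumption_slope Tonnes per person.
#' @param noise_sd Consumption noise s.d., tonnes.
#' @param years List with `start`, `hist_end`, `end` (e.g. 1950, 2011, 2100).
#' @param seed Integer seed.
#' @return An object of class `of_scenarios`: list with `historical`
#'   (tibble `year`, `population`, `consumption`) and `scenarios` (tibble
#'   `scenario`, `year`, `population` covering the whole range).
#' @export
generate_population <- function(base_pop = 2.5e9,
                                growth_rates = list(low = 0.003,
                                                    median = 0.008,
                                                    high = 0.013),
                                consumption_intercept = -3e7,
                                consumption_slope = 0.02,
                                noise_sd = 1e6,
                                years = list(start = 1950, hist_end = 2011,
                                             end = 2100),
                                seed = 1L) {
  assert_scalar_number(base_pop, "base_pop", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  g <- unlist(growth_rates[c("low", "median", "high")])
  if (any(is.na(g)) || !(g["high"] >= g["median"] && g["median"] >= g["low"])) {
    stop("growth rates must satisfy high >= median >= low", call. = FALSE)
  }
  y_hist <- seq(years$start, years$hist_end)
  y_proj <- seq(years$hist_end + 1, years$end)

  pop_hist <- base_pop * (1 + g[["median"]])^(seq_along(y_hist) - 1)
  with_seed(seed, {
    noise <- stats::rnorm(length(y_hist), 0, noise_sd)
  })
  historical <- tibble(
    year = as.integer(y_hist), population = pop_hist,
    consumption = consumption_intercept + consumption_slope * pop_hist +
      if (noise_sd > 0) noise else 0
  )

  p_end <- pop_hist[length(pop_hist)]
  scenarios <- bind_rows(lapply(c("low", "median", "high"), function(s) {
    proj <- p_end * (1 + g[[s]])^seq_along(y_proj)
    tibble(scenario = s,
           year = as.integer(c(y_hist, y_proj)),
           population = c(pop_hist, proj))
  }))

  structure(list(historical = historical, scenarios = scenarios,
                 hist_end = years$hist_end),
            class = "of_scenarios")
}

#' @export
print.of_scenarios <- function(x, ...) {
  cat(sprintf("<of_scenarios> history %d-%d, projection to %d\n",
              min(x$historical$year), x$hist_end, max(x$scenarios$year)))
  invisible(x)
}
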