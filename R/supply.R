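#' Parameters of the wild + mariculture supply-limit model
#'
#' Five scalars govern the ceiling on combined seafood supply when wild
#' landings are static and mariculture growth is limited by wild-sourced
#' fishmeal:
#' \describe{
#'   \item{W}{total wild capture including IUU landings, Mt/yr (mean 105,
#'     range 94.5-126: a 10% drop to a 20% rise on recent levels).}
#'   \item{fr}{proportion of wild catch diverted to fodder rather than
#'     eaten (0.36, range 0.25-0.45).}
#'   \item{fm}{proportion of fodder that is reduced to fishmeal (0.9,
#'     range 0.7-1.0).}
#'   \item{rfm}{reduction rate, tonnes fishmeal (with edible oils) per
#'     tonne of fodder fish (range 0.21-0.24; the default is the range
#'     midpoint 0.225, which reproduces the headline limits after rounding
#'     to whole Mt — the alternative point value 0.22 is also in
#'     circulation and can be supplied explicitly).}
#'   \item{ffm}{proportion of mariculture feed that is wild-sourced
#'     fishmeal; scenario values 0.10, 0.07, 0.05.}
#' }
#'
#' @param W,fr,fm,rfm,ffm See description.
#' @return A list of class `supply_params`.
#' @export
supply_params <- function(W = 105, fr = 0.36, fm = 0.9, rfm = 0.225,
                          ffm = 0.10) {
  assert_scalar_number(W, "W", lower = 0, strict_lower = TRUE)
  for (nm in c("fr", "fm", "rfm", "ffm")) {
    assert_scalar_number(get(nm), nm, lower = 0, upper = 1)
  }
  if (ffm == 0) stop("`ffm` must be > 0 (it divides)", call. = FALSE)
  structure(list(W = W, fr = fr, fm = fm, rfm = rfm, ffm = ffm),
            class = "supply_params")
}

#' Table of parameter ranges for the sensitivity analysis
#'
#' @return Tibble with `param`, `mean`, `min`, `max` for W, fr, fm, rfm.
#' @export
supply_ranges <- function() {
  tibble(param = c("W", "fr", "fm", "rfm"),
         mean = c(105, 0.36, 0.9, 0.225),
         min = c(94.5, 0.25, 0.7, 0.21),
         max = c(126, 0.45, 1.0, 0.24))
}

#' Combined wild + mariculture seafood supply limit
#'
#' Closed-form supply ceiling under a 100% feed-to-product conversion
#' efficiency (optimistic, to allow for farmed filter feeders):
#' \deqn{F = W \cdot fr, \quad M = F \cdot fm \cdot rfm / ffm, \quad
#'       S = W (1 - fr) + M}
#' where `F` is the tonnage removed for fodder and `M` the mariculture
#' production that the resulting fishmeal can feed at inclusion rate
#' `ffm`. All quantities in Mt/yr.
#'
#' @param params A [supply_params()] list.
#' @return A one-row tibble: `ffm`, `F`, `M`, `S`.
#' @export
#' @examples
#' supply_limit(supply_params(ffm = 0.10))  # S ~ 144 Mt
supply_limit <- function(params = supply_params()) {
  stopifnot(inherits(params, "supply_params"))
  F_ <- params$W * params$fr
  M <- F_ * params$fm * params$rfm / params$ffm
  tibble(ffm = params$ffm, F = F_, M = M,
         S = params$W * (1 - params$fr) + M)
}

#' Supply limits for the three fishmeal-inclusion scenarios
#'
#' @param ffm_scenarios Fishmeal inclusion rates, default `c(0.10, 0.07,
#'   0.05)`.
#' @param ... Other parameters forwarded to [supply_params()].
#' @return Tibble with one row per scenario: `ffm`, `F`, `M`, `S`.
#' @export
supply_scenarios <- function(ffm_scenarios = c(0.10, 0.07, 0.05), ...) {
  bind_rows(lapply(ffm_scenarios, function(f) {
    supply_limit(supply_params(ffm = f, ...))
  }))
}

#' Monte Carlo sensitivity of the supply limit
#'
#' Draws (W, fr, fm, rfm) independently from their ranges — uniform by
#' default, or truncated normal centred on the mean with ~95% of its mass
#' inside the range — with `ffm` held at the scenario value, and summarizes
#' the resulting supply limits.
#'
#' @param ranges Range table as from [supply_ranges()].
#' @param ffm_scenario Fishmeal inclusion rate for this scenario.
#' @param n_sims Number of simulations (default 1000).
#' @param sampling `"uniform"` or `"truncnorm"`.
#' @param seed Integer seed.
#' @return A one-row tibble: `ffm`, `mean_S`, `ci_low`, `ci_high`,
#'   `range_to_mean_pct` (100 x CI width / mean), `normality_rejected`.
#' @export
supply_sensitivity <- function(ranges = supply_ranges(), ffm_scenario = 0.10,
                               n_sims = 1000,
                               sampling = c("uniform", "truncnorm"),
                               seed = 1L) {
  sampling <- match.arg(sampling)
  if (n_sims < 1) stop("`n_sims` must be >= 1", call. = FALSE)
  stopifnot(all(c("param", "mean", "min", "max") %in% names(ranges)),
            all(ranges$min <= ranges$mean & ranges$mean <= ranges$max))
  draw <- function(p) {
    r <- ranges[ranges$param == p, ]
    if (r$max == r$min) return(rep(r$mean, n_sims))
    if (sampling == "uniform") {
      stats::runif(n_sims, r$min, r$max)
    } else {
      # s.d. set so the untruncated normal holds ~95% within the range
      rtruncnorm(n_sims, r$mean, (r$max - r$min) / (2 * 1.96),
                 r$min, r$max)
    }
  }
  S <- with_seed(seed, {
    W <- draw("W"); fr <- draw("fr"); fm <- draw("fm"); rfm <- draw("rfm")
    W * (1 - fr) + W * fr * fm * rfm / ffm_scenario
  })
  ci <- stats::quantile(S, c(0.025, 0.975), names = FALSE, type = 1)
  normality <- if (length(unique(S)) > 2 && n_sims >= 3 && n_sims <= 5000) {
    stats::shapiro.test(S)$p.value < 0.05
  } else NA
  tibble(ffm = ffm_scenario, mean_S = mean(S), ci_low = ci[1],
         ci_high = ci[2],
         range_to_mean_pct = 100 * (ci[2] - ci[1]) / mean(S),
         normality_rejected = normality)
}
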