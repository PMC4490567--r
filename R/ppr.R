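#' Trophic conversion parameters for primary production required
#'
#' The PPR of a catch back-calculates the photosynthetic carbon that
#' supported it: `PPR = sum_i (C_i / CR) * (1 / TE)^(TL_i - 1)` where `C_i`
#' is wet-weight catch of taxon `i`, `CR` converts wet weight to carbon
#' (canonically 9:1) and `TE` is the trophic transfer efficiency
#' (canonically 10%). A taxon at trophic level 1 (harvested primary
#' producers) contributes `C / CR` exactly.
#'
#' @param cr Wet-weight-to-carbon conversion ratio (> 0).
#' @param te Transfer efficiency, in `(0, 1)`.
#' @return A list of class `ppr_params`.
#' @export
ppr_params <- function(cr = 9, te = 0.1) {
  assert_scalar_number(cr, "cr", lower = 0, strict_lower = TRUE)
  assert_scalar_number(te, "te", lower = 0, upper = 1, strict_lower = TRUE)
  if (te >= 1) stop("`te` must be in (0, 1)", call. = FALSE)
  structure(list(cr = cr, te = te), class = "ppr_params")
}

#' Compute primary production required from catch records
#'
#' Applies the trophic back-calculation to every record and aggregates:
#' per cell, per EEZ country, or globally, always keeping years separate.
#' PPR is additive over disjoint groups and linear in tonnage.
#'
#' @param catches Catch table with `year`, `cell_id`, `taxon`, `tonnage`.
#' @param taxa Tibble with `taxon` and `tl`; every catch taxon must appear.
#' @param params A [ppr_params()] list.
#' @param group_by One of `"cell"`, `"eez"`, `"global"`.
#' @param world Required for `group_by = "eez"`: an `of_world` whose EEZ
#'   assignment maps cells to countries; non-EEZ catch is dropped from the
#'   EEZ aggregation.
#' @return A tibble with `year`, a group column (`cell_id` / `country` /
#'   none) and `ppr` in tonnes C per year.
#' @export
compute_ppr <- function(catches, taxa, params = ppr_params(),
                        group_by = c("cell", "eez", "global"),
                        world = NULL) {
  group_by <- match.arg(group_by)
  taxa <- as_tibble(taxa)
  tl <- taxa$tl[match(catches$taxon, taxa$taxon)]
  if (anyNA(tl)) {
    missing <- unique(catches$taxon[is.na(tl)])
    stop("no trophic level for taxon: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tl < 1)) stop("trophic level < 1", call. = FALSE)
  if (any(catches$tonnage < 0)) stop("negative tonnage", call. = FALSE)

  rec <- tibble(year = catches$year, cell_id = catches$cell_id,
                ppr = record_ppr(catches$tonnage, tl, params))
  switch(group_by,
    cell = rec |> group_by(.data$year, .data$cell_id) |>
      summarise(ppr = sum(.data$ppr), .groups = "drop"),
    global = rec |> group_by(.data$year) |>
      summarise(ppr = sum(.data$ppr), .groups = "drop"),
    eez = {
      if (is.null(world)) stop("`world` needed for EEZ grouping",
                               call. = FALSE)
      rec$country <- world$eez$country[match(rec$cell_id,
                                             world$eez$cell_id)]
      rec |> filter(!is.na(.data$country)) |>
        group_by(.data$year, .data$country) |>
        summarise(ppr = sum(.data$ppr), .groups = "drop")
    })
}

record_ppr <- function(tonnage, tl, params) {
  (tonnage / params$cr) * (1 / params$te)^(tl - 1)
}

#' Exploitation-ratio field and exploitation-band areas
#'
#' Computes the per-cell ratio of primary production required to available
#' primary production (multi-year mean field), then sums cell areas into
#' three exploitation bands per year: ratio in `[0.10, 0.20)`,
#' `[0.20, 0.30)` and `[0.30, Inf)` by default (half-open to the left so the
#' bands are disjoint and exhaust everything above the lowest threshold).
#'
#' @param catches Catch table.
#' @param pp An `of_ppfields` (its multi-year `summary` is used).
#' @param grid An `of_grid`.
#' @param taxa Taxon/trophic-level table.
#' @param params A [ppr_params()] list.
#' @param thresholds Increasing band edges (proportions), default
#'   `c(0.10, 0.20, 0.30)`.
#' @return List with `ratio` (tibble `year`, `cell_id`, `ppr`, `pp`,
#'   `ratio`) and `bands` (tibble `year`, `area_10_20`, `area_20_30`,
#'   `area_ge30`, each in km^2 x 10^6).
#' @export
ratio_and_bands <- function(catches, pp, grid, taxa,
                            params = ppr_params(),
                            thresholds = c(0.10, 0.20, 0.30)) {
  stopifnot(inherits(grid, "of_grid"), length(thresholds) == 3,
            !is.unsorted(thresholds, strictly = TRUE))
  by_cell <- compute_ppr(catches, taxa, params, group_by = "cell")
  pp_mean <- pp$summary$pp_mean[match(by_cell$cell_id, pp$summary$cell_id)]
  cell_ok <- grid$cells$sea[match(by_cell$cell_id, grid$cells$cell_id)]
  if (anyNA(pp_mean) || any(!cell_ok) || any(pp_mean <= 0)) {
    stop("catch on a land or zero-production cell", call. = FALSE)
  }
  ratio <- tibble(year = by_cell$year, cell_id = by_cell$cell_id,
                  ppr = by_cell$ppr, pp = pp_mean,
                  ratio = by_cell$ppr / pp_mean)

  area <- grid$cells$area_km2[match(ratio$cell_id, grid$cells$cell_id)]
  band <- cut(ratio$ratio, c(thresholds, Inf), right = FALSE,
              labels = c("area_10_20", "area_20_30", "area_ge30"))
  years <- sort(unique(catches$year))
  bands <- tibble(year = years, area_10_20 = 0, area_20_30 = 0,
                  area_ge30 = 0)
  keep <- !is.na(band)
  if (any(keep)) {
    agg <- stats::aggregate(area[keep] / 1e6,
                            list(year = ratio$year[keep],
                                 band = band[keep]), sum)
    for (i in seq_len(nrow(agg))) {
      bands[bands$year == agg$year[i], as.character(agg$band[i])] <-
        agg$x[i]
    }
  }
  list(ratio = ratio, bands = bands)
}

#' Percentage of accessible-ocean primary production used by fishing
#'
#' Accessible ocean is every sea cell shallower than `depth_limit` metres
#' (strict comparison). For each year the statistic is
#' `100 * sum(PPR over accessible cells) / sum(mean PP over accessible
#' cells)`; catch in deeper cells is excluded from the numerator and deep
#' cells' production from the denominator.
#'
#' @inheritParams ratio_and_bands
#' @param depth_limit Metres, default 1000.
#' @return Tibble with `year` and `percent`.
#' @export
accessible_percentage <- function(catches, pp, grid, taxa,
                                  params = ppr_params(),
                                  depth_limit = 1000) {
  stopifnot(inherits(grid, "of_grid"))
  acc <- grid$cells$sea & !is.na(grid$cells$depth_m) &
    grid$cells$depth_m < depth_limit
  acc_ids <- grid$cells$cell_id[acc]
  if (length(acc_ids) == 0) {
    stop("no accessible cells shallower than depth limit", call. = FALSE)
  }
  pp_acc <- sum(pp$summary$pp_mean[pp$summary$cell_id %in% acc_ids])
  years <- sort(unique(catches$year))
  if (length(years) == 0) return(tibble(year = integer(), percent = numeric()))

  by_cell <- compute_ppr(catches, taxa, params, group_by = "cell")
  by_cell <- by_cell[by_cell$cell_id %in% acc_ids, ]
  out <- tibble(year = years, percent = 0)
  if (nrow(by_cell) > 0) {
    ppr_y <- by_cell |> group_by(.data$year) |>
      summarise(ppr = sum(.data$ppr), .groups = "drop")
    out$percent[match(ppr_y$year, out$year)] <- 100 * ppr_y$ppr / pp_acc
  }
  out
}

#' Monte Carlo configuration for the accessible-percentage estimate
#'
#' Per trial, the transfer efficiency is drawn from a truncated normal
#' (default mean 10%, s.d. 3.03 percentage points — the spread whose
#' central 90% roughly spans 5-15% — truncated to 5-15%), and total
#' accessible production is scaled by a single global factor drawn from a
#' normal with the mean and s.d. of the annual accessible-PP totals.
#'
#' @param n_trials Trials per year (default 1000).
#' @param te_mean,te_sd Transfer-efficiency distribution (proportions).
#' @param te_bounds Truncation interval for TE draws.
#' @param seed Integer seed.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_trials = 1000, te_mean = 0.10, te_sd = 0.0303,
                      te_bounds = c(0.05, 0.15), seed = 1L) {
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  stopifnot(te_bounds[1] > 0, te_bounds[2] < 1,
            te_bounds[1] <= te_mean, te_mean <= te_bounds[2])
  structure(list(n_trials = as.integer(n_trials), te_mean = te_mean,
                 te_sd = te_sd, te_bounds = te_bounds,
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Monte Carlo accessible-percentage with confidence limits
#'
#' Propagates the two dominant uncertainties through the accessible
#' percentage: the transfer efficiency between trophic levels and the level
#' of global primary production. Each trial recomputes the percentage with
#' a fresh truncated-normal TE and a global PP level drawn from a normal
#' fitted to the interannual accessible totals. The yearly summary is the
#' trial median and the ranked 2.5/97.5 percentiles.
#'
#' With both variances zero every trial equals the deterministic
#' [accessible_percentage()] exactly.
#'
#' @inheritParams accessible_percentage
#' @param mc An [mc_config()].
#' @return Tibble with `year`, `median`, `ci_low`, `ci_high`,
#'   `pp_degenerate` (TRUE when only one PP year was available so the PP
#'   s.d. is zero).
#' @export
mc_accessible_percentage <- function(catches, pp, grid, taxa,
                                     mc = mc_config(),
                                     params = ppr_params(),
                                     depth_limit = 1000) {
  stopifnot(inherits(mc, "mc_config"), inherits(grid, "of_grid"))
  acc <- grid$cells$sea & !is.na(grid$cells$depth_m) &
    grid$cells$depth_m < depth_limit
  acc_ids <- grid$cells$cell_id[acc]
  if (length(acc_ids) == 0) {
    stop("no accessible cells shallower than depth limit", call. = FALSE)
  }
  # interannual distribution of total accessible production
  ann <- pp$annual[pp$annual$cell_id %in% acc_ids, ]
  totals <- vapply(split(ann$pp, ann$year), sum, numeric(1))
  pp_mu <- mean(totals)
  pp_sd <- if (length(totals) > 1) stats::sd(totals) else 0
  pp_degenerate <- length(totals) < 2

  tl <- taxa$tl[match(catches$taxon, taxa$taxon)]
  if (anyNA(tl)) stop("no trophic level for some catch taxon", call. = FALSE)
  keep <- catches$cell_id %in% acc_ids
  # collapse to carbon-converted tonnage per (year, TL): the TE power only
  # depends on TL, so trials cost O(n_TL) not O(n_records)
  carbon <- stats::aggregate(
    list(c_carbon = catches$tonnage[keep] / params$cr),
    list(year = catches$year[keep], tl = tl[keep]), sum)

  years <- sort(unique(catches$year))
  with_seed(mc$seed, {
    te <- rtruncnorm(mc$n_trials, mc$te_mean, mc$te_sd,
                     mc$te_bounds[1], mc$te_bounds[2])
    pp_draw <- if (pp_sd == 0) rep(pp_mu, mc$n_trials) else
      stats::rnorm(mc$n_trials, pp_mu, pp_sd)
  })
  pp_draw[pp_draw <= 0] <- pp_mu  # guard: production level must stay positive

  out <- lapply(years, function(y) {
    sub <- carbon[carbon$year == y, ]
    # trials x TL matrix of (1/TE)^(TL-1)
    ppr_trials <- if (nrow(sub) == 0) rep(0, mc$n_trials) else
      as.vector(outer(1 / te, sub$tl - 1, `^`) %*% sub$c_carbon)
    pct <- 100 * ppr_trials / pp_draw
    tibble(year = y, median = stats::median(pct),
           ci_low = stats::quantile(pct, 0.025, names = FALSE, type = 1),
           ci_high = stats::quantile(pct, 0.975, names = FALSE, type = 1),
           pp_degenerate = pp_degenerate)
  })
  bind_rows(out)
}

#' Per-country EEZ exploitation and consumption summary
#'
#' For every country: the percentage of the mean primary production inside
#' its EEZ that the catch taken there requires
#' (`100 * PPR(EEZ catch) / PP(EEZ)`, averaged per year when the catch table
#' spans several years), and per-capita seafood consumption in kg.
#'
#' @inheritParams ratio_and_bands
#' @param world An `of_world`.
#' @param consumption_by_country Named numeric, tonnes per year.
#' @param population_by_country Named numeric, persons.
#' @return Tibble with `country`, `ppr_percent`, `per_capita_kg`.
#' @export
eez_summary <- function(catches, pp, world, taxa, params = ppr_params(),
                        consumption_by_country = numeric(),
                        population_by_country = numeric()) {
  stopifnot(inherits(world, "of_world"))
  n_years <- length(unique(catches$year))
  ppr_eez <- compute_ppr(catches, taxa, params, group_by = "eez",
                         world = world)
  ppr_tot <- vapply(split(ppr_eez$ppr, ppr_eez$country), sum, numeric(1))

  out <- tibble(country = world$countries, ppr_percent = 0,
                per_capita_kg = NA_real_)
  for (i in seq_along(out$country)) {
    ctry <- out$country[i]
    ids <- world$eez$cell_id[world$eez$country == ctry]
    pp_eez <- sum(pp$summary$pp_mean[pp$summary$cell_id %in% ids])
    has_catch <- ctry %in% names(ppr_tot)
    if (length(ids) > 0 && pp_eez <= 0 && has_catch) {
      stop(sprintf("country %s has an EEZ with zero production", ctry),
           call. = FALSE)
    }
    if (has_catch) {
      out$ppr_percent[i] <- 100 * (ppr_tot[[ctry]] / max(n_years, 1)) / pp_eez
    }
    if (ctry %in% names(consumption_by_country)) {
      popn <- population_by_country[[ctry]]
      if (is.null(popn) || is.na(popn) || popn <= 0) {
        stop(sprintf("country %s has consumption but no population", ctry),
             call. = FALSE)
      }
      out$per_capita_kg[i] <- 1000 * consumption_by_country[[ctry]] / popn
    }
  }
  out
}
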