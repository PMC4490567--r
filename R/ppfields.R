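#' Generate annual primary-production fields
#'
#' Emulates a multi-year archive of satellite-derived net primary production.
#' Each sea cell receives a fixed spatial rate (tonnes C km^-2 yr^-1) drawn
#' from a lognormal field with arithmetic mean `mean_pp` and coefficient of
#' variation `spatial_cv`, multiplied by cell area to give tonnes C yr^-1 per
#' cell. Interannual variability multiplies each (cell, year) by an
#' independent lognormal factor with mean 1 and cv `interannual_cv`.
#'
#' @param grid An `of_grid`.
#' @param years Integer vector of years (e.g. `1998:2007`).
#' @param mean_pp Mean areal production rate, tonnes C km^-2 yr^-1.
#' @param spatial_cv,interannual_cv Coefficients of variation (>= 0). Both
#'   zero makes every cell-year exactly `mean_pp * area`.
#' @param seed Integer seed.
#' @return An object of class `of_ppfields`: list with `annual` (tibble
#'   `year`, `cell_id`, `pp` in tonnes C yr^-1), `summary` (tibble `cell_id`,
#'   `pp_mean`, `pp_sd` across years) and `years`.
#' @export
generate_pp_fields <- function(grid, years, mean_pp = 150,
                               spatial_cv = 0.5, interannual_cv = 0.05,
                               seed = 1L) {
  stopifnot(inherits(grid, "of_grid"))
  assert_scalar_number(mean_pp, "mean_pp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(spatial_cv, "spatial_cv", lower = 0)
  assert_scalar_number(interannual_cv, "interannual_cv", lower = 0)
  sc <- sea_cells(grid)
  if (nrow(sc) == 0) stop("grid has no sea cells", call. = FALSE)
  years <- as.integer(years)
  n_y <- length(years)
  stopifnot(n_y >= 1)

  with_seed(seed, {
    rate <- rlnorm_mean_cv(nrow(sc), mean_pp, spatial_cv)
    base <- rate * sc$area_km2
    factor <- rlnorm_mean_cv(nrow(sc) * n_y, 1, interannual_cv)
  })

  annual <- tibble(
    year = rep(years, each = nrow(sc)),
    cell_id = rep(sc$cell_id, times = n_y),
    pp = rep(base, times = n_y) * factor
  )
  summary <- annual |>
    group_by(.data$cell_id) |>
    summarise(pp_mean = mean(.data$pp),
              pp_sd = if (n() > 1) stats::sd(.data$pp) else 0,
              .groups = "drop")
  # zero interannual noise must give exactly zero spread
  if (interannual_cv == 0) summary$pp_sd <- 0

  structure(list(annual = annual, summary = summary, years = years),
            class = "of_ppfields")
}

#' @export
print.of_ppfields <- function(x, ...) {
  cat(sprintf("<of_ppfields> %d cells x %d years, total PP %.3g t C/yr\n",
              nrow(x$summary), length(x$years), sum(x$summary$pp_mean)))
  invisible(x)
}
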