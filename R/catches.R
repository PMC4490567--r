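#' Generate calibrated wild-capture catch records
#'
#' Places catch records on sea cells with a known, recoverable footprint: in
#' every seeded cell the tonnage is calibrated so that the implied primary
#' production required (at `CR = 9`, `TE = 0.1` unless other calibration
#' parameters are supplied) equals `target_ppr_fraction` times the cell's
#' multi-year mean production in the first year. An effort trend multiplies
#' tonnages by `(1 + effort_trend)` per elapsed year. Each seeded cell
#' carries one or more taxa; the cell's PPR budget is split across them by
#' random shares and inverted through the trophic ladder, so recomputing
#' PPR/PP on the output recovers the target exactly.
#'
#' Catches in EEZ cells belong to the EEZ country; high-seas catches are
#' attributed to a random fishing country.
#'
#' @param world An `of_world`.
#' @param grid An `of_grid`.
#' @param pp An `of_ppfields` built on the same grid.
#' @param years Integer years to simulate.
#' @param effort_trend Year-on-year proportional change in tonnage.
#' @param target_ppr_fraction PPR/PP ratio to calibrate in seeded cells,
#'   in `(0, 1)`.
#' @param coverage Fraction of sea cells receiving catch (default all).
#' @param max_taxa_per_cell Upper bound on taxa seeded per cell.
#' @param calib Calibration parameters, a [ppr_params()] list.
#' @param seed Integer seed.
#' @return A tibble of class `of_catches` with columns `year`, `cell_id`,
#'   `country`, `taxon`, `tonnage` (tonnes wet weight).
#' @export
generate_catches <- function(world, grid, pp, years,
                             effort_trend = 0, target_ppr_fraction = 0.1,
                             coverage = 1, max_taxa_per_cell = 3,
                             calib = ppr_params(), seed = 1L) {
  stopifnot(inherits(world, "of_world"), inherits(grid, "of_grid"),
            inherits(pp, "of_ppfields"))
  assert_scalar_number(target_ppr_fraction, "target_ppr_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  if (target_ppr_fraction >= 1) {
    stop("`target_ppr_fraction` must be in (0, 1)", call. = FALSE)
  }
  assert_scalar_number(coverage, "coverage", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (length(world$countries) == 0 || nrow(world$taxa) == 0) {
    stop("world has no countries or no taxa", call. = FALSE)
  }
  years <- as.integer(years)

  sc <- sea_cells(grid)
  pp_mean <- pp$summary$pp_mean[match(sc$cell_id, pp$summary$cell_id)]
  keep <- !is.na(pp_mean)
  sc <- sc[keep, ]; pp_mean <- pp_mean[keep]
  taxa <- world$taxa

  with_seed(seed, {
    n_seed <- max(1L, round(coverage * nrow(sc)))
    idx <- if (n_seed == nrow(sc)) seq_len(nrow(sc)) else
      sort(sample.int(nrow(sc), n_seed))
    n_tax <- sample.int(min(max_taxa_per_cell, nrow(taxa)), n_seed,
                        replace = TRUE)
    cell_tax <- lapply(seq_len(n_seed), function(i) {
      j <- sample.int(nrow(taxa), n_tax[i])
      w <- stats::runif(n_tax[i]); w <- w / sum(w)
      tibble(cell_id = sc$cell_id[idx[i]], taxon = taxa$taxon[j],
             tl = taxa$tl[j], share = w,
             ppr_budget = target_ppr_fraction * pp_mean[idx[i]] * w)
    })
    hs_country <- sample(world$countries, n_seed, replace = TRUE)
  })
  base <- bind_rows(cell_tax)
  # invert PPR = (C/CR) * (1/TE)^(TL-1)  =>  C = PPR * CR * TE^(TL-1)
  base$tonnage0 <- base$ppr_budget * calib$cr * calib$te^(base$tl - 1)

  eez_country <- world$eez$country[match(base$cell_id, world$eez$cell_id)]
  hs <- rep(hs_country, times = vapply(cell_tax, nrow, 1L))
  base$country <- ifelse(is.na(eez_country), hs, eez_country)

  out <- lapply(seq_along(years), function(k) {
    tibble(year = years[k], cell_id = base$cell_id, country = base$country,
           taxon = base$taxon,
           tonnage = base$tonnage0 * (1 + effort_trend)^(k - 1))
  })
  out <- bind_rows(out)
  out <- out[out$tonnage > 0, ]
  class(out) <- c("of_catches", class(out))
  out
}
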