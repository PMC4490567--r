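#' Generate export/import flows with known provenance
#'
#' Emulates trade records for a virtual global seafood market. A fixed
#' fraction of every catch record's tonnage is exported to a randomly drawn
#' importing country; the remainder is consumed domestically. Mariculture
#' production per country is traded with the same export fraction. Every
#' traded row retains ground-truth provenance (the originating catch cell
#' for wild flows, the origin country for mariculture), which downstream
#' matching code must not read — it exists to validate the matcher.
#'
#' @param world An `of_world`.
#' @param catches An `of_catches` table.
#' @param mariculture_by_country Named numeric vector, tonnes per year per
#'   producing country (names must be world countries). May be empty.
#' @param export_fraction Share of production exported, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble of class `of_trade`: `year`, `exporter`, `importer`,
#'   `source_kind` (`"wild"` or `"mariculture"`), `taxon`, `tonnage`,
#'   `src_cell_id` (wild provenance), `origin_country`.
#' @export
generate_trade <- function(world, catches, mariculture_by_country = numeric(),
                           export_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(world, "of_world"))
  assert_scalar_number(export_fraction, "export_fraction",
                       lower = 0, upper = 1)
  if (any(mariculture_by_country < 0)) {
    stop("mariculture tonnage must be >= 0", call. = FALSE)
  }
  if (length(mariculture_by_country) > 0 &&
      !all(names(mariculture_by_country) %in% world$countries)) {
    stop("unknown mariculture country", call. = FALSE)
  }
  empty <- tibble(year = integer(), exporter = character(),
                  importer = character(), source_kind = character(),
                  taxon = character(), tonnage = numeric(),
                  src_cell_id = integer(), origin_country = character())
  years <- sort(unique(catches$year))
  if (export_fraction == 0 || length(world$countries) < 2) {
    if (export_fraction > 0 && length(world$countries) < 2) {
      warning("fewer than two countries: no trade generated")
    }
    class(empty) <- c("of_trade", class(empty))
    return(empty)
  }

  draw_importer <- function(exporter) {
    pool <- setdiff(world$countries, exporter)
    pool[sample.int(length(pool), 1)]
  }

  with_seed(seed, {
    wild <- catches
    wild$importer <- vapply(wild$country, draw_importer, character(1))
    wild <- tibble(year = wild$year, exporter = wild$country,
                   importer = wild$importer, source_kind = "wild",
                   taxon = wild$taxon,
                   tonnage = export_fraction * wild$tonnage,
                   src_cell_id = wild$cell_id, origin_country = wild$country)

    mar <- empty
    if (length(mariculture_by_country) > 0) {
      grid_m <- expand.grid(year = years,
                            exporter = names(mariculture_by_country),
                            stringsAsFactors = FALSE)
      mar <- tibble(
        year = as.integer(grid_m$year), exporter = grid_m$exporter,
        importer = vapply(grid_m$exporter, draw_importer, character(1)),
        source_kind = "mariculture", taxon = "mariculture",
        tonnage = export_fraction *
          mariculture_by_country[grid_m$exporter],
        src_cell_id = NA_integer_, origin_country = grid_m$exporter)
      mar <- mar[mar$tonnage > 0, ]
    }
  })
  out <- bind_rows(wild[wild$tonnage > 0, ], mar)
  class(out) <- c("of_trade", class(out))
  out
}
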