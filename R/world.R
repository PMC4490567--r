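#' Generate countries, EEZs, ports, taxa and populations
#'
#' Partitions a share of the grid's sea cells into contiguous exclusive
#' economic zone (EEZ) blocks, one per country; the remaining sea cells are
#' high seas. Sea cells touching a land cell (4-neighbourhood) are coastal;
#' on an all-sea grid every sea cell counts as coastal. Each country gets
#' `n_ports` synthetic ports placed at centres of coastal cells in its EEZ
#' (falling back to any EEZ cell when its block has no coast). Taxa carry
#' assigned trophic levels in `[1, 5]`.
#'
#' @param grid An `of_grid`.
#' @param n_countries Number of countries (>= 1).
#' @param taxa_spec Tibble or data.frame with columns `taxon` and `tl`.
#' @param eez_fraction Share of sea cells claimed as EEZ, in `(0, 1]`.
#' @param n_ports Ports per country (>= 1).
#' @param years Years for the per-country population series.
#' @param pop_base Mean national population, persons.
#' @param pop_growth Annual national population growth rate.
#' @param seed Integer seed.
#' @return An object of class `of_world`: list with `countries` (character),
#'   `eez` (tibble `cell_id`, `country`; high-seas cells absent), `ports`
#'   (tibble `country`, `port_id`, `lat`, `lon`), `coastal` (tibble
#'   `country`, `cell_id`), `taxa` (tibble `taxon`, `tl`) and `population`
#'   (tibble `country`, `year`, `population`).
#' @export
generate_world <- function(grid, n_countries, taxa_spec,
                           eez_fraction = 0.8, n_ports = 1,
                           years = 2000:2009, pop_base = 1e7,
                           pop_growth = 0.01, seed = 1L) {
  stopifnot(inherits(grid, "of_grid"))
  assert_scalar_number(n_countries, "n_countries", lower = 1)
  assert_scalar_number(eez_fraction, "eez_fraction", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(n_ports, "n_ports", lower = 1)
  taxa_spec <- as_tibble(taxa_spec)
  stopifnot(all(c("taxon", "tl") %in% names(taxa_spec)))
  if (any(taxa_spec$tl < 1 | taxa_spec$tl > 5)) {
    stop("trophic levels must lie in [1, 5]", call. = FALSE)
  }
  if (anyDuplicated(taxa_spec$taxon)) {
    stop("duplicate taxon names in `taxa_spec`", call. = FALSE)
  }
  n_countries <- as.integer(n_countries)

  cells <- grid$cells
  sc <- sea_cells(grid)
  coastal_ids <- coastal_cell_ids(grid)
  if (n_countries > length(coastal_ids)) {
    stop(sprintf("cannot place %d countries on %d coastal cells",
                 n_countries, length(coastal_ids)), call. = FALSE)
  }
  countries <- sprintf("C%02d", seq_len(n_countries))

  # contiguous blocks: scan sea cells column-major so each country's claim
  # is a vertical strip of the ocean
  ord <- order(sc$col, sc$row)
  claimed_n <- max(n_countries, ceiling(eez_fraction * nrow(sc)))
  claimed <- sc$cell_id[ord][seq_len(min(claimed_n, nrow(sc)))]
  block <- if (n_countries == 1) rep(1L, length(claimed)) else
    cut(seq_along(claimed), breaks = n_countries, labels = FALSE)
  eez <- tibble(cell_id = claimed, country = countries[block])

  coastal <- eez[eez$cell_id %in% coastal_ids, ]
  # a country whose strip misses the coast keeps its EEZ cells as the
  # port-bearing "coastal" set so every country remains reachable
  for (ctry in setdiff(countries, unique(coastal$country))) {
    coastal <- bind_rows(coastal, eez[eez$country == ctry, ])
  }
  coastal <- arrange(coastal, .data$country, .data$cell_id)

  with_seed(seed, {
    ports <- lapply(countries, function(ctry) {
      ids <- coastal$cell_id[coastal$country == ctry]
      pick <- ids[sample.int(length(ids), min(n_ports, length(ids)))]
      cc <- cells[match(pick, cells$cell_id), ]
      tibble(country = ctry, port_id = seq_along(pick),
             lat = cc$lat, lon = cc$lon)
    })
    pop0 <- rlnorm_mean_cv(n_countries, pop_base, 0.5)
  })
  ports <- bind_rows(ports)

  population <- tibble(
    country = rep(countries, each = length(years)),
    year = rep(as.integer(years), times = n_countries),
    population = rep(pop0, each = length(years)) *
      (1 + pop_growth)^rep(seq_along(years) - 1, times = n_countries)
  )

  structure(
    list(countries = countries, eez = eez, ports = ports, coastal = coastal,
         taxa = taxa_spec[, c("taxon", "tl")], population = population),
    class = "of_world"
  )
}

#' @export
print.of_world <- function(x, ...) {
  cat(sprintf("<of_world> %d countries, %d EEZ cells, %d ports, %d taxa\n",
              length(x$countries), nrow(x$eez), nrow(x$ports), nrow(x$taxa)))
  invisible(x)
}

# Sea cells with a 4-neighbour land cell; all sea cells on an all-sea grid.
coastal_cell_ids <- function(grid) {
  cells <- grid$cells
  if (all(cells$sea)) return(cells$cell_id)
  sea_m <- matrix(cells$sea[order(cells$cell_id)], nrow = grid$n_lat,
                  ncol = grid$n_lon, byrow = TRUE)
  land <- !sea_m
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  near_land <- pad(land, 1, 0) | pad(land, -1, 0) |
    pad(land, 0, 1) | pad(land, 0, -1)
  coastal <- sea_m & near_land
  ids <- cells$cell_id[order(cells$cell_id)][as.vector(t(coastal))]
  if (length(ids) == 0) ids <- cells$cell_id[cells$sea]
  ids
}
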