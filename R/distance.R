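#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km. Vectorized over all
#' four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; latitudes in
#'   `[-90, 90]`, longitudes in `[-180, 180]`.
#' @return Distance(s) in km, bounded by `pi * R` = 20,015.09 km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 180)  # half the circumference
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Minimum distance from an origin to a set of ports
#'
#' @param lat,lon Origin coordinates, degrees.
#' @param ports Tibble with `lat` and `lon` (one row per port); must be
#'   non-empty. Ties are broken by the lowest port row index.
#' @return List with `km` and `port` (row index of the chosen port).
#' @export
min_port_distance <- function(lat, lon, ports) {
  if (is.null(ports) || nrow(ports) == 0) {
    stop("empty port list", call. = FALSE)
  }
  d <- haversine_km(lat, lon, ports$lat, ports$lon)
  i <- which.min(d)
  list(km = d[i], port = i)
}

#' Match export records to mapped catches
#'
#' Resolves the capture location of exported wild seafood with a
#' deterministic three-tier hierarchy:
#' \enumerate{
#'   \item exact (exporter, year, taxon) match — the exported tonnage is
#'     allocated across that taxon's catch cells pro-rata by catch tonnage;
#'   \item residue with no taxon match is allocated across all of the
#'     exporter's catch cells that year, again pro-rata;
#'   \item anything still unallocated (exports exceeding the exporter's
#'     recorded catch) is flagged unmatched, with a warning — never
#'     silently dropped.
#' }
#' Total tonnage is conserved: matched + unmatched equals the exported
#' total.
#'
#' @param catches Catch table (`year`, `cell_id`, `country`, `taxon`,
#'   `tonnage`).
#' @param exports Trade table rows with `source_kind == "wild"`.
#' @return List with `matched` (tibble `year`, `exporter`, `importer`,
#'   `taxon`, `cell_id`, `tonnage`, `tier`) and `unmatched` (tibble `year`,
#'   `exporter`, `importer`, `taxon`, `tonnage`).
#' @export
match_exports_to_catches <- function(catches, exports) {
  exports <- exports[exports$source_kind == "wild", , drop = FALSE]
  matched <- list(); unmatched <- list()
  if (nrow(exports) > 0) {
    agg <- stats::aggregate(list(tonnage = exports$tonnage),
                            exports[c("year", "exporter", "importer",
                                      "taxon")], sum)
  } else {
    agg <- exports[c("year", "exporter", "importer", "taxon", "tonnage")]
  }

  for (i in seq_len(nrow(agg))) {
    yr <- agg$year[i]; exp_c <- agg$exporter[i]
    need <- agg$tonnage[i]
    pool_all <- catches[catches$year == yr & catches$country == exp_c, ]
    pool_tax <- pool_all[pool_all$taxon == agg$taxon[i], ]
    total_cap <- sum(pool_all$tonnage)

    # tier 1: same taxon, pro-rata over its cells, capped by availability
    t1 <- min(need, sum(pool_tax$tonnage), total_cap)
    if (t1 > 0) {
      w <- pool_tax$tonnage / sum(pool_tax$tonnage)
      matched[[length(matched) + 1]] <- tibble(
        year = yr, exporter = exp_c, importer = agg$importer[i],
        taxon = agg$taxon[i], cell_id = pool_tax$cell_id,
        tonnage = t1 * w, tier = 1L)
    }
    # tier 2: residue over all taxa, capped by what tier 1 left available
    rem <- need - t1
    t2 <- min(rem, total_cap - t1)
    if (t2 > 0) {
      w <- pool_all$tonnage / total_cap
      matched[[length(matched) + 1]] <- tibble(
        year = yr, exporter = exp_c, importer = agg$importer[i],
        taxon = agg$taxon[i], cell_id = pool_all$cell_id,
        tonnage = t2 * w, tier = 2L)
    }
    # tier 3: flag the remainder
    rem <- rem - t2
    if (rem > 1e-9) {
      unmatched[[length(unmatched) + 1]] <- tibble(
        year = yr, exporter = exp_c, importer = agg$importer[i],
        taxon = agg$taxon[i], tonnage = rem)
    }
  }
  matched <- if (length(matched)) bind_rows(matched) else
    tibble(year = integer(), exporter = character(), importer = character(),
           taxon = character(), cell_id = integer(), tonnage = numeric(),
           tier = integer())
  unmatched <- if (length(unmatched)) bind_rows(unmatched) else
    tibble(year = integer(), exporter = character(), importer = character(),
           taxon = character(), tonnage = numeric())
  if (nrow(unmatched) > 0) {
    warning(sprintf("%.3g t of exports exceed recorded catches (flagged)",
                    sum(unmatched$tonnage)))
  }
  list(matched = matched, unmatched = unmatched)
}

#' Assemble per-year seafood distance records
#'
#' Builds the record set behind the yearly sourcing-distance estimate.
#' Four sourcing categories are distinguished:
#' \itemize{
#'   \item `domestic_wild` — catch consumed by the catching country;
#'     distance from the catch cell centre to the nearest domestic port;
#'   \item `imported_wild` — matched exports; distance from the catch cell
#'     to the nearest port of the importing country;
#'   \item `imported_mariculture` — minimum distance between any coastal
#'     cell of the origin country and any port of the importer;
#'   \item `domestic_mariculture` — distance exactly 0.
#' }
#'
#' @param world An `of_world`.
#' @param grid An `of_grid`.
#' @param matched Matched trade from [match_exports_to_catches()].
#' @param catches Catch table; domestic consumption is catch minus exports.
#' @param mariculture_domestic Tibble `year`, `country`, `tonnage` consumed
#'   where produced.
#' @param mariculture_imports Tibble `year`, `origin`, `importer`,
#'   `tonnage`.
#' @return Tibble of class `of_distance_records`: `year`, `category`,
#'   `country` (the consuming country), `distance_km`, `tonnage`.
#' @export
assemble_distance_records <- function(world, grid, matched = NULL,
                                      catches = NULL,
                                      mariculture_domestic = NULL,
                                      mariculture_imports = NULL) {
  stopifnot(inherits(world, "of_world"), inherits(grid, "of_grid"))
  cells <- grid$cells
  ports_of <- split(world$ports, world$ports$country)
  port_check <- function(ctry, what) {
    if (is.null(ports_of[[ctry]])) {
      stop(sprintf("consuming country %s has no ports (%s)", ctry, what),
           call. = FALSE)
    }
    ports_of[[ctry]]
  }
  nearest <- function(lat, lon, ctry, what) {
    min_port_distance(lat, lon, port_check(ctry, what))$km
  }
  out <- list()

  if (!is.null(catches) && nrow(catches) > 0) {
    exported <- if (!is.null(matched) && nrow(matched) > 0) {
      stats::aggregate(list(exported = matched$tonnage),
                       list(year = matched$year, country = matched$exporter,
                            taxon = matched$taxon,
                            cell_id = matched$cell_id), sum)
    } else NULL
    dom <- as_tibble(catches)
    if (!is.null(exported)) {
      dom <- left_join(dom, as_tibble(exported),
                       by = c("year", "country", "taxon", "cell_id"))
      dom$exported[is.na(dom$exported)] <- 0
      dom$tonnage <- dom$tonnage - dom$exported
    }
    dom <- dom[dom$tonnage > 1e-12, ]
    if (nrow(dom) > 0) {
      cc <- cells[match(dom$cell_id, cells$cell_id), ]
      d <- vapply(seq_len(nrow(dom)), function(i) {
        nearest(cc$lat[i], cc$lon[i], dom$country[i], "domestic wild")
      }, numeric(1))
      out[[length(out) + 1]] <- tibble(
        year = dom$year, category = "domestic_wild", country = dom$country,
        distance_km = d, tonnage = dom$tonnage)
    }
  }

  if (!is.null(matched) && nrow(matched) > 0) {
    cc <- cells[match(matched$cell_id, cells$cell_id), ]
    d <- vapply(seq_len(nrow(matched)), function(i) {
      nearest(cc$lat[i], cc$lon[i], matched$importer[i], "imported wild")
    }, numeric(1))
    out[[length(out) + 1]] <- tibble(
      year = matched$year, category = "imported_wild",
      country = matched$importer, distance_km = d,
      tonnage = matched$tonnage)
  }

  if (!is.null(mariculture_imports) && nrow(mariculture_imports) > 0) {
    mi <- as_tibble(mariculture_imports)
    d <- vapply(seq_len(nrow(mi)), function(i) {
      ids <- world$coastal$cell_id[world$coastal$country == mi$origin[i]]
      if (length(ids) == 0) {
        stop(sprintf("origin country %s has no coastal cells", mi$origin[i]),
             call. = FALSE)
      }
      oc <- cells[match(ids, cells$cell_id), ]
      pts <- port_check(mi$importer[i], "imported mariculture")
      pairs <- expand.grid(a = seq_len(nrow(oc)), b = seq_len(nrow(pts)))
      min(haversine_km(oc$lat[pairs$a], oc$lon[pairs$a],
                       pts$lat[pairs$b], pts$lon[pairs$b]))
    }, numeric(1))
    out[[length(out) + 1]] <- tibble(
      year = mi$year, category = "imported_mariculture",
      country = mi$importer, distance_km = d, tonnage = mi$tonnage)
  }

  if (!is.null(mariculture_domestic) && nrow(mariculture_domestic) > 0) {
    md <- as_tibble(mariculture_domestic)
    out[[length(out) + 1]] <- tibble(
      year = md$year, category = "domestic_mariculture",
      country = md$country, distance_km = 0, tonnage = md$tonnage)
  }

  res <- if (length(out)) bind_rows(out) else
    tibble(year = integer(), category = character(), country = character(),
           distance_km = numeric(), tonnage = numeric())
  res <- res[res$tonnage > 0, ]
  class(res) <- c("of_distance_records", class(res))
  res
}

#' Catch-weighted median
#'
#' The smallest value `v` such that the cumulative weight of all values
#' `<= v` reaches half the total weight (ties resolve to the lower value,
#' for determinism).
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @return The weighted median.
#' @export
weighted_median <- function(values, weights) {
  if (length(values) == 0 || length(values) != length(weights)) {
    stop("values and weights must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  v[which(cw >= cw[length(cw)] / 2)[1]]
}

#' Hierarchical bootstrap of the yearly sourcing-distance median
#'
#' For one year's records: each of `n_trials` bootstrap trials draws
#' `n_samples` records hierarchically — first the sourcing category, with
#' probability proportional to the category's published total tonnage, then
#' a record within the category (tonnage-weighted by default, uniform with
#' `within_weighted = FALSE`). The per-trial statistic is the catch-weighted
#' median of the sample: each sampled record is weighted by tonnage over
#' selection probability, so tonnage-weighted draws (whose frequencies
#' already carry the weighting) contribute equally while uniform draws are
#' importance-reweighted — both modes estimate the same catch-weighted
#' median. Confidence limits are the ranked
#' 2.5th/97.5th percentiles of the trial statistics; Shapiro-Wilk at
#' alpha = 0.05 flags non-normal trial distributions (the reason the median
#' rather than the mean summarizes the trials).
#'
#' @param records Distance records for a single year (`category`,
#'   `distance_km`, `tonnage`).
#' @param category_tonnages Named numeric of published per-category totals;
#'   defaults to the totals observed in `records`. A category with positive
#'   tonnage but no records is an error.
#' @param n_trials,n_samples Bootstrap design (defaults 1000 and 10000).
#' @param within_weighted Tonnage-weighted within-category sampling
#'   (default) or uniform.
#' @param seed Integer seed.
#' @return A one-row tibble: `median_km`, `ci_low_km`, `ci_high_km`,
#'   `normality_rejected`.
#' @export
bootstrap_median_distance <- function(records, category_tonnages = NULL,
                                      n_trials = 1000, n_samples = 10000,
                                      within_weighted = TRUE, seed = 1L) {
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  if (nrow(records) == 0) stop("no distance records", call. = FALSE)
  if (is.null(category_tonnages)) {
    category_tonnages <- vapply(split(records$tonnage, records$category),
                                sum, numeric(1))
  }
  category_tonnages <- category_tonnages[category_tonnages > 0]
  if (length(category_tonnages) == 0) {
    stop("all category tonnages are zero", call. = FALSE)
  }
  absent <- setdiff(names(category_tonnages), unique(records$category))
  if (length(absent) > 0) {
    stop("category with tonnage but no records: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cats <- names(category_tonnages)
  prob <- category_tonnages / sum(category_tonnages)
  # canonical within-category order makes the estimate invariant to the
  # caller's record order
  by_cat <- lapply(split(records, records$category)[cats], function(rc) {
    rc[order(rc$distance_km, rc$tonnage), , drop = FALSE]
  })

  # each record's selection probability under the two-stage draw; the
  # per-trial statistic weights sampled records by tonnage / probability,
  # so both sampling modes estimate the same catch-weighted median
  # (tonnage-weighted draws get constant weights — the plain sample median)
  total_t <- sum(category_tonnages)
  for (j in seq_along(cats)) {
    rc <- by_cat[[j]]
    q <- if (within_weighted) {
      prob[j] * rc$tonnage / sum(rc$tonnage)
    } else {
      rep(prob[j] / nrow(rc), nrow(rc))
    }
    by_cat[[j]]$iw <- rc$tonnage / (q * total_t)
  }

  stats_v <- with_seed(seed, {
    vapply(seq_len(n_trials), function(trial) {
      k <- as.vector(stats::rmultinom(1, n_samples, prob))
      d <- numeric(0); w <- numeric(0)
      for (j in seq_along(cats)) {
        if (k[j] == 0) next
        rc <- by_cat[[j]]
        pr <- if (within_weighted) rc$tonnage else NULL
        idx <- sample.int(nrow(rc), k[j], replace = TRUE, prob = pr)
        d <- c(d, rc$distance_km[idx])
        w <- c(w, rc$iw[idx])
      }
      weighted_median(d, w)
    }, numeric(1))
  })

  normality <- if (length(unique(stats_v)) > 2 && n_trials >= 3) {
    sw <- try(stats::shapiro.test(stats_v), silent = TRUE)
    if (inherits(sw, "try-error")) NA else sw$p.value < 0.05
  } else NA
  tibble(
    median_km = stats::median(stats_v),
    ci_low_km = stats::quantile(stats_v, 0.025, names = FALSE, type = 1),
    ci_high_km = stats::quantile(stats_v, 0.975, names = FALSE, type = 1),
    normality_rejected = normality
  )
}

#' Yearly sourcing-distance series with bootstrap confidence limits
#'
#' Runs [bootstrap_median_distance()] on every year present in the record
#' set. Years whose records carry zero total tonnage are skipped with a
#' warning.
#'
#' @param records Multi-year distance records.
#' @param n_trials,n_samples,within_weighted,seed Passed through; each
#'   year gets its own derived seed so the series is order-invariant.
#' @return Tibble with `year`, `median_km`, `ci_low_km`, `ci_high_km`,
#'   `normality_rejected`.
#' @export
distance_series <- function(records, n_trials = 1000, n_samples = 10000,
                            within_weighted = TRUE, seed = 1L) {
  years <- sort(unique(records$year))
  out <- list()
  for (y in years) {
    rec_y <- records[records$year == y, ]
    if (sum(rec_y$tonnage) <= 0) {
      warning(sprintf("year %d has zero tonnage; skipped", y))
      next
    }
    est <- bootstrap_median_distance(
      rec_y, n_trials = n_trials, n_samples = n_samples,
      within_weighted = within_weighted,
      seed = stage_seed(seed, paste0("distance_year_", y)))
    out[[length(out) + 1]] <- cbind(tibble(year = y), est)
  }
  if (length(out)) as_tibble(bind_rows(out)) else
    tibble(year = integer(), median_km = numeric(), ci_low_km = numeric(),
           ci_high_km = numeric(), normality_rejected = logical())
}
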