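test_that("the trophic back-calculation matches closed-form cases", {
  taxa <- tibble::tibble(taxon = c("a", "b"), tl = c(1, 3))
  ct <- tibble::tibble(year = 2000, cell_id = 0L,
                       taxon = "a", tonnage = 9)
  # TL 1: exponent zero, PPR = C / CR
  expect_equal(compute_ppr(ct, taxa, group_by = "global")$ppr, 1)
  # TL 3 at TE = 0.1: (1/0.1)^2 = 100
  ct$taxon <- "b"
  expect_equal(compute_ppr(ct, taxa, group_by = "global")$ppr, 100)
})

test_that("grouped PPR equals a per-record brute-force sum", {
  taxa <- default_taxa()
  set.seed(101)
  ct <- tibble::tibble(
    year = sample(2000:2002, 50, TRUE),
    cell_id = sample(0:9, 50, TRUE),
    taxon = sample(taxa$taxon, 50, TRUE),
    tonnage = runif(50, 1, 500))
  p <- ppr_params(cr = 9, te = 0.1)
  got <- sum(compute_ppr(ct, taxa, p, group_by = "global")$ppr)
  expect_equal(got, brute_ppr(ct, taxa, 9, 0.1), tolerance = 1e-9)
  # additivity over disjoint groups
  by_cell <- compute_ppr(ct, taxa, p, group_by = "cell")
  expect_equal(sum(by_cell$ppr), got, tolerance = 1e-12)
})

test_that("PPR is linear in tonnage, halved by doubled CR, increasing in TL", {
  taxa <- tibble::tibble(taxon = letters[1:3], tl = c(2, 3, 4))
  ct <- tibble::tibble(year = 2000, cell_id = 0L, taxon = c("a", "b"),
                       tonnage = c(10, 20))
  base <- compute_ppr(ct, taxa, ppr_params(), group_by = "global")$ppr
  ct2 <- ct; ct2$tonnage <- 3 * ct2$tonnage
  expect_equal(compute_ppr(ct2, taxa, ppr_params(),
                           group_by = "global")$ppr, 3 * base)
  expect_equal(compute_ppr(ct, taxa, ppr_params(cr = 18),
                           group_by = "global")$ppr, base / 2)
  one <- function(tx) compute_ppr(
    tibble::tibble(year = 2000, cell_id = 0L, taxon = tx, tonnage = 10),
    taxa, ppr_params(), group_by = "global")$ppr
  expect_true(one("a") < one("b") && one("b") < one("c"))
})

test_that("unknown taxa and bad trophic levels are hard errors", {
  taxa <- tibble::tibble(taxon = "a", tl = 2)
  ct <- tibble::tibble(year = 2000, cell_id = 0L, taxon = "mystery",
                       tonnage = 1)
  expect_error(compute_ppr(ct, taxa), "mystery")
  expect_error(ppr_params(te = 1.2), "te")
  expect_error(ppr_params(cr = 0), "cr")
})

test_that("band areas equal exhaustive per-cell classification", {
  tw <- tiny_world(seed = 5, target = 0.25, interannual_cv = 0)
  rb <- ratio_and_bands(tw$catches, tw$pp, tw$grid, default_taxa())
  expect_true(all(rb$ratio$ratio >= 0))

  # scan oracle: classify every (year, cell) by hand
  for (y in unique(rb$ratio$year)) {
    sub <- rb$ratio[rb$ratio$year == y, ]
    area <- tw$grid$cells$area_km2[match(sub$cell_id,
                                         tw$grid$cells$cell_id)]
    expect_equal(rb$bands$area_10_20[rb$bands$year == y],
                 sum(area[sub$ratio >= 0.10 & sub$ratio < 0.20]) / 1e6)
    expect_equal(rb$bands$area_20_30[rb$bands$year == y],
                 sum(area[sub$ratio >= 0.20 & sub$ratio < 0.30]) / 1e6)
    expect_equal(rb$bands$area_ge30[rb$bands$year == y],
                 sum(area[sub$ratio >= 0.30]) / 1e6)
  }
  # bands disjoint and bounded by the sea area
  sea_area <- sum(tw$grid$cells$area_km2[tw$grid$cells$sea]) / 1e6
  expect_true(all(rb$bands$area_10_20 + rb$bands$area_20_30 +
                    rb$bands$area_ge30 <= sea_area + 1e-9))
})

test_that("a single cell above the top threshold fills only the top band", {
  g <- generate_grid(1, 1, 0, seed = 1)
  pp <- generate_pp_fields(g, 2000, 100, 0, 0, seed = 1)
  taxa <- tibble::tibble(taxon = "t", tl = 1)
  # tonnage chosen so PPR/PP = 0.35
  ct <- tibble::tibble(year = 2000L, cell_id = 0L, taxon = "t",
                       tonnage = 0.35 * pp$summary$pp_mean * 9)
  rb <- ratio_and_bands(ct, pp, g, taxa)
  expect_equal(rb$bands$area_ge30, g$cells$area_km2 / 1e6)
  expect_equal(rb$bands$area_10_20 + rb$bands$area_20_30, 0)
})

test_that("accessible percentage equals masked brute-force sums", {
  tw <- tiny_world(seed = 8, depth_max = 3000)
  acc <- accessible_percentage(tw$catches, tw$pp, tw$grid, default_taxa())
  # mask-and-sum oracle
  cells <- tw$grid$cells
  acc_ids <- cells$cell_id[cells$sea & cells$depth_m < 1000]
  pp_sum <- sum(tw$pp$summary$pp_mean[tw$pp$summary$cell_id %in% acc_ids])
  for (y in unique(tw$catches$year)) {
    sub <- tw$catches[tw$catches$year == y &
                        tw$catches$cell_id %in% acc_ids, ]
    expect_equal(acc$percent[acc$year == y],
                 100 * brute_ppr(sub, default_taxa(), 9, 0.1) / pp_sum,
                 tolerance = 1e-9)
  }
})

test_that("a world calibrated to ratio 0.10 in every accessible cell gives 10%", {
  g <- generate_grid(5, 8, 0, list(min = 10, max = 900), seed = 3)
  pp <- generate_pp_fields(g, 2000:2002, 150, 0.4, 0, seed = 4)
  w <- generate_world(g, 2, default_taxa(), seed = 5)
  ct <- generate_catches(w, g, pp, 2000:2002, 0, 0.10, 1, seed = 6)
  acc <- accessible_percentage(ct, pp, g, default_taxa())
  expect_equal(acc$percent, rep(10, 3), tolerance = 1e-9)
  # zero catch: 0%
  acc0 <- accessible_percentage(ct[0, ], pp, g, default_taxa())
  expect_equal(nrow(acc0), 0)
})

test_that("depth masking excludes deep catch and errors without shallow cells", {
  g <- generate_grid(2, 2, 0, list(min = 2000, max = 3000), seed = 1)
  pp <- generate_pp_fields(g, 2000, 100, 0, 0, seed = 1)
  ct <- tibble::tibble(year = 2000L, cell_id = 0L, taxon = "t", tonnage = 1)
  expect_error(accessible_percentage(ct, pp, g,
                                     tibble::tibble(taxon = "t", tl = 2)),
               "accessible")
})

test_that("EEZ summary matches per-country masked sums and unit conversion", {
  tw <- tiny_world(seed = 13)
  w <- tw$world
  cons <- setNames(c(1, 2000, 0), w$countries)
  popn <- setNames(c(1000, 1e6, 1e6), w$countries)
  es <- eez_summary(tw$catches, tw$pp, w, default_taxa(),
                    consumption_by_country = cons,
                    population_by_country = popn)
  # 1 t over 1,000 people = 1 kg per capita
  expect_equal(es$per_capita_kg[es$country == w$countries[1]], 1)
  # brute-force masked sums per country
  n_years <- length(unique(tw$catches$year))
  for (ctry in w$countries) {
    ids <- w$eez$cell_id[w$eez$country == ctry]
    sub <- tw$catches[tw$catches$cell_id %in% ids, ]
    pp_eez <- sum(tw$pp$summary$pp_mean[tw$pp$summary$cell_id %in% ids])
    want <- 100 * (brute_ppr(sub, default_taxa(), 9, 0.1) / n_years) / pp_eez
    expect_equal(es$ppr_percent[es$country == ctry], want,
                 tolerance = 1e-9)
  }
})

test_that("Monte Carlo collapses to the deterministic value when variance is zero", {
  tw <- tiny_world(seed = 21, interannual_cv = 0)
  det <- accessible_percentage(tw$catches, tw$pp, tw$grid, default_taxa())
  mc <- mc_accessible_percentage(
    tw$catches, tw$pp, tw$grid, default_taxa(),
    mc_config(n_trials = 50, te_sd = 0, seed = 1))
  expect_equal(mc$median, det$percent, tolerance = 1e-12)
  expect_equal(mc$ci_low, det$percent, tolerance = 1e-12)
  expect_equal(mc$ci_high, det$percent, tolerance = 1e-12)
  expect_true(all(mc$pp_degenerate == FALSE))
})

test_that("Monte Carlo CI brackets the trial median and is seed-stable", {
  tw <- tiny_world(seed = 22)
  mc1 <- mc_accessible_percentage(tw$catches, tw$pp, tw$grid,
                                  default_taxa(),
                                  mc_config(n_trials = 200, seed = 5))
  mc2 <- mc_accessible_percentage(tw$catches, tw$pp, tw$grid,
                                  default_taxa(),
                                  mc_config(n_trials = 200, seed = 5))
  expect_identical(mc1, mc2)
  expect_true(all(mc1$ci_low <= mc1$median & mc1$median <= mc1$ci_high))
})
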