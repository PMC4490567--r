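# Shared fixture builders: everything is generated in code, no stored data.

default_taxa <- function() {
  tibble::tibble(
    taxon = c("anchovy", "shrimp", "hake", "tuna", "kelp"),
    tl = c(2.5, 2.7, 4.0, 4.5, 1.0)
  )
}

# A small but complete world: grid + productivity + countries + catches.
tiny_world <- function(seed = 42, n_lat = 6, n_lon = 10, land_fraction = 0.2,
                       years = 2000:2004, n_countries = 3,
                       effort_trend = 0, target = 0.1, coverage = 1,
                       interannual_cv = 0.05, depth_max = 4000) {
  grid <- generate_grid(n_lat, n_lon, land_fraction,
                        list(min = 10, max = depth_max), seed = seed)
  pp <- generate_pp_fields(grid, years, mean_pp = 150, spatial_cv = 0.4,
                           interannual_cv = interannual_cv, seed = seed + 1)
  world <- generate_world(grid, n_countries, default_taxa(),
                          n_ports = 2, seed = seed + 2)
  catches <- generate_catches(world, grid, pp, years, effort_trend,
                              target, coverage, seed = seed + 3)
  list(grid = grid, pp = pp, world = world, catches = catches)
}

# Independent per-record PPR summation (the brute-force oracle).
brute_ppr <- function(catches, taxa, cr, te) {
  total <- 0
  for (i in seq_len(nrow(catches))) {
    tl <- taxa$tl[taxa$taxon == catches$taxon[i]]
    total <- total + (catches$tonnage[i] / cr) * (1 / te)^(tl - 1)
  }
  total
}
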