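# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; panel sizes are kept small so the suite stays fast while preserving
# the qualitative regimes (neutral vs niche assembly, surface domain shift,
# planted signatures).

climate_levels <- c("tropical", "arid", "temperate", "continental", "polar")

# one planted signature block per climate level, so the climate category is
# fully decodable from the community
climate_signatures <- function(effect = 8, block = 2) {
  lapply(seq_along(climate_levels), function(k) {
    list(characteristic = "koppen_climate", level = climate_levels[k],
         taxa = ((k - 1) * block + 1):(k * block), effect = effect)
  })
}

# neutral panel in the regime where drift variance is small relative to
# sampling noise (strong dispersal coupling)
neutral_community <- function(seed, n_taxa = 80, n_samples = 30,
                              Nm = 5000, depth = 2000) {
  pool <- sample_metacommunity(n_taxa, seed = seed)
  simulate_neutral(pool, Nm = Nm, n_samples = n_samples, depth = depth,
                   seed = seed + 100)
}

# strongly niche-filtered panel: three environment groups, narrow kernel
niche_community <- function(seed, n_taxa = 80, per_group = 10,
                            niche_sigma = 0.3, Nm = 500, depth = 2000) {
  pool <- sample_metacommunity(n_taxa, seed = seed)
  optima <- with_seed(seed + 50, stats::runif(n_taxa, 0.5, 3.5))
  env <- rep(c(1, 2, 3), each = per_group)
  list(table = simulate_niche(pool, env, optima, niche_sigma = niche_sigma,
                              Nm = Nm, depth = depth, seed = seed + 100),
       groups = env)
}

# multi-city multi-surface panel with strong between-surface domain shift
# and a city-level niche filter providing the shared city signal
shift_panel <- function(seed, samples_per_surface = 12) {
  simulate_city_panel(panel_config(
    n_cities = 5, samples_per_surface = samples_per_surface, n_taxa = 60,
    depth = 5000, Nm = 500, niche_sigma = 1, surface_shift_sd = 1.5,
    seed = seed))
}

# panel with a single planted city-discriminating genus (index 7) and
# otherwise neutral assembly
planted_city_panel <- function(seed) {
  simulate_city_panel(panel_config(
    n_cities = 4, samples_per_surface = 10, n_taxa = 40, depth = 5000,
    Nm = 500, niche_sigma = Inf, surface_shift_sd = 0.4,
    signatures = list(list(characteristic = "city", level = "city02",
                           taxa = 7, effect = 8)),
    seed = seed))
}

# panel with per-climate signature taxa for characteristic prediction
climate_panel <- function(seed, n_cities = 6, samples_per_surface = 10) {
  simulate_city_panel(panel_config(
    n_cities = n_cities, samples_per_surface = samples_per_surface,
    n_taxa = 60, depth = 5000, Nm = 500, niche_sigma = Inf,
    surface_shift_sd = 0.4, signatures = climate_signatures(), seed = seed))
}

# tiny deterministic counts table for exact-arithmetic tests
toy_table <- function() {
  m <- matrix(c(2, 2, 4,
                1, 1, 0,
                0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("gA", "gB", "gC")))
  abundance_table(m)
}

toy_metadata <- function(n = 3) {
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             city = rep(c("c1", "c2"), length.out = n),
             surface_type = rep(c("bench", "door"), length.out = n),
             stringsAsFactors = FALSE)
}
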