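test_that("metacommunity pools are normalized, reproducible and shaped as requested", {
  pool <- sample_metacommunity(100, "lognormal", seed = 1)
  expect_equal(sum(pool$p), 1, tolerance = 1e-12)
  expect_true(all(pool$p > 0))
  expect_identical(pool, sample_metacommunity(100, "lognormal", seed = 1))
  expect_error(sample_metacommunity(1), ">= 2")

  ls_pool <- sample_metacommunity(200, "logseries", shape = 0.99, seed = 2)
  expect_gt(max(ls_pool$p) / stats::median(ls_pool$p), 10)
})

test_that("neutral simulation is deterministic and concentrates around the pool at large Nm", {
  pool <- sample_metacommunity(40, seed = 3)
  a <- simulate_neutral(pool, Nm = 500, n_samples = 10, depth = 1000, seed = 7)
  b <- simulate_neutral(pool, Nm = 500, n_samples = 10, depth = 1000, seed = 7)
  expect_identical(a$values, b$values)
  expect_true(all(rowSums(a$values) == 1000))

  # Nm -> very large: per-taxon relative abundance across samples has
  # vanishing variance around the pool composition
  big <- simulate_neutral(pool, Nm = 1e7, n_samples = 50, depth = 1e5, seed = 8)
  rel <- to_relative(big)$values
  expect_lt(max(abs(colMeans(rel) - pool$p)), 0.005)
  expect_lt(max(apply(rel, 2, stats::sd)), 0.005)
})

test_that("neutral occurrence frequencies agree with the beta-CDF prediction", {
  pool <- sample_metacommunity(100, seed = 5)
  tab <- simulate_neutral(pool, Nm = 500, n_samples = 200, depth = 5e4, seed = 6)
  os <- occurrence_stats(tab)
  keep <- pool$taxon_ids %in% os$taxon_ids
  fhat <- predict_frequency(pmin(pmax(pool$p[keep], 1e-12), 1 - 1e-12), 500, os$d)
  dev <- abs(os$freq - fhat)
  expect_lt(mean(dev), 0.05)
  expect_gte(mean(dev < 0.1), 0.9)
})

test_that("the niche filter reduces to neutrality as sigma grows", {
  # distributional agreement of per-taxon means at sigma = Inf over many seeds
  n_reject <- 0
  for (s in 1:100) {
    pool <- sample_metacommunity(30, seed = s)
    env <- rep(c(1, 2, 3), each = 7)
    optima <- with_seed(s + 500, stats::runif(30, 0, 4))
    neu <- simulate_neutral(pool, Nm = 200, n_samples = 21, depth = 1000, seed = s + 1000)
    nic <- simulate_niche(pool, env, optima, niche_sigma = Inf, Nm = 200,
                          depth = 1000, seed = s + 2000)
    ks <- suppressWarnings(stats::ks.test(colMeans(to_relative(neu)$values),
                                          colMeans(to_relative(nic)$values)))
    if (ks$p.value < 0.01) n_reject <- n_reject + 1
  }
  expect_lte(n_reject, 5)
})

test_that("a strong niche filter suppresses taxa far from the local optimum", {
  pool <- sample_metacommunity(50, seed = 9)
  optima <- seq(0, 4, length.out = 50)
  tab <- simulate_niche(pool, env_values = rep(0, 30), optima = optima,
                        niche_sigma = 0.2, Nm = 500, depth = 5000, seed = 10)
  rel <- to_relative(tab)$values
  far <- optima > 2
  expect_lt(max(colMeans(rel)[far]), 1e-3)
  expect_error(simulate_niche(pool, 1, optima, niche_sigma = 0, Nm = 1, depth = 10),
               "niche_sigma")
})

test_that("city panels carry planted signatures and valid metadata", {
  sig_taxa <- 1:2
  sim <- simulate_city_panel(panel_config(
    n_cities = 6, samples_per_surface = 6, n_taxa = 50, depth = 5e4,
    surface_shift_sd = 0, niche_sigma = Inf,
    signatures = list(list(characteristic = "koppen_climate",
                           level = "temperate", taxa = sig_taxa, effect = 8)),
    seed = 21))
  md <- sim$metadata
  expect_identical(md$sample_id, sim$table$sample_ids)
  expect_true(all(md$latitude >= -90 & md$latitude <= 90))
  expect_setequal(unique(md$surface_type), c("bench", "door", "handrail", "kiosk"))

  rel <- to_relative(sim$table)$values
  match_idx <- md$koppen_climate == "temperate"
  expect_true(any(match_idx) && any(!match_idx))
  for (g in sig_taxa) {
    ratio <- mean(rel[match_idx, g]) / mean(rel[!match_idx, g])
    expect_gte(ratio, 4)
  }
  # determinism under the config seed
  sim2 <- simulate_city_panel(panel_config(
    n_cities = 6, samples_per_surface = 6, n_taxa = 50, depth = 5e4,
    surface_shift_sd = 0, niche_sigma = Inf,
    signatures = list(list(characteristic = "koppen_climate",
                           level = "temperate", taxa = sig_taxa, effect = 8)),
    seed = 21))
  expect_identical(sim$table$values, sim2$table$values)
})

test_that("surface biases of one leave surfaces statistically exchangeable", {
  # under exchangeability the PERMANOVA p-value is uniform; its mean over
  # panels sits well away from 0
  ps <- vapply(1:5, function(s) {
    sim <- simulate_city_panel(panel_config(
      n_cities = 3, samples_per_surface = 8, n_taxa = 40, depth = 2000,
      surface_shift_sd = 0, niche_sigma = Inf, seed = 30 + s))
    D <- bray_curtis(to_relative(sim$table))
    permanova(D, sim$metadata$surface_type, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.15)
})

test_that("source/sink mixtures follow the requested proportions", {
  set.seed(11)
  prof <- t(sapply(1:2, function(k) { g <- rgamma(60, 0.5); g / sum(g) }))
  expect_error(simulate_source_sink(prof, c(0.5, 0.4, 0.2), depth = 100), "sum to 1")
  expect_error(simulate_source_sink(prof, c(0.6, 0.3, 0.1), depth = 0), "depth")

  # alpha = (1, 0): the sink is a draw from source 1 alone
  ss <- simulate_source_sink(prof, c(1, 0, 0), depth = 1e5, seed = 12)
  sink_rel <- ss$sink_counts / sum(ss$sink_counts)
  expect_lt(max(abs(sink_rel - prof[1, ])), 0.01)
  expect_equal(sum(ss$sink_counts), 1e5)
})

test_that("the Moran-process simulator agrees with the stationary sampler at tiny scale", {
  pool <- sample_metacommunity(10, seed = 13)
  # Nm = N * m with N = 200, m = 0.5
  moran <- simulate_neutral_moran(pool, N = 200, m = 0.5, n_samples = 15,
                                  generations = 30, seed = 14)
  stat <- simulate_neutral(pool, Nm = 100, n_samples = 15, depth = 200, seed = 15)
  m_rel <- colMeans(to_relative(moran)$values)
  s_rel <- colMeans(to_relative(stat)$values)
  expect_gt(stats::cor(m_rel, s_rel), 0.9)
})
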