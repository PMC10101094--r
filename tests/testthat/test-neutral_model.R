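test_that("occurrence statistics match hand computation", {
  m <- matrix(c(0, 10,
                0, 10,
                5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  os <- occurrence_stats(abundance_table(m))
  expect_equal(os$freq[os$taxon_ids == "gA"], 1 / 3)
  expect_equal(os$p[os$taxon_ids == "gA"], mean(c(0, 0, 0.5)))
  expect_equal(os$freq[os$taxon_ids == "gB"], 1)

  depths <- matrix(c(60, 40, 100, 200), 2, 2,
                   dimnames = list(c("s1", "s2"), c("gA", "gB")))
  os2 <- occurrence_stats(abundance_table(depths))
  expect_equal(os2$N, 200)
  expect_equal(os2$d, 0.005)
  expect_error(occurrence_stats(abundance_table(m[1, , drop = FALSE])), "single sample")
})

test_that("frequency prediction matches an independent quadrature of the beta density", {
  # oracle: numerical integration of the beta density above the detection
  # limit, with log substitutions at both endpoint singularities
  quad <- function(p, Nm, d) {
    a <- Nm * p; b <- Nm * (1 - p)
    lower_piece <- function(t) exp(-lbeta(a, b) + a * t + (b - 1) * log1p(-exp(t)))
    upper_piece <- function(u) exp(-lbeta(a, b) + (a - 1) * log1p(-exp(u)) + b * u)
    stats::integrate(lower_piece, log(d), log(0.5),
                     rel.tol = 1e-11, subdivisions = 1000L)$value +
      stats::integrate(upper_piece, -Inf, log(0.5),
                       rel.tol = 1e-11, subdivisions = 1000L)$value
  }
  expect_equal(predict_frequency(0.01, 1000, 5e-4), quad(0.01, 1000, 5e-4),
               tolerance = 1e-8)
  for (p in c(0.001, 0.01, 0.1, 0.5)) {
    for (Nm in c(10, 100, 1000)) {
      expect_equal(predict_frequency(p, Nm, 0.001), quad(p, Nm, 0.001),
                   tolerance = 1e-8)
    }
  }
  # limits: abundant taxa are always seen, ultra-rare ones never
  expect_gt(predict_frequency(0.01, 1e7, 0.001), 1 - 1e-6)
  expect_lt(predict_frequency(1e-4, 1e7, 0.001), 1e-6)
  # at p = d the concentrating beta is symmetric around its mean
  expect_equal(predict_frequency(0.001, 1e7, 0.001), 0.5, tolerance = 0.01)
  expect_error(predict_frequency(0, 100, 0.01), "strictly")
})

test_that("frequency prediction is monotone in abundance", {
  p_grid <- seq(1e-4, 0.2, length.out = 100)
  for (Nm in c(50, 500, 5000)) {
    expect_true(all(diff(predict_frequency(p_grid, Nm, 0.001)) >= 0))
  }
})

test_that("the neutral fit recovers the generating Nm and a high explanation rate", {
  pool <- sample_metacommunity(150, seed = 1)
  tab <- simulate_neutral(pool, Nm = 500, n_samples = 200, depth = 5e4, seed = 101)
  fit <- fit_ncm(tab)
  expect_lt(abs(fit$Nm - 500) / 500, 0.15)
  expect_gt(fit$r_squared, 0.8)
  expect_equal(fit$d * fit$N, 1, tolerance = 1e-12)
  expect_true(all(fit$taxa$predicted >= 0 & fit$taxa$predicted <= 1))
  expect_true(all(fit$taxa$partition %in% c("above", "neutral", "below")))
  # partition is consistent with the envelope
  above <- fit$taxa$partition == "above"
  expect_true(all(fit$taxa$freq[above] > fit$taxa$ci_high[above]))

  # cross-check against an independent brute-force grid fit
  os <- occurrence_stats(tab)
  usable <- os$p > 0 & os$p < 1
  grid <- exp(seq(log(50), log(5000), length.out = 400))
  sse <- vapply(grid, function(nm) {
    sum((os$freq[usable] - predict_frequency(os$p[usable], nm, os$d))^2)
  }, numeric(1))
  expect_equal(fit$Nm, grid[which.min(sse)], tolerance = 0.02)
})

test_that("the fit is invariant to taxon order and row duplication", {
  pool <- sample_metacommunity(60, seed = 2)
  tab <- simulate_neutral(pool, Nm = 300, n_samples = 50, depth = 5000, seed = 3)
  fit <- fit_ncm(tab)

  shuf <- abundance_table(tab$values[, sample(ncol(tab$values))])
  fit_shuf <- fit_ncm(shuf)
  expect_equal(fit_shuf$Nm, fit$Nm, tolerance = 1e-10)
  expect_equal(fit_shuf$r_squared, fit$r_squared, tolerance = 1e-10)

  dup_vals <- rbind(tab$values, tab$values)
  rownames(dup_vals) <- sprintf("r%03d", seq_len(nrow(dup_vals)))
  fit_dup <- fit_ncm(abundance_table(dup_vals))
  expect_equal(fit_dup$Nm, fit$Nm, tolerance = 1e-10)
  expect_equal(fit_dup$r_squared, fit$r_squared, tolerance = 1e-10)
})

test_that("niche filtering lowers the neutral explanation rate", {
  worse <- 0
  for (s in 1:10) {
    pool <- sample_metacommunity(60, seed = s)
    neu <- simulate_neutral(pool, Nm = 500, n_samples = 45, depth = 5000,
                            seed = s + 100)
    optima <- with_seed(s + 50, stats::runif(60, 0.5, 3.5))
    nic <- simulate_niche(pool, rep(c(1, 2, 3), each = 15), optima,
                          niche_sigma = 0.3, Nm = 500, depth = 5000,
                          seed = s + 200)
    if (fit_ncm(nic)$r_squared < fit_ncm(neu)$r_squared) worse <- worse + 1
  }
  expect_gte(worse, 9)
})

test_that("degenerate frequency spectra are rejected", {
  m <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  expect_error(suppressWarnings(fit_ncm(abundance_table(m))), "degenerate frequency spectrum")
})

test_that("per-city fitting returns one fit per sufficiently sampled group", {
  sim <- simulate_city_panel(panel_config(n_cities = 3, samples_per_surface = 5,
                                          n_taxa = 50, depth = 2000, seed = 4))
  fits <- fit_ncm_by_group(sim$table, sim$metadata, "city")
  expect_length(fits, 3)
  expect_true(all(vapply(fits, function(f) f$r_squared <= 1, logical(1))))
})
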