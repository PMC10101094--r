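test_that("Shannon diversity matches direct formula evaluation", {
  m <- rbind(uniform = c(0.25, 0.25, 0.25, 0.25),
             single = c(1, 0, 0, 0),
             mixed = c(0.5, 0.25, 0.25, 0))
  colnames(m) <- paste0("g", 1:4)
  tab <- abundance_table(m, is_relative = FALSE)
  h <- shannon_index(tab)
  expect_equal(unname(h["uniform"]), log(4), tolerance = 1e-12)
  expect_equal(unname(h["single"]), 0, tolerance = 1e-12)
  # oracle: direct -sum(q log q) evaluation
  expect_equal(unname(h["mixed"]),
               -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))),
               tolerance = 1e-12)
  expect_equal(unname(h["mixed"]), 1.0397, tolerance = 1e-4)
})

test_that("PCoA reconstructs planar configurations and degenerate inputs", {
  with_seed(2, {
    pts <- cbind(stats::rnorm(12), stats::rnorm(12))
  })
  rownames(pts) <- paste0("s", 1:12)
  D <- as.matrix(stats::dist(pts))
  fit <- pcoa_ordination(D)
  # distances among recovered coordinates equal the input (rotation-invariant)
  rec <- as.matrix(stats::dist(fit$coordinates[, 1:2]))
  expect_lt(max(abs(rec - D)), 1e-8)

  # collinear points: first axis carries almost all positive inertia
  line <- as.matrix(stats::dist(cbind(1:10, 0)))
  rownames(line) <- colnames(line) <- paste0("s", 1:10)
  lf <- pcoa_ordination(line)
  pos <- lf$eigenvalues[lf$eigenvalues > 1e-10]
  expect_gt(pos[1] / sum(pos), 0.99)

  zero <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  zf <- pcoa_ordination(zero)
  expect_true(all(abs(zf$eigenvalues) < 1e-12))
  asym <- D; asym[1, 2] <- asym[1, 2] + 1
  expect_error(pcoa_ordination(asym), "symmetric")
})

test_that("PERMANOVA matches the direct sum-of-squares decomposition", {
  with_seed(3, {
    a <- matrix(stats::rnorm(10 * 5, 0), 10)
    b <- matrix(stats::rnorm(10 * 5, 2), 10)
  })
  pts <- rbind(a, b)
  rownames(pts) <- paste0("s", 1:20)
  D <- as.matrix(stats::dist(pts))
  groups <- rep(c("x", "y"), each = 10)
  res <- permanova(D, groups, n_perm = 999, seed = 4)

  # direct SS oracle from squared distances
  n <- nrow(D)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  ss_within <- sum(vapply(unique(groups), function(g) {
    idx <- groups == g
    sub <- D[idx, idx]
    sum(sub[lower.tri(sub)]^2) / sum(idx)
  }, numeric(1)))
  expect_equal(res$r_squared, 1 - ss_within / ss_total, tolerance = 1e-10)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  expect_error(permanova(D, rep("x", 20)), "2 levels")
})

test_that("PERMANOVA p-values are calibrated under the null", {
  with_seed(5, {
    pts <- matrix(stats::rnorm(16 * 4), 16)
  })
  rownames(pts) <- paste0("s", 1:16)
  D <- as.matrix(stats::dist(pts))
  ps <- vapply(1:100, function(s) {
    labs <- with_seed(1000 + s, sample(rep(c("x", "y"), each = 8)))
    permanova(D, labs, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MST PERMANOVA attributes stochasticity variation to the driving factor", {
  # niche strength driven by a 3-level environment; a second, independent label
  nic <- niche_community(21, per_group = 8)
  ps <- pairwise_stochasticity(nic$table, null_model_config(60, seed = 22))
  md <- data.frame(sample_id = nic$table$sample_ids,
                   env_group = paste0("e", nic$groups),
                   noise_group = with_seed(23, sample(rep(c("u", "v"), 12))),
                   stringsAsFactors = FALSE)
  res <- permanova_mst(ps$MST, md, c("env_group", "noise_group"),
                       mode = "marginal", n_perm = 199, seed = 24)
  expect_gt(res$r_squared[res$factor == "env_group"],
            res$r_squared[res$factor == "noise_group"])
  expect_lte(res$p_value[res$factor == "env_group"], 0.05)
  expect_gt(res$p_value[res$factor == "noise_group"], 0.05)

  # MST identically 1 (pure null coincidence) carries no signal
  ones <- matrix(1, 24, 24)
  res1 <- permanova_mst(ones, md, "env_group", mode = "marginal",
                        n_perm = 99, seed = 25)
  expect_lt(res1$r_squared, 0.15)

  seq_res <- permanova_mst(ps$MST, md, c("env_group", "noise_group"),
                           mode = "sequential", n_perm = 99, seed = 26)
  expect_equal(nrow(seq_res), 2)
})

test_that("Mantel behaves at its fixed points and under rank transforms", {
  with_seed(6, {
    pts <- matrix(stats::rnorm(15 * 3), 15)
  })
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:15)
  self <- mantel_test(D, D, n_perm = 199, seed = 7)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$p_value, 1 / 200)

  mono <- mantel_test(D, sqrt(D), n_perm = 99, seed = 8)
  expect_equal(mono$r, 1, tolerance = 1e-12)

  with_seed(9, {
    other <- as.matrix(stats::dist(matrix(stats::rnorm(15 * 3), 15)))
  })
  indep <- mantel_test(D, other, n_perm = 199, seed = 10)
  expect_lt(abs(indep$r), 0.3)
  expect_error(mantel_test(D, other[1:10, 1:10]), "size")
})

test_that("the association panel flags planted signature genera", {
  hits <- 0
  for (s in 1:5) {
    sim <- climate_panel(700 + s, n_cities = 6, samples_per_surface = 5)
    panel <- characteristic_association_panel(
      sim$table, sim$metadata, genera = sim$table$taxon_ids[c(1, 30)],
      characteristics = c("avg_june_temp", "region", "latitude"),
      n_perm = 199, seed = s)
    planted <- panel$mantel[panel$mantel$variable == sim$table$taxon_ids[1], ]
    if (any(planted$p_value < 0.01)) hits <- hits + 1
  }
  expect_gte(hits, 4)

  sim <- climate_panel(42, n_cities = 6, samples_per_surface = 5)
  panel <- characteristic_association_panel(
    sim$table, sim$metadata, genera = character(0),
    characteristics = c("latitude", "longitude", "population"),
    n_perm = 99, seed = 1)
  expect_true(all(c("community", "shannon") %in% panel$mantel$variable))
  # Pearson block: symmetric, unit diagonal
  expect_equal(unname(diag(panel$pearson)), rep(1, nrow(panel$pearson)))
  expect_equal(panel$pearson, t(panel$pearson))
})
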