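sep_data <- function(n, seed, noise_features = 4) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * (noise_features + 1)), n)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    y <- factor(ifelse(X[, 1] > 0, "a", "b"))
    list(X = X, y = y)
  })
}

test_that("forests separate a separable problem and are chance-level on noise", {
  tr <- sep_data(200, 1); te <- sep_data(200, 2)
  fm <- train_forest(tr$X, tr$y, n_trees = 50, seed = 3)
  expect_equal(macro_auroc(te$y, predict(fm, te$X)), 1.0, tolerance = 0.005)

  aucs <- vapply(1:10, function(s) {
    d <- sep_data(120, 100 + s)
    y_shuf <- with_seed(200 + s, sample(d$y))
    fm <- train_forest(d$X[1:60, ], y_shuf[1:60], n_trees = 30, seed = s)
    macro_auroc(y_shuf[61:120], predict(fm, d$X[61:120, ]))
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("forests are deterministic under seed and probabilities sum to one", {
  d <- sep_data(100, 4)
  f1 <- train_forest(d$X, d$y, n_trees = 20, seed = 9)
  f2 <- train_forest(d$X, d$y, n_trees = 20, seed = 9)
  p1 <- predict(f1, d$X); p2 <- predict(f2, d$X)
  expect_identical(p1, p2)
  expect_equal(unname(rowSums(p1)), rep(1, 100), tolerance = 1e-12)
  f3 <- train_forest(d$X, d$y, n_trees = 20, seed = 10)
  expect_false(identical(predict(f3, d$X), p1))
  expect_error(train_forest(d$X, factor(rep("a", 100))), "2 classes")
})

test_that("macro AUROC equals brute-force concordant-pair counting", {
  # exhaustive pair-enumeration oracle, ties credited one half
  pair_auc <- function(scores, pos) {
    num <- 0; den <- 0
    for (i in which(pos)) for (j in which(!pos)) {
      den <- den + 1
      num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    num / den
  }
  truth <- factor(c("a", "a", "a", "b", "b", "b"))
  probs <- cbind(a = c(0.9, 0.8, 0.25, 0.3, 0.1, 0.25),
                 b = 1 - c(0.9, 0.8, 0.25, 0.3, 0.1, 0.25))
  expected <- mean(c(pair_auc(probs[, "a"], truth == "a"),
                     pair_auc(probs[, "b"], truth == "b")))
  expect_equal(macro_auroc(truth, probs), expected)
  # analytic cases
  expect_equal(macro_auroc(factor(c("a", "a", "b", "b")),
                           cbind(a = c(0.9, 0.8, 0.3, 0.1),
                                 b = c(0.1, 0.2, 0.7, 0.9))), 1)
  expect_equal(macro_auroc(factor(c("a", "b")), cbind(a = c(0.5, 0.5), b = c(0.5, 0.5))), 0.5)
  # inverted scores mirror the AUROC
  inv <- cbind(a = probs[, "b"], b = probs[, "a"])
  expect_equal(macro_auroc(truth, inv), 1 - macro_auroc(truth, probs))
  expect_warning(macro_auroc(factor(c("a", "a", "b")),
                             cbind(a = c(1, 1, 0), b = c(0, 0, 1), c = 0)),
                 "absent from truth")
})

test_that("SER adaptation relabels toward the target domain", {
  d <- sep_data(150, 5)
  fm <- train_forest(d$X, d$y, n_trees = 30, seed = 6)
  # target with flipped labels: adaptation must follow the target labelling
  flipped <- factor(ifelse(d$y == "a", "b", "a"), levels = levels(d$y))
  tm <- ser_transfer(fm, d$X, flipped, seed = 6)
  te <- sep_data(150, 7)
  te_flip <- factor(ifelse(te$y == "a", "b", "a"), levels = levels(te$y))
  expect_gt(macro_auroc(te_flip, predict(tm, te$X)), 0.95)
  expect_error(ser_transfer(fm, d$X[0, , drop = FALSE], d$y[0]), "empty target")

  # no shift + ample target: TM performs at least as well as BM (tolerance)
  same <- sep_data(200, 8)
  tm2 <- ser_transfer(fm, same$X, same$y, seed = 8)
  auc_bm <- macro_auroc(te$y, predict(fm, te$X))
  auc_tm <- macro_auroc(te$y, predict(tm2, te$X))
  expect_gte(auc_tm, auc_bm - 0.02)
})

test_that("top-variance selection ranks by variance with lexicographic ties", {
  m <- cbind(g_const = rep(0.20, 4),
             g_b = c(0.30, 0.10, 0.30, 0.10),
             g_a = c(0.30, 0.10, 0.30, 0.10),
             g_mid = c(0.15, 0.21, 0.15, 0.21))
  m <- cbind(m, g_bal = 1 - rowSums(m))
  rownames(m) <- paste0("s", 1:4)
  tab <- abundance_table(m, is_relative = TRUE)
  # direct-variance oracle with the same tie convention
  v <- apply(m, 2, stats::var)
  expected <- colnames(m)[order(-v, colnames(m))]
  expect_identical(top_variance_genera(tab, 5), expected)
  # tied identical columns resolve alphabetically; constants sort last
  top <- top_variance_genera(tab, 4)
  expect_lt(match("g_a", top), match("g_b", top))
  expect_false("g_const" %in% top)
  expect_warning(all5 <- top_variance_genera(tab, 10), "exceeds")
  expect_setequal(all5, colnames(m))
})

test_that("BM/IM/TM evaluation is paired, partitioned and ordered under domain shift", {
  sim <- shift_panel(41)
  ev <- evaluate_bm_im_tm(sim$table, sim$metadata, "bench", protocol = "split",
                          train_frac = 0.2, repeats = 2, n_trees = 40, seed = 5)
  expect_setequal(unique(ev$model_kind), c("BM", "IM", "TM"))
  # every (repeat, fold) cell carries all three paired models
  cells <- table(ev$repeat_id, ev$model_kind)
  expect_true(all(cells == cells[, "BM"]))
  expect_true(all(ev$auroc >= 0 & ev$auroc <= 1))

  # cv10 folds partition target samples exactly once
  labels <- factor(sim$metadata$city[sim$metadata$surface_type == "bench"])
  fold <- utsassembly:::stratified_folds(labels, 10, seed = 3)
  expect_length(fold, length(labels))
  expect_true(all(table(fold) >= 1))

  expect_error(evaluate_bm_im_tm(sim$table, sim$metadata, "bench",
                                 protocol = "cv10", repeats = 1,
                                 features = sim$table$taxon_ids[1:5],
                                 n_trees = 5, seed = 1),
               NA)
})

test_that("cv10 demands enough target samples", {
  sim <- planted_city_panel(3)
  md <- sim$metadata
  md$surface_type[md$surface_type == "bench"][-(1:5)] <- "door"
  expect_error(evaluate_bm_im_tm(sim$table, md, "bench", protocol = "cv10"),
               "split")
})

test_that("city specificity ranks the planted genus first and ignores constants", {
  sim <- planted_city_panel(51)
  feats <- sim$table$taxon_ids[1:15]
  expect_true("g007" %in% feats)
  imp <- city_specificity(sim$table, sim$metadata, "bench", feats,
                          repeats = 3, n_trees = 40, seed = 2)
  expect_identical(imp$genus[1], "g007")
  expect_identical(imp$rank, seq_len(15L))
  # feature list order does not matter
  imp_shuf <- city_specificity(sim$table, sim$metadata, "bench", rev(feats),
                               repeats = 3, n_trees = 40, seed = 2)
  expect_identical(imp, imp_shuf)
  expect_error(city_specificity(sim$table, sim$metadata, "bench", "g001"),
               "at least 2")
})
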