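#' Bray-Curtis dissimilarity matrix
#'
#' @param x An [abundance_table()] (counts or relative) with positive row
#'   sums.
#' @return A symmetric dissimilarity matrix in \[0, 1\] with zero diagonal.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rs <- rowSums(x$values)
  if (any(rs <= 0)) stop("zero-sum samples: ", paste(x$sample_ids[rs <= 0], collapse = ", "))
  as.matrix(vegan::vegdist(x$values, method = "bray"))
}

#' Null-model configuration for stochasticity analysis
#'
#' @param n_null Number of null replicates (default 1000).
#' @param seed Integer seed.
#' @return A `null_model_config` list.
#' @export
null_model_config <- function(n_null = 1000, seed = 1) {
  if (n_null < 1) stop("n_null must be >= 1")
  structure(list(n_null = n_null, seed = seed), class = "null_model_config")
}

#' Null ensemble of pairwise dissimilarities
#'
#' For each replicate, every sample is reassembled under the random-zero
#' expectation: its observed richness of taxa is drawn with probability
#' proportional to taxon occupancy across samples, one individual is placed
#' on each drawn taxon, and the remainder of its observed total abundance is
#' distributed multinomially in proportion to the regional (summed) relative
#' abundances. Each null sample therefore conserves the observed richness
#' and total abundance exactly. Bray-Curtis is recomputed per replicate.
#'
#' @param x A counts [abundance_table()].
#' @param config A [null_model_config()].
#' @return A matrix (n_null x n_pairs) of null dissimilarities; pairs follow
#'   lower-triangle `dist` order of the samples. Attribute `sample_ids`
#'   records the ordering.
#' @export
null_ensemble <- function(x, config = null_model_config()) {
  stopifnot(inherits(x, "abundance_table"), inherits(config, "null_model_config"))
  counts <- round(x$values)
  n <- nrow(counts); K <- ncol(counts)
  occupancy <- colSums(counts > 0)
  regional <- colSums(counts)
  regional_p <- regional / sum(regional)
  richness <- rowSums(counts > 0)
  totals <- rowSums(counts)
  stopifnot(all(richness <= K))
  nulls <- with_seed(config$seed, {
    t(vapply(seq_len(config$n_null), function(r) {
      null_tab <- matrix(0, n, K)
      for (s in seq_len(n)) {
        drawn <- sample.int(K, richness[s], replace = FALSE, prob = occupancy)
        row <- numeric(K)
        row[drawn] <- 1
        rest <- totals[s] - richness[s]
        if (rest > 0) {
          pr <- regional_p[drawn]
          row[drawn] <- row[drawn] +
            as.numeric(stats::rmultinom(1, rest, pr / sum(pr)))
        }
        null_tab[s, ] <- row
      }
      as.numeric(vegan::vegdist(null_tab, method = "bray"))
    }, numeric(n * (n - 1) / 2)))
  })
  attr(nulls, "sample_ids") <- x$sample_ids
  nulls
}

#' Modified stochasticity ratio from observed and null-mean dissimilarities
#'
#' MST is 1 exactly where the observed dissimilarity equals the null
#' expectation and decreases toward 0 as the observation becomes either
#' deterministically similar (D below E: MST = D/E) or deterministically
#' dissimilar (D above E: MST = (d_max - D)/(d_max - E)). Values above 0.5
#' indicate assembly dominated by stochastic processes.
#'
#' @param D Observed dissimilarity matrix.
#' @param E Null-mean dissimilarity matrix (same shape).
#' @param d_max Maximum possible dissimilarity (1 for Bray-Curtis).
#' @return A matrix of MST values in \[0, 1\] (diagonal 1 by convention).
#' @export
mst <- function(D, E, d_max = 1) {
  D <- assert_square_symmetric(D, "D"); E <- assert_square_symmetric(E, "E")
  if (!all(dim(D) == dim(E))) stop("D and E must have matching dimensions")
  if (any(D < 0 | D > d_max) || any(E < 0 | E > d_max)) {
    stop("dissimilarities must lie in [0, d_max]")
  }
  below <- D <= E
  out <- matrix(NA_real_, nrow(D), ncol(D), dimnames = dimnames(D))
  out[below] <- ifelse(E[below] == 0, 1, D[below] / E[below])
  up <- !below
  out[up] <- ifelse(E[up] == d_max, 1, (d_max - D[up]) / (d_max - E[up]))
  # degenerate null expectations: any observed departure is fully deterministic
  if (any(E == 0 & D > 0)) {
    warning("null expectation 0 with positive observed dissimilarity; MST set to 0")
    out[E == 0 & D > 0] <- 0
  }
  if (any(E == d_max & D < d_max)) {
    warning("null expectation at d_max with smaller observed dissimilarity; MST set to 0")
    out[E == d_max & D < d_max] <- 0
  }
  diag(out) <- 1
  out
}

#' Modified Raup-Crick metric from a null ensemble
#'
#' Ranks each observed pairwise dissimilarity within its null distribution
#' (ties counted as half) and rescales the rank to \[-1, 1\]: +1 when the
#' observation exceeds every null draw (deterministic divergence), -1 when
#' it undercuts every null draw (deterministic convergence), ~0 at the null
#' median.
#'
#' @param D Observed dissimilarity matrix.
#' @param null_samples Null ensemble from [null_ensemble()] (n_null x
#'   n_pairs, `dist` order).
#' @return A symmetric matrix of beta_RC values in \[-1, 1\], zero diagonal.
#' @export
raup_crick <- function(D, null_samples) {
  D <- assert_square_symmetric(D, "D")
  n <- nrow(D)
  d_vec <- D[lower.tri(D)]
  if (ncol(null_samples) != length(d_vec)) stop("null ensemble does not match D")
  n_null <- nrow(null_samples)
  frac <- vapply(seq_along(d_vec), function(k) {
    nl <- null_samples[, k]
    (sum(nl < d_vec[k]) + 0.5 * sum(nl == d_vec[k])) / n_null
  }, numeric(1))
  brc <- matrix(0, n, n, dimnames = dimnames(D))
  brc[lower.tri(brc)] <- 2 * frac - 1
  brc <- brc + t(brc)
  brc
}

#' Full pairwise stochasticity analysis
#'
#' Computes observed Bray-Curtis, the null ensemble, null-mean E, MST and
#' beta_RC in one pass.
#'
#' @param x A counts [abundance_table()].
#' @param config A [null_model_config()].
#' @return An object of class `pairwise_stochasticity`: list with `D`, `E`,
#'   `MST`, `beta_rc`, `d_max`, `n_null`.
#' @export
pairwise_stochasticity <- function(x, config = null_model_config()) {
  D <- bray_curtis(x)
  nulls <- null_ensemble(x, config)
  E <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  E[lower.tri(E)] <- colMeans(nulls)
  E <- E + t(E)
  structure(
    list(D = D, E = E, MST = mst(D, E, d_max = 1),
         beta_rc = raup_crick(D, nulls), d_max = 1, n_null = config$n_null),
    class = "pairwise_stochasticity"
  )
}

#' Per-group summaries of MST and beta_RC
#'
#' For each group (e.g. city or surface type), averages the within-group
#' pairwise MST and bins the within-group beta_RC values into the grade
#' histogram used to describe deterministic vs stochastic pair structure:
#' \[-1, -0.95\], (-0.95, 0), 0, (0, 0.95), \[0.95, 1\], plus the fraction
#' of pairs with |beta_RC| > 0.95.
#'
#' @param ps A `pairwise_stochasticity` object.
#' @param groups Group label per sample (aligned to the analysed table).
#' @return A data.frame, one row per group, with `mean_mst`, grade
#'   proportions and `frac_extreme`.
#' @export
summarize_by_group <- function(ps, groups) {
  stopifnot(inherits(ps, "pairwise_stochasticity"))
  if (length(groups) != nrow(ps$MST)) stop("one group label per sample required")
  res <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    sub_mst <- ps$MST[idx, idx][lower.tri(diag(length(idx)))]
    sub_brc <- ps$beta_rc[idx, idx][lower.tri(diag(length(idx)))]
    n_pairs <- length(sub_brc)
    grades <- c(
      strong_neg = sum(sub_brc <= -0.95),
      mod_neg = sum(sub_brc > -0.95 & sub_brc < 0),
      zero = sum(sub_brc == 0),
      mod_pos = sum(sub_brc > 0 & sub_brc < 0.95),
      strong_pos = sum(sub_brc >= 0.95)
    )
    res[[length(res) + 1]] <- data.frame(
      group = g, n_pairs = n_pairs, mean_mst = mean(sub_mst),
      prop_strong_neg = grades[["strong_neg"]] / n_pairs,
      prop_mod_neg = grades[["mod_neg"]] / n_pairs,
      prop_zero = grades[["zero"]] / n_pairs,
      prop_mod_pos = grades[["mod_pos"]] / n_pairs,
      prop_strong_pos = grades[["strong_pos"]] / n_pairs,
      frac_extreme = mean(abs(sub_brc) > 0.95),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}
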