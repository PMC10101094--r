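#' Shannon diversity per sample
#'
#' @param x An [abundance_table()] (counts or relative; diversity is
#'   computed on relative abundances, natural log).
#' @return Named numeric vector of Shannon indices.
#' @export
shannon_index <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rs <- rowSums(x$values)
  if (any(rs <= 0)) stop("zero-sum samples: ", paste(x$sample_ids[rs <= 0], collapse = ", "))
  vegan::diversity(x$values, index = "shannon")
}

#' Principal-coordinate analysis of a dissimilarity matrix
#'
#' Gower double-centering and eigendecomposition; coordinates are returned
#' for positive eigenvalues, negative eigenvalues are reported uncorrected.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return A list with `coordinates` (samples x positive axes) and
#'   `eigenvalues` (all, decreasing).
#' @export
pcoa_ordination <- function(D) {
  D <- assert_square_symmetric(D, "D")
  if (max(abs(D)) < 1e-12) {
    return(list(coordinates = matrix(0, nrow(D), 1, dimnames = list(rownames(D), "Axis.1")),
                eigenvalues = rep(0, nrow(D))))
  }
  fit <- ape::pcoa(stats::as.dist(D))
  list(coordinates = as.matrix(fit$vectors), eigenvalues = fit$values$Eigenvalues)
}

#' PERMANOVA of a dissimilarity matrix against one factor
#'
#' Permutational multivariate analysis of variance: pseudo-F from the
#' Gower-centered dissimilarity partitioned by groups, with a permutation
#' p-value of the form (count >= observed + 1) / (n_perm + 1).
#'
#' @param D Symmetric dissimilarity matrix.
#' @param factor_labels Group label per sample; at least 2 levels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `permanova_result` with `factor`, `pseudo_F`,
#'   `r_squared`, `p_value`, `df`, `n_perm`, `seed`.
#' @export
permanova <- function(D, factor_labels, n_perm = 999, seed = 1) {
  D <- assert_square_symmetric(D, "D")
  f <- factor(factor_labels)
  if (length(f) != nrow(D)) stop("one label per sample required")
  if (nlevels(droplevels(f)) < 2) stop("factor must have at least 2 levels")
  res <- with_seed(seed, {
    vegan::adonis2(stats::as.dist(D) ~ f, permutations = n_perm)
  })
  structure(
    list(factor = deparse(substitute(factor_labels)),
         pseudo_F = res$F[1], r_squared = res$R2[1],
         p_value = res$`Pr(>F)`[1], df = res$Df[1],
         n_perm = n_perm, seed = seed),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' PERMANOVA of the stochasticity ratio against city characteristics
#'
#' Feeds 1 - MST as a pairwise dissimilarity to PERMANOVA for a set of
#' sample-level factors. `mode = "sequential"` fits all factors in one
#' sequential (terms-wise) partition, so the per-factor R-squared values sum
#' within the total; `mode = "marginal"` tests each factor alone.
#'
#' @param MST Pairwise MST matrix (from [pairwise_stochasticity()]).
#' @param metadata Aligned metadata.
#' @param factors Character vector of metadata columns.
#' @param mode `"sequential"` (default) or `"marginal"`.
#' @param n_perm,seed Permutation settings.
#' @return A data.frame with `factor`, `df`, `pseudo_F`, `r_squared`,
#'   `p_value` and a significance tier.
#' @export
permanova_mst <- function(MST, metadata, factors, mode = c("sequential", "marginal"),
                          n_perm = 999, seed = 1) {
  mode <- match.arg(mode)
  MST <- assert_square_symmetric(MST, "MST")
  d <- stats::as.dist(1 - MST)
  if (sum(d) < 1e-12) {
    # MST identically 1: the stochasticity structure carries no variation to
    # partition, so every factor explains none of it
    return(data.frame(factor = factors, df = NA_integer_, pseudo_F = 0,
                      r_squared = 0, p_value = 1,
                      significance = factor("NS", levels = c("***", "**", "*", "NS")),
                      stringsAsFactors = FALSE))
  }
  keep <- factors[vapply(factors, function(f) {
    length(unique(metadata[[f]])) >= 2
  }, logical(1))]
  dropped <- setdiff(factors, keep)
  if (length(dropped)) warning("constant factors skipped: ", paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no usable factors")
  df <- metadata[, keep, drop = FALSE]
  for (f in keep) if (!is.numeric(df[[f]])) df[[f]] <- factor(df[[f]])
  rows <- if (mode == "sequential") {
    fml <- stats::as.formula(paste("d ~", paste(keep, collapse = " + ")))
    res <- with_seed(seed, vegan::adonis2(fml, data = df, permutations = n_perm, by = "terms"))
    data.frame(factor = rownames(res)[seq_along(keep)],
               df = res$Df[seq_along(keep)],
               pseudo_F = res$F[seq_along(keep)],
               r_squared = res$R2[seq_along(keep)],
               p_value = res$`Pr(>F)`[seq_along(keep)],
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(keep, function(f) {
      res <- with_seed(derive_seed(seed, f), {
        vegan::adonis2(stats::as.formula(paste("d ~", f)), data = df,
                       permutations = n_perm)
      })
      data.frame(factor = f, df = res$Df[1], pseudo_F = res$F[1],
                 r_squared = res$R2[1], p_value = res$`Pr(>F)`[1],
                 stringsAsFactors = FALSE)
    }))
  }
  rows$significance <- cut(rows$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
                           labels = c("***", "**", "*", "NS"))
  rows
}

#' Mantel test between two distance matrices
#'
#' Spearman (by default) correlation of the off-diagonal entries, with a
#' permutation p-value from row/column permutations of the second matrix.
#'
#' @param D1,D2 Matched symmetric matrices.
#' @param method Correlation method (default `"spearman"`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `mantel_result` with `r`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(D1, D2, method = "spearman", n_perm = 999, seed = 1) {
  D1 <- assert_square_symmetric(D1, "D1")
  D2 <- assert_square_symmetric(D2, "D2")
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
  res <- with_seed(seed, {
    vegan::mantel(stats::as.dist(D1), stats::as.dist(D2), method = method,
                  permutations = n_perm)
  })
  structure(list(r = unname(res$statistic), p_value = res$signif,
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_perm))
  invisible(x)
}

#' @keywords internal
characteristic_distance <- function(values) {
  if (is.numeric(values)) {
    as.matrix(stats::dist(scale(values)))
  } else {
    outer(values, values, FUN = function(a, b) as.numeric(a != b))
  }
}

#' Association panel between microbes and city characteristics
#'
#' Mantel (Spearman) tests between community structure — Bray-Curtis of the
#' full community, Euclidean distance of Shannon diversity, and the
#' per-genus abundance distance of each supplied city-specific genus — and
#' the distance structure of each city characteristic (standardized
#' Euclidean for continuous, 0/1 mismatch for categorical), plus the
#' Pearson correlation matrix among continuous characteristics. Edges are
#' tiered at p < 0.01, 0.01-0.05, > 0.05.
#'
#' @param x An [abundance_table()].
#' @param metadata Aligned metadata.
#' @param genera City-specific genus names to test individually.
#' @param characteristics Metadata columns to associate against.
#' @param n_perm,seed Permutation settings.
#' @return A list with `mantel` (data.frame: variable, characteristic, r,
#'   p_value, tier) and `pearson` (correlation matrix of the continuous
#'   characteristics).
#' @export
characteristic_association_panel <- function(x, metadata, genera,
                                             characteristics = c("latitude", "longitude",
                                                                 "population",
                                                                 "population_density",
                                                                 "region", "avg_june_temp",
                                                                 "elevation"),
                                             n_perm = 999, seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  rel <- if (x$is_relative) x else to_relative(x)
  md <- metadata[match(x$sample_ids, metadata$sample_id), ]
  characteristics <- characteristics[vapply(characteristics, function(ch) {
    ch %in% names(md) && length(unique(md[[ch]])) >= 2
  }, logical(1))]
  if (!length(characteristics)) stop("no usable characteristics")
  comm <- list(
    community = bray_curtis(rel),
    shannon = as.matrix(stats::dist(shannon_index(rel)))
  )
  for (g in intersect(genera, rel$taxon_ids)) {
    comm[[g]] <- as.matrix(stats::dist(rel$values[, g]))
  }
  rows <- list()
  for (v in names(comm)) {
    if (max(comm[[v]]) == 0) next
    for (ch in characteristics) {
      dch <- characteristic_distance(md[[ch]])
      mt <- mantel_test(comm[[v]], dch, n_perm = n_perm,
                        seed = derive_seed(seed, paste(v, ch)))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, characteristic = ch, r = mt$r, p_value = mt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  mres <- do.call(rbind, rows)
  mres$tier <- cut(mres$p_value, c(-Inf, 0.01, 0.05, Inf),
                   labels = c("p<0.01", "0.01-0.05", "p>0.05"))
  cont <- characteristics[vapply(characteristics, function(ch) is.numeric(md[[ch]]), logical(1))]
  pearson <- if (length(cont) >= 2) stats::cor(md[, cont], method = "pearson") else NULL
  list(mantel = mres, pearson = pearson)
}
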