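#' EM estimation of source contributions to a sink community
#'
#' Fits a multinomial mixture by expectation-maximization: the sink count
#' vector is modelled as a multinomial draw from a convex combination of K
#' known source profiles plus (optionally) one unknown source estimated
#' from the sink itself. The E-step attributes each sink read to a source
#' in proportion to alpha_k * gamma_kj; the M-step re-estimates the mixing
#' proportions alpha from attributed reads and the source profiles gamma
#' from source counts pooled with attributed sink counts (the unknown
#' profile from attributed sink counts alone). The tracked log-likelihood
#' (source multinomials plus sink mixture) is non-decreasing.
#'
#' @param source_counts Matrix (K sources x T taxa) of counts, or a single
#'   count vector for K = 1.
#' @param sink_counts Count vector of length T (same taxon order).
#' @param include_unknown Estimate an additional unknown source.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return An object of class `mixture_estimate`: list with `alpha`
#'   (length K or K + 1, summing to 1; last entry `"unknown"` when
#'   estimated), `gamma` (profiles, rows summing to 1), `loglik_trace`,
#'   `n_iter`, `converged`.
#' @export
em_fit <- function(source_counts, sink_counts, include_unknown = TRUE,
                   tol = 1e-6, max_iter = 1000) {
  if (is.vector(source_counts)) source_counts <- matrix(source_counts, nrow = 1)
  source_counts <- as.matrix(source_counts)
  x <- as.numeric(sink_counts)
  if (length(x) != ncol(source_counts)) stop("sink and source taxon sets are misaligned")
  if (sum(x) <= 0) stop("empty sink")
  K <- nrow(source_counts)
  eps <- 1e-10
  src_names <- rownames(source_counts)
  if (is.null(src_names)) src_names <- sprintf("source%d", seq_len(K))
  gamma_known <- (source_counts + eps) / rowSums(source_counts + eps)
  if (include_unknown) {
    # initialize the unknown profile from the sink mass the known sources
    # cannot explain; a flat start lets the free component ride the
    # likelihood ridge and absorb known-source contributions. The
    # unexplained mass is measured against a preliminary known-sources-only
    # fit of the sink.
    x_rel <- x / sum(x)
    pre <- em_fit(source_counts, sink_counts, include_unknown = FALSE,
                  tol = tol, max_iter = max_iter)
    resid <- pmax(x_rel - drop(crossprod(pre$gamma, pre$alpha)), 0)
    if (sum(resid) == 0) resid <- rep(1, length(x))
    gam <- rbind(gamma_known, (resid + eps) / sum(resid + eps))
    rownames(gam) <- c(src_names, "unknown")
  } else {
    gam <- gamma_known
    rownames(gam) <- src_names
  }
  M <- nrow(gam)
  alpha <- rep(1 / M, M)
  loglik <- function(alpha, gam) {
    mix <- drop(crossprod(gam, alpha))
    sum(x[x > 0] * log(mix[x > 0])) +
      sum(source_counts[source_counts > 0] *
            log(gam[seq_len(K), , drop = FALSE][source_counts > 0]))
  }
  trace <- loglik(alpha, gam)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: responsibility of source k for each sink read on taxon j
    num <- alpha * gam                     # M x T (rows scaled)
    denom <- colSums(num)
    denom[denom == 0] <- eps
    r <- sweep(num, 2, denom, "/")
    attributed <- sweep(r, 2, x, "*")      # M x T attributed sink counts
    # M-step
    alpha <- rowSums(attributed) / sum(x)
    new_gam <- attributed
    new_gam[seq_len(K), ] <- new_gam[seq_len(K), , drop = FALSE] + source_counts
    new_gam <- new_gam + eps
    gam <- new_gam / rowSums(new_gam)
    ll <- loglik(alpha, gam)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  names(alpha) <- rownames(gam)
  structure(
    list(alpha = alpha, gamma = gam, loglik_trace = trace,
         n_iter = iter, converged = converged),
    class = "mixture_estimate"
  )
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("EM source-tracking estimate (", x$n_iter, " iterations",
      if (x$converged) ", converged" else "", ")\n", sep = "")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Bidirectional surface-to-surface contribution analysis
#'
#' Treats each surface type in turn as the sink and all remaining surface
#' types as sources: every sink sample is fitted with [em_fit()] against the
#' pooled count profile of each other surface (plus an unknown source), and
#' per-(sink, source) mean and standard deviation of the estimated mixing
#' proportions are reported.
#'
#' @param x A counts [abundance_table()].
#' @param metadata Metadata aligned to `x`.
#' @param surface_field Metadata column naming the surface type.
#' @param include_unknown Estimate the unknown source (default TRUE).
#' @return A list with `mean` and `sd` matrices (sink surfaces in rows,
#'   source surfaces plus `"unknown"` in columns; `mean` rows sum to 1) and
#'   `samples`, the per-sink-sample alpha table.
#' @export
bidirectional_contributions <- function(x, metadata, surface_field = "surface_type",
                                        include_unknown = TRUE) {
  stopifnot(inherits(x, "abundance_table"), surface_field %in% names(metadata))
  surf <- as.character(metadata[[surface_field]][match(x$sample_ids, metadata$sample_id)])
  counts <- table(surf)
  usable <- names(counts)[counts >= 2]
  dropped <- setdiff(names(counts), usable)
  if (length(dropped)) warning("surfaces with fewer than 2 samples excluded: ",
                               paste(dropped, collapse = ", "))
  if (length(usable) < 2) stop("need at least 2 surface types with >= 2 samples")
  pooled <- rowsum(x$values, group = surf)
  cols <- c(usable, if (include_unknown) "unknown")
  mean_mat <- matrix(NA_real_, length(usable), length(cols),
                     dimnames = list(usable, cols))
  sd_mat <- mean_mat
  per_sample <- list()
  for (sink in usable) {
    sources <- setdiff(usable, sink)
    src_counts <- pooled[sources, , drop = FALSE]
    sink_rows <- which(surf == sink)
    alphas <- t(vapply(sink_rows, function(i) {
      fit <- em_fit(src_counts, x$values[i, ], include_unknown = include_unknown)
      fit$alpha
    }, numeric(length(sources) + include_unknown)))
    colnames(alphas) <- c(sources, if (include_unknown) "unknown")
    per_sample[[sink]] <- data.frame(
      sink_surface = sink,
      sample_id = rep(x$sample_ids[sink_rows], ncol(alphas)),
      source_surface = rep(colnames(alphas), each = nrow(alphas)),
      alpha = as.vector(alphas), stringsAsFactors = FALSE)
    mean_mat[sink, colnames(alphas)] <- colMeans(alphas)
    sd_mat[sink, colnames(alphas)] <- apply(alphas, 2, stats::sd)
    mean_mat[sink, sink] <- 0
    sd_mat[sink, sink] <- 0
  }
  list(mean = mean_mat, sd = sd_mat,
       samples = do.call(rbind, c(per_sample, make.row.names = FALSE)))
}
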