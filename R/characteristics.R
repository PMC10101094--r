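#' Discretize a continuous characteristic into ordered bins
#'
#' Equal-width bins over \[min, max\], right-inclusive, with the lowest edge
#' nudged down by 0.1% of the range so the minimum falls in the first bin.
#' With `n_bins = 3` the labels are low/medium/high.
#'
#' @param values Numeric vector with at least `n_bins` distinct values.
#' @param n_bins Number of bins (default 3).
#' @param labels Bin labels (defaults to low/medium/high for 3 bins).
#' @return A factor of bin labels, ordered with the values.
#' @export
discretize <- function(values, n_bins = 3,
                       labels = if (n_bins == 3) c("low", "medium", "high") else NULL) {
  values <- as.numeric(values)
  if (length(unique(values)) < n_bins) {
    stop("fewer distinct values than bins")
  }
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  breaks[1] <- rng[1] - 0.001 * diff(rng)
  cut(values, breaks = breaks, labels = labels, right = TRUE)
}

#' @keywords internal
characteristic_labels <- function(metadata, characteristic, n_bins = 3) {
  vals <- metadata[[characteristic]]
  if (is.numeric(vals)) {
    city_vals <- tapply(vals, metadata$city, function(v) v[1])
    if (length(unique(city_vals)) < n_bins) return(NULL)
    city_lab <- discretize(as.numeric(city_vals), n_bins)
    factor(as.character(city_lab[match(metadata$city, names(city_vals))]),
           levels = levels(city_lab))
  } else {
    factor(vals)
  }
}

#' Predict city characteristics from mined city-specific genera
#'
#' For each characteristic (continuous ones first discretized into 3
#' equal-width bins at the city level), trains an independent model (IM) on
#' the target surface's training portion and a transfer model (TM, a base
#' model trained on the other surfaces SER-adapted to the training portion),
#' under a stratified `train_frac`/rest split repeated `repeats` times, and
#' reports the mean per-city test accuracy.
#'
#' @param x An [abundance_table()].
#' @param metadata Aligned metadata; characteristics are inherited from the
#'   sample's city.
#' @param features Genus names used as classifier features (e.g. the top-50
#'   city-specific genera of one surface).
#' @param target_surface Surface whose samples are split and scored.
#' @param characteristics Character vector of metadata columns to predict.
#' @param repeats Number of data configurations (default 10).
#' @param train_frac Training fraction (default 0.2).
#' @param n_trees,min_leaf,seed Forest and transfer parameters.
#' @return A data.frame keyed by (characteristic, city, model_kind) with
#'   `accuracy` (mean over repeats), `n_test` (mean test samples per
#'   repeat) and `low_n` flag for cities with fewer than 20 target-surface
#'   samples. Characteristics constant over the cities are skipped with a
#'   warning.
#' @export
predict_characteristics <- function(x, metadata, features, target_surface,
                                    characteristics = c("latitude", "longitude",
                                                        "elevation", "population",
                                                        "population_density",
                                                        "coastal_proximity", "region",
                                                        "avg_june_temp", "koppen_climate"),
                                    repeats = 10, train_frac = 0.2,
                                    n_trees = 100, min_leaf = 5, seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  if (!x$is_relative) x <- to_relative(x)
  md <- metadata[match(x$sample_ids, metadata$sample_id), ]
  feat <- x$values[, sort(features), drop = FALSE]
  target <- which(md$surface_type == target_surface)
  other <- which(md$surface_type != target_surface)
  out <- list()
  for (ch in characteristics) {
    if (!ch %in% names(md)) {
      warning("characteristic '", ch, "' missing from metadata; skipped")
      next
    }
    labels <- characteristic_labels(md, ch)
    if (is.null(labels) || length(unique(labels[c(target, other)])) < 2) {
      warning("characteristic '", ch, "' is (near-)constant; skipped")
      next
    }
    acc <- list()
    for (r in seq_len(repeats)) {
      rseed <- seed + r
      train <- stratified_split(labels[target], train_frac, rseed)
      tr <- target[train]; te <- target[!train]
      if (length(unique(labels[tr])) < 2) next
      im <- train_forest(feat[tr, , drop = FALSE], labels[tr],
                         n_trees = n_trees, seed = rseed)
      bm <- train_forest(feat[other, , drop = FALSE],
                         factor(labels[other], levels = levels(labels)),
                         n_trees = n_trees, seed = rseed)
      tm <- ser_transfer(bm, feat[tr, , drop = FALSE], labels[tr],
                         min_leaf = min_leaf, seed = rseed)
      for (kind in c("IM", "TM")) {
        model <- if (kind == "IM") im else tm
        pred <- as.character(predict(model, feat[te, , drop = FALSE], type = "class"))
        correct <- pred == as.character(labels[te])
        for (city in unique(md$city[te])) {
          sel <- md$city[te] == city
          acc[[length(acc) + 1]] <- data.frame(
            characteristic = ch, city = city, model_kind = kind, repeat_id = r,
            accuracy = mean(correct[sel]), n_test = sum(sel),
            stringsAsFactors = FALSE)
        }
      }
    }
    acc <- do.call(rbind, acc)
    if (is.null(acc)) next
    agg <- stats::aggregate(cbind(accuracy, n_test) ~ characteristic + city + model_kind,
                            data = acc, FUN = mean)
    n_city <- table(md$city[target])
    agg$low_n <- n_city[agg$city] < 20
    out[[ch]] <- agg
  }
  if (!length(out)) stop("no characteristic could be modelled")
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Compare mined features against random control feature sets
#'
#' Draws `n_controls` random feature sets of the same size from the
#' non-selected genera, runs the same characteristic-prediction protocol on
#' each, and tests (one-sided paired Wilcoxon signed-rank, paired by repeat)
#' whether the selected features outperform the controls.
#'
#' @param x An [abundance_table()].
#' @param metadata Aligned metadata.
#' @param selected_features The mined genus set.
#' @param target_surface Surface whose samples are scored.
#' @param characteristic Single metadata column to predict.
#' @param n_controls Number of random control sets (>= 1).
#' @param repeats,train_frac,n_trees,min_leaf,seed As in
#'   [predict_characteristics()].
#' @return A list with `selected_accuracy` (per-repeat overall accuracies),
#'   `control_accuracy` (repeats x n_controls matrix), `frac_controls_beaten`
#'   (fraction of control sets with lower mean accuracy), `statistic` and
#'   `p_value` of the Wilcoxon test.
#' @export
control_comparison <- function(x, metadata, selected_features, target_surface,
                               characteristic, n_controls = 20, repeats = 10,
                               train_frac = 0.2, n_trees = 100, min_leaf = 5,
                               seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  if (n_controls < 1) stop("n_controls must be >= 1")
  pool <- setdiff(x$taxon_ids, selected_features)
  if (length(pool) < length(selected_features)) {
    stop("non-selected genus pool smaller than the selected feature set")
  }
  if (!x$is_relative) x <- to_relative(x)
  md <- metadata[match(x$sample_ids, metadata$sample_id), ]
  labels <- characteristic_labels(md, characteristic)
  if (is.null(labels)) stop("characteristic '", characteristic, "' is degenerate")
  target <- which(md$surface_type == target_surface)
  other <- which(md$surface_type != target_surface)
  run_features <- function(feats) {
    feat <- x$values[, sort(feats), drop = FALSE]
    vapply(seq_len(repeats), function(r) {
      rseed <- seed + r
      train <- stratified_split(labels[target], train_frac, rseed)
      tr <- target[train]; te <- target[!train]
      bm <- train_forest(feat[other, , drop = FALSE],
                         factor(labels[other], levels = levels(labels)),
                         n_trees = n_trees, seed = rseed)
      tm <- ser_transfer(bm, feat[tr, , drop = FALSE], labels[tr],
                         min_leaf = min_leaf, seed = rseed)
      pred <- as.character(predict(tm, feat[te, , drop = FALSE], type = "class"))
      mean(pred == as.character(labels[te]))
    }, numeric(1))
  }
  selected_acc <- run_features(selected_features)
  controls <- with_seed(derive_seed(seed, "controls"), {
    lapply(seq_len(n_controls), function(i) sample(pool, length(selected_features)))
  })
  control_acc <- vapply(controls, run_features, numeric(repeats))
  control_acc <- matrix(control_acc, nrow = repeats)
  wt <- stats::wilcox.test(rep(selected_acc, n_controls), as.vector(control_acc),
                           paired = TRUE, alternative = "greater", exact = FALSE)
  list(selected_accuracy = selected_acc, control_accuracy = control_acc,
       frac_controls_beaten = mean(colMeans(control_acc) < mean(selected_acc)),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
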