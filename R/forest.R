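#' Train a bagged CART classification forest
#'
#' Native random forest (gini splits, per-split feature subsampling of size
#' `mtry`, bootstrap resampling per tree) used for city and
#' city-characteristic classification. Implemented in compiled code with a
#' structural contract — decision-path traversal and mutable leaves — so the
#' same trees can later be adapted to a new domain with [ser_transfer()].
#' Fully deterministic: identical (data, config, seed) give identical trees.
#'
#' @param features Numeric matrix, samples x features (genus relative
#'   abundances).
#' @param labels Factor (or coercible) of class labels; at least two classes
#'   must be present. Factor levels define the probability columns even if
#'   some levels are absent from this training set.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features per split (default `ceiling(sqrt(ncol(features)))`).
#' @param min_split Minimum node size to attempt a split (default 2).
#' @param max_depth Maximum tree depth (default 30).
#' @param seed Integer seed.
#' @return An object of class `forest_model`.
#' @export
train_forest <- function(features, labels, n_trees = 100, mtry = NULL,
                         min_split = 2, max_depth = 30, seed = 1) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) != length(labels)) stop("features and labels are misaligned")
  present <- unique(as.character(labels))
  if (length(present) < 2) stop("need at least 2 classes present in the training labels")
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(features)))
  y <- as.integer(labels) - 1L
  trees <- rf_train_cpp(features, y, nlevels(labels), as.integer(n_trees),
                        as.integer(mtry), as.integer(min_split),
                        as.integer(max_depth), as.integer(seed))
  structure(
    list(trees = trees, classes = levels(labels),
         feature_names = colnames(features), n_trees = n_trees, mtry = mtry,
         min_split = min_split, max_depth = max_depth, seed = seed,
         trained_on = sprintf("%d samples x %d features", nrow(features), ncol(features))),
    class = "forest_model"
  )
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees, mtry %d, %d classes (%s)\n",
              x$n_trees, x$mtry, length(x$classes), x$trained_on))
  invisible(x)
}

#' Predict class probabilities or labels from a forest
#'
#' @param object A `forest_model`.
#' @param newdata Numeric matrix with the model's features (matched by name
#'   when column names are present).
#' @param type `"prob"` for a class-probability matrix (rows sum to 1) or
#'   `"class"` for hard labels.
#' @param ... Unused.
#' @export
predict.forest_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing)) stop("newdata lacks features: ", paste(missing, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  probs <- rf_predict_cpp(object$trees, newdata, length(object$classes))
  colnames(probs) <- object$classes
  rownames(probs) <- rownames(newdata)
  if (type == "prob") probs else
    factor(object$classes[max.col(probs, ties.method = "first")], levels = object$classes)
}

#' Macro-averaged one-vs-rest AUROC
#'
#' Computes the rank-statistic AUROC (ties credited 0.5) of each class
#' against the rest and macro-averages over the classes present in the
#' truth; classes with probability columns but no true instances are
#' excluded with a warning.
#'
#' @param true_labels Factor or character of true classes (at least 2
#'   present).
#' @param class_probabilities Matrix of scores with one named column per
#'   class.
#' @return A single AUROC in \[0, 1\].
#' @export
macro_auroc <- function(true_labels, class_probabilities) {
  truth <- as.character(true_labels)
  present <- unique(truth)
  if (length(present) < 2) stop("need at least 2 classes present in true_labels")
  cols <- colnames(class_probabilities)
  if (is.null(cols)) stop("class_probabilities must have named columns")
  absent <- setdiff(cols, present)
  if (length(absent)) {
    warning("classes absent from truth excluded from macro mean: ",
            paste(absent, collapse = ", "))
  }
  aucs <- vapply(intersect(cols, present), function(cl) {
    scores <- class_probabilities[, cl]
    pos <- truth == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(scores, ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  mean(aucs)
}

#' SER transfer adaptation of a trained forest
#'
#' Adapts a base forest to a new domain by structure expansion/reduction:
#' target samples are routed down each tree; leaves reached by at least
#' `min_leaf` target samples are expanded with a CART subtree grown on those
#' samples; then, bottom-up, any subtree whose collapsed-leaf target
#' misclassification is no worse than the subtree's is pruned to a leaf
#' labelled by the target majority. Leaf class probabilities are
#' re-estimated from target counts with Laplace (+1) smoothing wherever
#' target samples reach; leaves the target never visits keep their source
#' distribution.
#'
#' @param base_forest A `forest_model`.
#' @param target_features Numeric matrix of target-domain samples (same
#'   features as the base model).
#' @param target_labels Target labels; levels must be a subset of the base
#'   model's classes.
#' @param min_leaf Minimum target samples at a leaf to trigger expansion
#'   (default 5).
#' @param seed Integer seed for the expansion's feature subsampling.
#' @return A `forest_model` with adapted trees; attribute `n_unchanged`
#'   counts trees left unmodified.
#' @export
ser_transfer <- function(base_forest, target_features, target_labels,
                         min_leaf = 5, seed = base_forest$seed) {
  stopifnot(inherits(base_forest, "forest_model"))
  target_features <- as.matrix(target_features)
  if (nrow(target_features) == 0) stop("empty target set")
  if (!is.null(colnames(target_features)) && !is.null(base_forest$feature_names)) {
    target_features <- target_features[, base_forest$feature_names, drop = FALSE]
  }
  labels <- factor(as.character(target_labels), levels = base_forest$classes)
  if (anyNA(labels)) stop("target labels outside the base model's classes")
  y <- as.integer(labels) - 1L
  trees <- rf_ser_cpp(base_forest$trees, target_features, y,
                      length(base_forest$classes),
                      as.integer(base_forest$mtry),
                      as.integer(base_forest$min_split),
                      as.integer(base_forest$max_depth),
                      as.integer(min_leaf), as.integer(seed))
  out <- base_forest
  out$trees <- trees
  out$trained_on <- paste0(base_forest$trained_on, " + SER(",
                           nrow(target_features), " target samples)")
  attr(out, "n_unchanged") <- attr(trees, "n_unchanged")
  out
}

#' Select the genera with the highest abundance variance
#'
#' Standard preselection before city-specificity mining: the k genera with
#' the largest relative-abundance variance across samples, ties broken
#' lexicographically by genus name.
#'
#' @param x A relative [abundance_table()] (converted if counts).
#' @param k Number of genera (default 100).
#' @return Character vector of genus names, in decreasing-variance order.
#' @export
top_variance_genera <- function(x, k = 100) {
  stopifnot(inherits(x, "abundance_table"))
  if (!x$is_relative) x <- to_relative(x)
  v <- apply(x$values, 2, stats::var)
  if (k > length(v)) {
    warning("k exceeds the number of genera; returning all")
    k <- length(v)
  }
  ord <- order(-v, x$taxon_ids)
  x$taxon_ids[ord][seq_len(k)]
}

#' @keywords internal
stratified_split <- function(labels, frac, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_train <- max(1, round(frac * length(idx)))
      train[sample(idx, min(n_train, length(idx)))] <- TRUE
    }
    train
  })
}

#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

#' Evaluate base, independent and transfer city classifiers
#'
#' Reproduces the three-model comparison for one target surface type: the
#' base model (BM) is trained on all samples of the other surfaces, the
#' independent model (IM) on the target surface's training portion alone,
#' and the transfer model (TM) adapts the BM to the target training portion
#' with [ser_transfer()]. All three are scored with [macro_auroc()] on the
#' same target-surface validation samples. Protocol `"cv10"` uses
#' city-stratified 10-fold cross-validation per repeat; `"split"` uses a
#' stratified `train_frac` train / rest test split per repeat. Repeat r uses
#' seed `seed + r` for splits and tree randomness, shared across the three
#' models so comparisons are paired.
#'
#' @param x An [abundance_table()] (converted to relative abundances).
#' @param metadata Metadata aligned to `x` with `surface_type` and the label
#'   column.
#' @param target_surface Surface type to classify on.
#' @param protocol `"cv10"` or `"split"`.
#' @param train_frac Training fraction for the split protocol (default 0.2).
#' @param repeats Number of repeats (default 10).
#' @param features Genus names to use (default: all).
#' @param label_field Metadata column with the class label (default
#'   `"city"`).
#' @param n_trees,min_leaf,seed Forest and transfer parameters.
#' @return A data.frame with columns `model_kind` (BM/IM/TM), `repeat_id`,
#'   `fold`, `auroc`.
#' @export
evaluate_bm_im_tm <- function(x, metadata, target_surface,
                              protocol = c("cv10", "split"), train_frac = 0.2,
                              repeats = 10, features = NULL,
                              label_field = "city", n_trees = 100,
                              min_leaf = 5, seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(x, "abundance_table"))
  if (!x$is_relative) x <- to_relative(x)
  md <- metadata[match(x$sample_ids, metadata$sample_id), ]
  if (is.null(features)) features <- x$taxon_ids
  # canonical feature order: results do not depend on how the caller
  # ordered the feature list
  feat <- x$values[, sort(features), drop = FALSE]
  labels <- factor(md[[label_field]])
  target <- which(md$surface_type == target_surface)
  other <- which(md$surface_type != target_surface)
  if (length(target) == 0) stop("target surface has no samples")
  if (length(other) == 0) stop("no non-target surfaces available for the base model")
  if (protocol == "cv10" && length(target) < 10) {
    stop("target surface has fewer than 10 samples; use protocol = 'split'")
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    rseed <- seed + r
    bm <- train_forest(feat[other, , drop = FALSE], labels[other],
                       n_trees = n_trees, seed = rseed)
    if (protocol == "cv10") {
      fold <- stratified_folds(labels[target], 10, rseed)
      fold_ids <- sort(unique(fold))
    } else {
      train <- stratified_split(labels[target], train_frac, rseed)
      fold <- ifelse(train, 0L, 1L)
      fold_ids <- 1L
    }
    for (f in fold_ids) {
      tr <- target[fold != f]
      va <- target[fold == f]
      if (length(unique(labels[va])) < 2 || length(unique(labels[tr])) < 2) next
      im <- train_forest(feat[tr, , drop = FALSE], labels[tr],
                         n_trees = n_trees, seed = rseed)
      tm <- ser_transfer(bm, feat[tr, , drop = FALSE], labels[tr],
                         min_leaf = min_leaf, seed = rseed)
      for (kind in c("BM", "IM", "TM")) {
        model <- switch(kind, BM = bm, IM = im, TM = tm)
        probs <- predict(model, feat[va, , drop = FALSE])
        auc <- suppressWarnings(macro_auroc(labels[va], probs))
        rows[[length(rows) + 1]] <- data.frame(
          model_kind = kind, repeat_id = r, fold = f, auroc = auc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Delta-AUROC city specificity of genera
#'
#' Quantifies each genus's city specificity as the mean decrease in
#' transfer-model AUROC when the genus is excluded from the feature set:
#' for each repeat, the target surface is split (stratified, `train_frac`
#' train), a base model is trained on the other surfaces and SER-adapted on
#' the target training portion, once with all features and once per
#' leave-one-genus-out set; all fits within a repeat share the repeat seed,
#' so differences are paired.
#'
#' @param x An [abundance_table()].
#' @param metadata Aligned metadata.
#' @param target_surface Surface type whose samples are classified.
#' @param features Preselected genus names (see [top_variance_genera()]);
#'   at least 2.
#' @param repeats Number of repeats (default 10).
#' @param train_frac,label_field,n_trees,min_leaf,seed As in
#'   [evaluate_bm_im_tm()].
#' @return A data.frame with `genus`, `delta_auroc` (mean over repeats) and
#'   `rank` (1 = most city-specific), sorted by rank.
#' @export
city_specificity <- function(x, metadata, target_surface, features,
                             repeats = 10, train_frac = 0.2,
                             label_field = "city", n_trees = 100,
                             min_leaf = 5, seed = 1) {
  stopifnot(inherits(x, "abundance_table"))
  if (length(features) < 2) stop("need at least 2 features")
  features <- sort(features)
  if (!x$is_relative) x <- to_relative(x)
  md <- metadata[match(x$sample_ids, metadata$sample_id), ]
  labels <- factor(md[[label_field]])
  target <- which(md$surface_type == target_surface)
  other <- which(md$surface_type != target_surface)
  fit_auc <- function(feats, tr, te, rseed) {
    fm <- x$values[, feats, drop = FALSE]
    bm <- train_forest(fm[other, , drop = FALSE], labels[other],
                       n_trees = n_trees, seed = rseed)
    tm <- ser_transfer(bm, fm[tr, , drop = FALSE], labels[tr],
                       min_leaf = min_leaf, seed = rseed)
    suppressWarnings(macro_auroc(labels[te], predict(tm, fm[te, , drop = FALSE])))
  }
  deltas <- matrix(NA_real_, repeats, length(features),
                   dimnames = list(NULL, features))
  for (r in seq_len(repeats)) {
    rseed <- seed + r
    train <- stratified_split(labels[target], train_frac, rseed)
    tr <- target[train]; te <- target[!train]
    full <- fit_auc(features, tr, te, rseed)
    for (g in features) {
      deltas[r, g] <- full - fit_auc(setdiff(features, g), tr, te, rseed)
    }
  }
  delta <- colMeans(deltas)
  ord <- order(-delta, features)
  data.frame(genus = features[ord], delta_auroc = unname(delta[ord]),
             rank = seq_along(features), stringsAsFactors = FALSE)
}
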