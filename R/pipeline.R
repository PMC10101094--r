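#' Run the full analysis pipeline on a table/metadata pair
#'
#' Orchestrates the stages in dependency order: input loading (or synthetic
#' panel generation), preprocessing, neutral-model fitting per city,
#' null-model stochasticity, bidirectional source tracking, transfer-forest
#' city classification and city-specificity mining, characteristic
#' prediction, and association statistics. Every stochastic stage receives
#' a seed derived from the global seed via [derive_seed()], all results are
#' written as TSV/JSON under `out_dir`, and a manifest records inputs,
#' parameters, seeds and output checksums.
#'
#' @param config A list with elements:
#'   * `panel`: a [panel_config()] to simulate, or `table_path` +
#'     `metadata_path` pointing at TSV inputs;
#'   * `out_dir`: output directory;
#'   * `seed`: global integer seed (default 1);
#'   * `stages`: subset of `c("ncm", "stochasticity", "sourcetrack",
#'     "transfer_rf", "city_clf", "associate")` (default: all);
#'   * `params`: per-stage overrides (`n_null`, `repeats`, `n_features`,
#'     `n_trees`, `protocol`, `train_frac`, `target_surface`, `n_perm`,
#'     `max_stochasticity_samples`).
#' @return The manifest (invisibly), a list describing every written file.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages)) {
    c("ncm", "stochasticity", "sourcetrack", "transfer_rf", "city_clf", "associate")
  } else config$stages
  p <- utils::modifyList(
    list(n_null = 1000, repeats = 10, n_features = 100, n_trees = 100,
         protocol = "split", train_frac = 0.2, n_perm = 999,
         target_surface = NULL, max_stochasticity_samples = 200,
         top_features = 50, n_specificity_repeats = NULL),
    if (is.null(config$params)) list() else config$params)
  files <- character()
  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", name, sprintf(...)))
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_result_table(df, path)
    files <<- c(files, path)
    path
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(config$panel)) {
    panel <- config$panel
    panel$seed <- derive_seed(seed, "panel")
    sim <- simulate_city_panel(panel)
    tab <- sim$table; md <- sim$metadata
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(
      list(Nm = panel$Nm, niche_sigma = panel$niche_sigma,
           surface_shift_sd = panel$surface_shift_sd,
           signatures = lapply(panel$signatures, function(s) {
             list(characteristic = s$characteristic, level = s$level,
                  taxa = sim$table$taxon_ids[s$taxa], effect = s$effect)
           })),
      truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  } else {
    tab <- read_abundance_table(config$table_path)
    md <- read_sample_metadata(config$metadata_path)
  }
  tab <- remove_unassigned(tab)
  aligned <- filter_samples(tab, md, rep(TRUE, nrow(md)))
  tab <- aligned$table; md <- aligned$metadata
  rel <- to_relative(tab)
  emit(md, "metadata_used.tsv")
  log_stage("io", "%d samples x %d genera", nrow(tab$values), ncol(tab$values))

  surfaces <- unique(md$surface_type)
  target_surface <- if (is.null(p$target_surface)) surfaces[1] else p$target_surface
  char_cols <- intersect(c("latitude", "longitude", "elevation", "population",
                           "population_density", "coastal_proximity", "region",
                           "continent", "avg_june_temp", "koppen_climate"),
                         names(md))

  # --- neutral model per city ---------------------------------------------
  if ("ncm" %in% stages) {
    fits <- fit_ncm_by_group(tab, md, "city")
    per_taxon <- do.call(rbind, lapply(names(fits), function(city) {
      cbind(city = city, fits[[city]]$taxa)
    }))
    emit(per_taxon, "ncm_fit.tsv")
    summ <- lapply(fits, function(f) {
      list(Nm = f$Nm, m = f$m, N = f$N, d = f$d, r_squared = f$r_squared,
           partition = as.list(table(f$taxa$partition)))
    })
    path <- file.path(out_dir, "ncm_summary.json")
    jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA)
    files <- c(files, path)
    log_stage("ncm", "fitted %d cities; median R^2 = %.3f", length(fits),
              stats::median(vapply(fits, `[[`, numeric(1), "r_squared")))
  }

  # --- stochasticity -------------------------------------------------------
  if ("stochasticity" %in% stages) {
    sseed <- derive_seed(seed, "stochasticity")
    idx <- seq_len(nrow(tab$values))
    if (length(idx) > p$max_stochasticity_samples) {
      idx <- with_seed(sseed, {
        unlist(lapply(split(idx, md$city), function(i) {
          sample(i, min(length(i), ceiling(p$max_stochasticity_samples /
                                             length(unique(md$city)))))
        }), use.names = FALSE)
      })
      idx <- sort(idx)
    }
    sub <- abundance_table(tab$values[idx, , drop = FALSE])
    ps <- pairwise_stochasticity(sub, null_model_config(p$n_null, seed = sseed))
    groups <- md$city[idx]
    emit(summarize_by_group(ps, groups), "stochasticity_by_city.tsv")
    pm <- permanova_mst(ps$MST, md[idx, ], intersect(char_cols, names(md)),
                        n_perm = p$n_perm, seed = derive_seed(seed, "permanova_mst"))
    emit(pm, "permanova_mst.tsv")
    log_stage("stochasticity", "mean MST = %.3f over %d samples, %d nulls",
              mean(ps$MST[lower.tri(ps$MST)]), length(idx), p$n_null)
  }

  # --- source tracking -----------------------------------------------------
  if ("sourcetrack" %in% stages) {
    focal_city <- names(which.max(table(md$city)))
    sub <- filter_samples(tab, md, md$city == focal_city)
    bc <- bidirectional_contributions(sub$table, sub$metadata)
    long <- data.frame(
      sink_surface = rep(rownames(bc$mean), ncol(bc$mean)),
      source_surface = rep(colnames(bc$mean), each = nrow(bc$mean)),
      mean_alpha = as.vector(bc$mean), sd_alpha = as.vector(bc$sd),
      stringsAsFactors = FALSE)
    emit(long[!is.na(long$mean_alpha), ], "feast_contributions.tsv")
    log_stage("sourcetrack", "bidirectional contributions in %s", focal_city)
  }

  # --- transfer forest -----------------------------------------------------
  importance <- NULL
  if ("transfer_rf" %in% stages) {
    feats <- top_variance_genera(rel, p$n_features)
    ev <- evaluate_bm_im_tm(rel, md, target_surface, protocol = p$protocol,
                            train_frac = p$train_frac, repeats = p$repeats,
                            features = feats, n_trees = p$n_trees,
                            seed = derive_seed(seed, "transfer_rf"))
    emit(ev, "auroc_results.tsv")
    sp_rep <- if (is.null(p$n_specificity_repeats)) p$repeats else p$n_specificity_repeats
    importance <- city_specificity(rel, md, target_surface, feats,
                                   repeats = sp_rep, train_frac = p$train_frac,
                                   n_trees = p$n_trees,
                                   seed = derive_seed(seed, "specificity"))
    emit(importance, "importance.tsv")
    means <- tapply(ev$auroc, ev$model_kind, mean)
    log_stage("transfer_rf", "mean AUROC BM %.3f / IM %.3f / TM %.3f",
              means[["BM"]], means[["IM"]], means[["TM"]])
  }

  # --- characteristic prediction -------------------------------------------
  if ("city_clf" %in% stages) {
    if (is.null(importance)) stop("city_clf requires the transfer_rf stage")
    top <- utils::head(importance$genus, p$top_features)
    cc <- predict_characteristics(rel, md, top, target_surface,
                                  characteristics = char_cols,
                                  repeats = p$repeats, train_frac = p$train_frac,
                                  n_trees = p$n_trees,
                                  seed = derive_seed(seed, "city_clf"))
    emit(cc, "characteristic_accuracy.tsv")
    log_stage("city_clf", "%d (characteristic, city, model) cells", nrow(cc))
  }

  # --- association statistics ----------------------------------------------
  if ("associate" %in% stages) {
    genera <- if (!is.null(importance)) utils::head(importance$genus, 10) else
      top_variance_genera(rel, 10)
    assoc <- characteristic_association_panel(
      rel, md, genera, characteristics = setdiff(char_cols, "koppen_climate"),
      n_perm = p$n_perm, seed = derive_seed(seed, "associate"))
    emit(assoc$mantel, "mantel_results.tsv")
    if (!is.null(assoc$pearson)) {
      emit(data.frame(characteristic = rownames(assoc$pearson), assoc$pearson,
                      check.names = FALSE), "pearson_characteristics.tsv")
    }
    emit(data.frame(sample_id = rel$sample_ids, shannon = shannon_index(rel)),
         "shannon.tsv")
    D <- bray_curtis(rel)
    pc <- pcoa_ordination(D)
    emit(data.frame(sample_id = rownames(pc$coordinates),
                    pc$coordinates[, seq_len(min(2, ncol(pc$coordinates))), drop = FALSE]),
         "pcoa_coordinates.tsv")
    pmv <- permanova(D, md$surface_type, n_perm = p$n_perm,
                     seed = derive_seed(seed, "permanova_surface"))
    emit(data.frame(factor = "surface_type", pseudo_F = pmv$pseudo_F,
                    r_squared = pmv$r_squared, p_value = pmv$p_value),
         "permanova_results.tsv")
    log_stage("associate", "%d Mantel edges", nrow(assoc$mantel))
  }

  manifest <- list(
    seed = seed, stages = stages, params = p,
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' End-to-end synthetic demonstration run
#'
#' Generates the default multi-city panel with a planted climate signature
#' and a planted city-discriminating genus, then runs every pipeline stage
#' at demonstration scale (reduced null replicates and repeat counts so the
#' whole run stays interactive). Outputs mirror the full analysis: per-city
#' neutral-model fits, MST and beta_RC grade summaries with the
#' characteristic PERMANOVA, bidirectional surface contributions, BM/IM/TM
#' AUROCs with the genus importance table, characteristic prediction
#' accuracies, and the Mantel association panel.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param n_cities,samples_per_surface,n_taxa,depth Panel size overrides
#'   (defaults are the standard panel scaled to 6 cities x 15
#'   samples/surface for interactivity).
#' @return The run manifest (invisibly).
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("uts_demo_"),
                     n_cities = 6, samples_per_surface = 15,
                     n_taxa = 120, depth = 1e4) {
  panel <- panel_config(
    n_cities = n_cities, samples_per_surface = samples_per_surface,
    n_taxa = n_taxa, depth = depth,
    signatures = list(
      list(characteristic = "koppen_climate", level = "temperate",
           taxa = 1:3, effect = 8),
      list(characteristic = "city", level = "city01", taxa = 5, effect = 6)
    ),
    seed = seed)
  run_pipeline(list(
    panel = panel, out_dir = out_dir, seed = seed,
    params = list(n_null = 50, repeats = 3, n_features = 20, n_trees = 50,
                  n_specificity_repeats = 2, n_perm = 199,
                  max_stochasticity_samples = 120, top_features = 10)
  ))
}
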