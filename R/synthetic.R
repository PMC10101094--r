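#' Sample a metacommunity relative-abundance pool
#'
#' Draws the shared regional species pool from which local communities
#' assemble. A lognormal pool gives the familiar few-dominant/many-rare
#' shape; a log-series pool (shape close to 1) is far more skewed.
#'
#' @param n_taxa Number of genera (>= 2).
#' @param distribution `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog Lognormal parameters.
#' @param shape Log-series parameter in (0, 1); mass at abundance n is
#'   proportional to shape^n / n.
#' @param seed Integer seed; same seed gives an identical pool.
#' @return A list of class `metacommunity_pool` with `taxon_ids` and `p`
#'   (relative abundances summing to 1).
#' @export
sample_metacommunity <- function(n_taxa, distribution = c("lognormal", "logseries"),
                                 meanlog = 0, sdlog = 1, shape = 0.99, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  distribution <- match.arg(distribution)
  p <- with_seed(seed, {
    if (distribution == "lognormal") {
      stats::rlnorm(n_taxa, meanlog = meanlog, sdlog = sdlog)
    } else {
      if (shape <= 0 || shape >= 1) stop("logseries shape must be in (0, 1)")
      nmax <- 100000L
      k <- seq_len(nmax)
      pk <- shape^k / k
      as.numeric(sample(k, n_taxa, replace = TRUE, prob = pk))
    }
  })
  structure(
    list(taxon_ids = sprintf("g%03d", seq_len(n_taxa)), p = p / sum(p)),
    class = "metacommunity_pool"
  )
}

#' Simulate neutrally assembled local communities
#'
#' Each local community is an independent draw from the stationary
#' distribution implied by the Sloan neutral model: a latent composition
#' from Dirichlet(Nm * p), observed through multinomial sampling at the
#' given sequencing depth. Nm (community size times immigration rate)
#' controls how tightly local communities track the metacommunity pool, so
#' fitting the neutral model to the output is a parameter-recovery exercise.
#'
#' @param pool A `metacommunity_pool`.
#' @param Nm Immigration-scaled community size (> 0).
#' @param n_samples Number of local communities.
#' @param depth Reads per sample (>= 1).
#' @param seed Integer seed.
#' @return A counts [abundance_table()], samples in rows.
#' @export
simulate_neutral <- function(pool, Nm, n_samples, depth, seed = NULL) {
  stopifnot(inherits(pool, "metacommunity_pool"))
  if (Nm <= 0) stop("Nm must be > 0")
  if (depth < 1) stop("depth must be >= 1")
  counts <- with_seed(seed, {
    t(vapply(seq_len(n_samples), function(i) {
      w <- rdirichlet1(Nm * pool$p)
      as.numeric(stats::rmultinom(1, size = depth, prob = w))
    }, numeric(length(pool$p))))
  })
  dimnames(counts) <- list(sprintf("s%04d", seq_len(n_samples)), pool$taxon_ids)
  abundance_table(counts)
}

#' Simulate niche-filtered local communities
#'
#' Before neutral sampling, the metacommunity pool is filtered by a Gaussian
#' niche kernel: in a sample with environment value e, taxon i with optimum
#' o_i contributes weight p_i * exp(-(e - o_i)^2 / (2 sigma^2)). As
#' `niche_sigma` grows the filter flattens and the output converges to
#' [simulate_neutral()].
#'
#' @param pool A `metacommunity_pool`.
#' @param env_values Environment value per sample.
#' @param optima Niche optimum per taxon.
#' @param niche_sigma Niche width (> 0; `Inf` disables filtering).
#' @param Nm,depth,seed As in [simulate_neutral()].
#' @return A counts [abundance_table()].
#' @export
simulate_niche <- function(pool, env_values, optima, niche_sigma, Nm, depth, seed = NULL) {
  stopifnot(inherits(pool, "metacommunity_pool"))
  if (niche_sigma <= 0) stop("niche_sigma must be > 0")
  if (length(optima) != length(pool$p)) stop("one optimum per taxon required")
  counts <- with_seed(seed, {
    t(vapply(seq_along(env_values), function(i) {
      filt <- if (is.infinite(niche_sigma)) rep(1, length(optima)) else
        exp(-(env_values[i] - optima)^2 / (2 * niche_sigma^2))
      w <- pool$p * filt
      if (sum(w) == 0) w <- pool$p
      w <- w / sum(w)
      comp <- rdirichlet1(Nm * w)
      as.numeric(stats::rmultinom(1, size = depth, prob = comp))
    }, numeric(length(pool$p))))
  })
  dimnames(counts) <- list(sprintf("s%04d", seq_along(env_values)), pool$taxon_ids)
  abundance_table(counts)
}

#' Configuration for a synthetic multi-city, multi-surface panel
#'
#' Defaults describe the standard study panel: 8 cities, the four main
#' transit-surface types, 25 samples per surface per city, 150 genera at a
#' sequencing depth of 20,000 reads — sized so a full analysis run stays
#' comfortably interactive on one CPU.
#'
#' @param n_cities Number of cities.
#' @param surfaces Character vector of surface types.
#' @param samples_per_surface Samples per (city, surface) cell.
#' @param n_taxa Number of genera in the metacommunity.
#' @param depth Reads per sample.
#' @param Nm Immigration-scaled community size of the neutral kernel.
#' @param niche_sigma Gaussian niche width applied against the per-city
#'   environment value (`Inf` = purely neutral assembly).
#' @param surface_shift_sd Standard deviation (log scale) of the per-surface
#'   multiplicative taxon biases; 0 makes surfaces exchangeable, larger
#'   values create the between-surface domain shift the transfer models are
#'   designed for.
#' @param char_climate_cor Correlation between continuous city
#'   characteristics and the climate category.
#' @param signatures List of planted signatures; each element is
#'   `list(characteristic =, level =, taxa =, effect =)` boosting the named
#'   taxa multiplicatively by `effect` in samples whose metadata
#'   characteristic equals `level`.
#' @param seed Integer seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_cities = 8,
                         surfaces = c("bench", "door", "handrail", "kiosk"),
                         samples_per_surface = 25,
                         n_taxa = 150,
                         depth = 2e4,
                         Nm = 500,
                         niche_sigma = Inf,
                         surface_shift_sd = 0.4,
                         char_climate_cor = 0.5,
                         signatures = list(),
                         seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (Nm <= 0) stop("Nm must be > 0")
  if (niche_sigma <= 0) stop("niche_sigma must be > 0")
  roles <- unlist(lapply(signatures, `[[`, "taxa"))
  if (anyDuplicated(roles)) {
    warning("the same taxon appears in more than one signature")
  }
  structure(
    list(n_cities = n_cities, surfaces = surfaces,
         samples_per_surface = samples_per_surface, n_taxa = n_taxa,
         depth = depth, Nm = Nm, niche_sigma = niche_sigma,
         surface_shift_sd = surface_shift_sd,
         char_climate_cor = char_climate_cor,
         signatures = signatures, seed = seed),
    class = "panel_config"
  )
}

#' Simulate a multi-city, multi-surface community panel with ground truth
#'
#' Generates per-city characteristics (Koppen-style climate category plus
#' continuous fields correlated with it), assembles each sample neutrally
#' from a shared lognormal metacommunity pool (optionally niche-filtered by
#' the city's climate-derived environment value), applies planted
#' characteristic signatures and per-surface multiplicative biases, and
#' draws counts at the configured depth.
#'
#' @param config A [panel_config()].
#' @return A list with `table` (counts [abundance_table()]), `metadata`
#'   (data.frame) and `truth` (the generating parameters: pool, Nm,
#'   surface biases, signatures, per-city environment values).
#' @export
simulate_city_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    climates <- c("tropical", "arid", "temperate", "continental", "polar")
    continents <- c("Asia", "Europe", "North America", "South America",
                    "Africa", "Oceania")
    n_city <- config$n_cities
    cities <- sprintf("city%02d", seq_len(n_city))
    # round-robin over a shuffled level order: every climate level is
    # represented once the panel has >= 5 cities
    climate <- sample(rep(sample(climates), length.out = n_city))
    climate_idx <- match(climate, climates)
    rho <- config$char_climate_cor
    mix <- function(signal, sd0) {
      z <- scale(signal)[, 1]
      if (stats::sd(signal) == 0) z <- rep(0, length(signal))
      rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_city) * 1 + 0 * sd0
    }
    city_md <- data.frame(
      city = cities,
      koppen_climate = climate,
      continent = sample(continents, n_city, replace = TRUE),
      latitude = pmax(-90, pmin(90, 12 * mix(climate_idx, 1) + 15 * climate_idx - 20)),
      longitude = stats::runif(n_city, -180, 180),
      elevation = round(exp(stats::rnorm(n_city, 5.5, 1))),
      population = round(exp(4 + 0.5 * mix(climate_idx, 1) + stats::rnorm(n_city, 10, 0.8))),
      coastal_proximity = sample(c("coastal", "inland"), n_city, replace = TRUE),
      avg_june_temp = round(28 - 5 * climate_idx + 3 * mix(-climate_idx, 1) + 10, 1),
      stringsAsFactors = FALSE
    )
    city_md$region <- paste(city_md$continent,
                            ifelse(city_md$longitude >= 0, "east", "west"))
    city_md$population_density <- round(city_md$population /
                                          exp(stats::rnorm(n_city, 6, 0.5)))
    env_by_city <- stats::setNames(climate_idx + stats::rnorm(n_city, 0, 0.1), cities)

    pool <- sample_metacommunity(config$n_taxa, "lognormal",
                                 seed = derive_seed(config$seed, "pool"))
    optima <- stats::runif(config$n_taxa, 0.5, length(climates) + 0.5)
    surf_bias <- vapply(config$surfaces, function(s) {
      exp(stats::rnorm(config$n_taxa, 0, config$surface_shift_sd))
    }, numeric(config$n_taxa))
    colnames(surf_bias) <- config$surfaces

    n_total <- n_city * length(config$surfaces) * config$samples_per_surface
    md <- data.frame(
      sample_id = sprintf("s%05d", seq_len(n_total)),
      city = rep(cities, each = length(config$surfaces) * config$samples_per_surface),
      surface_type = rep(rep(config$surfaces, each = config$samples_per_surface), n_city),
      stringsAsFactors = FALSE
    )
    md <- merge(md, city_md, by = "city", sort = FALSE)
    md <- md[order(md$sample_id), c("sample_id", setdiff(names(md), "sample_id"))]
    rownames(md) <- NULL

    counts <- matrix(0, n_total, config$n_taxa,
                     dimnames = list(md$sample_id, pool$taxon_ids))
    for (i in seq_len(n_total)) {
      w <- pool$p
      if (!is.infinite(config$niche_sigma)) {
        e <- env_by_city[[md$city[i]]]
        w <- w * exp(-(e - optima)^2 / (2 * config$niche_sigma^2))
      }
      for (sg in config$signatures) {
        if (identical(as.character(md[[sg$characteristic]][i]), as.character(sg$level))) {
          w[sg$taxa] <- w[sg$taxa] * sg$effect
        }
      }
      w <- w * surf_bias[, md$surface_type[i]]
      w <- w / sum(w)
      comp <- rdirichlet1(config$Nm * w)
      counts[i, ] <- stats::rmultinom(1, size = config$depth, prob = comp)
    }
    list(table = abundance_table(counts), metadata = md,
         truth = list(pool = pool, Nm = config$Nm, optima = optima,
                      niche_sigma = config$niche_sigma,
                      env_by_city = env_by_city, surface_bias = surf_bias,
                      signatures = config$signatures))
  })
}

#' Simulate a source/sink mixture with an unknown source
#'
#' Builds a sink community as a multinomial draw from a convex combination
#' of known source profiles plus one freshly drawn unknown profile, and
#' draws observed counts for each known source — the ground-truth input for
#' source-tracking recovery tests.
#'
#' @param source_profiles Matrix (K sources x T taxa) of relative
#'   abundances; rows are renormalized.
#' @param alpha Mixing proportions of length K + 1; the last entry is the
#'   unknown-source proportion. Must be non-negative and sum to 1.
#' @param depth Sink sequencing depth (>= 1).
#' @param source_depth Depth for each observed source (default `depth`).
#' @param seed Integer seed.
#' @return A list with `source_counts` (K x T), `sink_counts` (length T),
#'   and `unknown_profile`.
#' @export
simulate_source_sink <- function(source_profiles, alpha, depth,
                                 source_depth = depth, seed = NULL) {
  source_profiles <- as.matrix(source_profiles)
  K <- nrow(source_profiles)
  if (length(alpha) != K + 1) stop("alpha must have one entry per source plus the unknown")
  if (any(alpha < 0)) stop("alpha must be non-negative")
  if (abs(sum(alpha) - 1) > 1e-9) stop("alpha must sum to 1")
  if (depth < 1) stop("depth must be >= 1")
  gam <- source_profiles / rowSums(source_profiles)
  with_seed(seed, {
    unknown <- rdirichlet1(rep(0.5, ncol(gam)))
    mixture <- drop(crossprod(rbind(gam, unknown), alpha))
    sink <- as.numeric(stats::rmultinom(1, depth, mixture))
    src <- t(vapply(seq_len(K), function(k) {
      as.numeric(stats::rmultinom(1, source_depth, gam[k, ]))
    }, numeric(ncol(gam))))
    rownames(src) <- rownames(source_profiles)
    colnames(src) <- colnames(source_profiles)
    names(sink) <- colnames(source_profiles)
    list(source_counts = src, sink_counts = sink, unknown_profile = unknown)
  })
}

#' Explicit Moran-process neutral simulator (slow cross-check)
#'
#' Runs the individual-based neutral dynamics directly: a local community of
#' N individuals where each death is replaced by an immigrant from the
#' metacommunity (probability m) or the offspring of a random local
#' individual. Provided as an independent cross-check of the stationary
#' Dirichlet sampler used by [simulate_neutral()]; far too slow for routine
#' use.
#'
#' @param pool A `metacommunity_pool`.
#' @param N Local community size (individuals).
#' @param m Immigration probability per replacement.
#' @param n_samples Number of communities.
#' @param generations Number of complete turnovers (N replacements each).
#' @param seed Integer seed.
#' @return A counts [abundance_table()] of the final community states.
#' @export
simulate_neutral_moran <- function(pool, N, m, n_samples, generations = 50, seed = NULL) {
  stopifnot(inherits(pool, "metacommunity_pool"))
  K <- length(pool$p)
  with_seed(seed, {
    counts <- t(vapply(seq_len(n_samples), function(s) {
      com <- as.numeric(stats::rmultinom(1, N, pool$p))
      for (step in seq_len(generations * N)) {
        dead <- sample.int(K, 1, prob = com)
        com[dead] <- com[dead] - 1
        born <- if (stats::runif(1) < m) {
          sample.int(K, 1, prob = pool$p)
        } else if (sum(com) > 0) {
          sample.int(K, 1, prob = com)
        } else {
          sample.int(K, 1, prob = pool$p)
        }
        com[born] <- com[born] + 1
      }
      com
    }, numeric(K)))
    dimnames(counts) <- list(sprintf("s%04d", seq_len(n_samples)), pool$taxon_ids)
    abundance_table(counts)
  })
}
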