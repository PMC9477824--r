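# Synthetic experiment generator. Every stochastic quantity is drawn under
# the config seed, so identical config + seed reproduces identical output.

# Dirichlet draw (rows = draws) via normalised gammas.
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Draw source community profiles from the configured Dirichlet priors
#'
#' @param config An [experiment_config()].
#' @param seed RNG seed; defaults to the config seed.
#' @return Taxa x source matrix of relative abundances (columns sum to 1).
#' @export
generate_source_profiles <- function(config, seed = config$seed) {
  conc <- config$source_concentration
  with_seed(seed, {
    prof <- t(vapply(seq_len(nrow(conc)),
                     function(i) rdirichlet(1, conc[i, ])[1, ],
                     numeric(ncol(conc))))
  })
  dimnames(prof) <- dimnames(conc)
  t(prof)  # taxa x sources
}

# Expected slide abundance at each collection for one treatment, and the
# per-route share of the standing immigrant pool (death discounts every
# route's arrivals equally in time, so shares follow the same recursion).
slide_expectation <- function(config, treatment) {
  days <- c(0, config$collection_days)
  n_int <- length(config$collection_days)
  routes <- c("above", "near", "below")
  N_route <- stats::setNames(numeric(3), routes)
  total <- numeric(n_int)
  shares <- matrix(0, nrow = 3, ncol = n_int,
                   dimnames = list(routes, NULL))
  exposed <- route_exposures()[[treatment]]
  for (j in seq_len(n_int)) {
    dt <- days[j + 1] - days[j]
    for (r in routes) {
      active <- r %in% exposed && (r != "below" || config$rain_intervals[j])
      I_r <- if (active) config$immigration_per_route[r, j] else 0
      N_route[r] <- accumulate_immigration(I_r, config$death_rate_delta,
                                           dt, N0 = N_route[r])
    }
    total[j] <- sum(N_route)
    if (total[j] > 0) shares[, j] <- N_route / total[j]
  }
  list(expected = total, route_shares = shares)
}

#' Simulate death-rate slides
#'
#' Slides pre-loaded with `death_slide_n0` cells and closed to dispersal are
#' deployed at day 0 and sampled at every collection; expected abundance
#' decays as `N0 * exp(-delta * t)` with multiplicative lognormal noise.
#'
#' @param config An [experiment_config()].
#' @param seed RNG seed; defaults to the config seed.
#' @return Data frame with columns `block`, `day`, `abundance` including
#'   timepoint-0 samples.
#' @export
generate_death_slides <- function(config, seed = config$seed) {
  if (config$death_slide_n0 <= 0) stop_field("death_slide_n0", "must be > 0")
  days <- c(0, config$collection_days)
  grid <- expand.grid(block = seq_len(config$n_blocks), day = days)
  mu <- config$death_slide_n0 * exp(-config$death_rate_delta * grid$day)
  with_seed(seed, {
    grid$abundance <- mu * lognormal_noise(nrow(grid), config$count_noise_cv)
  })
  grid[order(grid$day, grid$block), c("block", "day", "abundance")]
}

#' Draw a sink community from a mixture of source profiles
#'
#' @param profiles Taxa x source matrix of relative abundances.
#' @param weights Mixing weights over the sources (recycled to columns);
#'   must be non-negative with positive sum.
#' @param depth Multinomial read depth.
#' @param seed Optional RNG seed.
#' @return Integer count vector over taxa.
#' @export
simulate_sink <- function(profiles, weights, depth, seed = NULL) {
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  p <- as.numeric(profiles %*% w)
  with_seed(seed, counts <- stats::rmultinom(1, size = depth, prob = p)[, 1])
  stats::setNames(as.integer(counts), rownames(profiles))
}

#' Generate a complete synthetic dispersal experiment
#'
#' Produces, for every block x treatment x substrate x collection day, a
#' sample with metadata, cell abundances, community profiles and (for
#' litterbags) mass records, alongside the death-rate slide series and the
#' environmental source samples — plus the full generating truth, so any
#' downstream estimate can be checked by parameter recovery.
#'
#' Slides accumulate immigrants under the immigration-death balance, summing
#' the treatment's exposed routes and silencing the below-surface route in
#' rain-free intervals; their communities are pure immigrant mixtures
#' weighted by each route's standing pool. Litterbags carry a resident
#' phyllosphere community that mixes geometrically toward the immigrant pool
#' by `succession_mixing` per interval, and lose dry mass per interval with
#' the route boost applied to the first interval of above/near-exposed
#' treatments. Closed slides receive no cells and are flagged below
#' detection rather than given a community profile.
#'
#' @param config An [experiment_config()].
#' @param seed Master seed; defaults to the config seed.
#' @param communities Set `FALSE` to skip the multinomial community draws
#'   (abundance, death-slide and mass records only) — much faster for
#'   replication studies of the demographic estimators.
#' @return Object of class `dispersal_experiment`: list with `metadata`,
#'   `cell_counts`, `death_counts`, `communities` (matrices `slides`,
#'   `litter`, `sources`), `source_labels`, `mass`, `below_detection`
#'   and `truth`.
#' @export
#' @examples
#' cfg <- experiment_config(n_blocks = 3, n_taxa = 40, seq_depth = 200)
#' ex <- generate_experiment(cfg)
#' head(ex$metadata)
generate_experiment <- function(config, seed = config$seed,
                                communities = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  n_int <- length(config$collection_days)
  seeds <- derive_seeds(seed, 7)
  profiles <- if (communities) {
    generate_source_profiles(config, seeds[[1]])
  } else {
    matrix(1 / config$n_taxa, nrow = config$n_taxa, ncol = 4,
           dimnames = list(sprintf("t%03d", seq_len(config$n_taxa)),
                           c("air", "litter", "soil", "phyllosphere")))
  }
  rs <- route_sources()
  near_litter_boost <- 0.1  # modest abundance gain where the near route feeds litter

  # --- metadata ------------------------------------------------------------
  grid <- expand.grid(block = seq_len(config$n_blocks),
                      treatment = config$treatments,
                      substrate = c("slide", "litter"),
                      day = config$collection_days,
                      stringsAsFactors = FALSE)
  grid$interval <- match(grid$day, config$collection_days)
  grid$surface <- ifelse(grid$treatment == "Elevated", "table", "ground")
  grid$rain <- config$rain_intervals[grid$interval]
  grid$sample_id <- sprintf("B%d_%s_%s_d%03d", grid$block, grid$treatment,
                            grid$substrate, grid$day)
  meta <- grid[order(grid$day, grid$substrate, grid$treatment, grid$block),
               c("sample_id", "block", "treatment", "substrate", "day",
                 "surface", "rain")]
  rownames(meta) <- NULL

  # --- expectations per treatment ------------------------------------------
  exp_by_trt <- lapply(stats::setNames(nm = config$treatments),
                       function(tr) slide_expectation(config, tr))

  # --- cell counts ----------------------------------------------------------
  is_slide <- meta$substrate == "slide"
  interval <- match(meta$day, config$collection_days)
  mu <- numeric(nrow(meta))
  mu[is_slide] <- mapply(function(tr, j) exp_by_trt[[tr]]$expected[j],
                         meta$treatment[is_slide], interval[is_slide])
  near_exposed <- vapply(meta$treatment,
                         function(tr) "near" %in% route_exposures()[[tr]],
                         logical(1))
  mu[!is_slide] <- config$resident_abundance *
    (1 + near_litter_boost * near_exposed[!is_slide])
  with_seed(seeds[[2]], {
    noise <- lognormal_noise(nrow(meta), config$count_noise_cv)
  })
  cell_counts <- data.frame(sample_id = meta$sample_id,
                            substrate = meta$substrate,
                            abundance = mu * noise)

  death_counts <- generate_death_slides(config, seeds[[3]])

  # --- slide communities (pure immigrant mixtures) -------------------------
  slide_meta <- meta[is_slide, ]
  slide_int <- match(slide_meta$day, config$collection_days)
  detected <- mapply(function(tr, j) exp_by_trt[[tr]]$expected[j] > 0,
                     slide_meta$treatment, slide_int)
  if (!communities) detected <- rep(FALSE, length(detected))
  below_detection <- slide_meta$sample_id[!mapply(
    function(tr, j) exp_by_trt[[tr]]$expected[j] > 0,
    slide_meta$treatment, slide_int)]
  with_seed(seeds[[4]], {
    slide_comm <- vapply(which(detected), function(i) {
      tr <- slide_meta$treatment[i]; j <- slide_int[i]
      shares <- exp_by_trt[[tr]]$route_shares[, j]
      w <- stats::setNames(numeric(ncol(profiles)), colnames(profiles))
      w[rs[names(shares)]] <- w[rs[names(shares)]] + shares
      simulate_sink(profiles, w, config$seq_depth)
    }, integer(config$n_taxa))
  })
  if (length(dim(slide_comm)) == 2 && ncol(slide_comm) > 0) {
    colnames(slide_comm) <- slide_meta$sample_id[detected]
    rownames(slide_comm) <- rownames(profiles)
  } else {
    slide_comm <- matrix(integer(0), nrow = config$n_taxa,
                         dimnames = list(rownames(profiles), NULL))
  }

  # --- litter communities (succession toward the immigrant pool) -----------
  litter_meta <- meta[!is_slide, ]
  litter_profiles <- lapply(stats::setNames(nm = config$treatments),
                            function(tr) {
    prof <- profiles[, "phyllosphere"]
    out <- matrix(0, nrow = nrow(profiles), ncol = n_int)
    exposed <- route_exposures()[[tr]]
    for (j in seq_len(n_int)) {
      active <- exposed
      if (!config$rain_intervals[j]) active <- setdiff(active, "below")
      I <- if (length(active)) config$immigration_per_route[active, j] else 0
      if (sum(I) > 0) {
        pool <- as.numeric(profiles[, rs[active], drop = FALSE] %*% (I / sum(I)))
        s <- config$succession_mixing[j]
        prof <- (1 - s) * prof + s * pool
      }
      out[, j] <- prof
    }
    out
  })
  if (communities) {
    with_seed(seeds[[5]], {
      litter_comm <- vapply(seq_len(nrow(litter_meta)), function(i) {
        j <- match(litter_meta$day[i], config$collection_days)
        p <- litter_profiles[[litter_meta$treatment[i]]][, j]
        as.integer(stats::rmultinom(1, config$seq_depth, p)[, 1])
      }, integer(config$n_taxa))
    })
    dimnames(litter_comm) <- list(rownames(profiles), litter_meta$sample_id)
  } else {
    litter_comm <- matrix(integer(0), nrow = config$n_taxa,
                          dimnames = list(rownames(profiles), NULL))
  }

  # --- environmental source samples (3 per source per collection) ----------
  src_names <- c("air", "litter", "soil")
  src_grid <- expand.grid(rep = 1:3, source = src_names,
                          day = config$collection_days,
                          stringsAsFactors = FALSE)
  src_grid$sample_id <- sprintf("src_%s_r%d_d%03d", src_grid$source,
                                src_grid$rep, src_grid$day)
  if (communities) {
    with_seed(seeds[[6]], {
      src_comm <- vapply(seq_len(nrow(src_grid)), function(i) {
        as.integer(stats::rmultinom(1, config$seq_depth,
                                    profiles[, src_grid$source[i]])[, 1])
      }, integer(config$n_taxa))
    })
    dimnames(src_comm) <- list(rownames(profiles), src_grid$sample_id)
  } else {
    src_comm <- matrix(integer(0), nrow = config$n_taxa,
                       dimnames = list(rownames(profiles), NULL))
    src_grid <- src_grid[0, ]
  }
  with_seed(seeds[[7]], {
    L <- cumulative_mass_loss(config)
    li <- match(litter_meta$treatment, rownames(L))
    lj <- match(litter_meta$day, config$collection_days)
    loss <- pmin(L[cbind(li, lj)] *
                   lognormal_noise(nrow(litter_meta), config$count_noise_cv),
                 0.95)
  })

  dry0 <- config$wet_initial_g * config$dry_ratio_initial
  dry1 <- dry0 * (1 - loss)
  ratio1 <- 0.85  # litter dries toward senesced ratio in the field
  mass <- data.frame(sample_id = litter_meta$sample_id,
                     block = litter_meta$block,
                     treatment = litter_meta$treatment,
                     day = litter_meta$day,
                     wet_initial_g = config$wet_initial_g,
                     wet_final_g = dry1 / ratio1,
                     dry_ratio_initial = config$dry_ratio_initial,
                     dry_ratio_final = ratio1)

  truth <- list(
    delta = config$death_rate_delta,
    m = 1 - exp(-config$death_rate_delta),
    immigration_per_route = config$immigration_per_route,
    rain_intervals = config$rain_intervals,
    collection_days = config$collection_days,
    mean_open_rate = mean(vapply(seq_len(n_int), function(j)
      treatment_rate(config, "Open", j), numeric(1))),
    resident_abundance = config$resident_abundance,
    source_profiles = profiles,
    succession_mixing = config$succession_mixing,
    mass_loss = cumulative_mass_loss(config),
    seed = seed
  )

  out <- list(metadata = meta,
              cell_counts = cell_counts,
              death_counts = death_counts,
              communities = list(slides = slide_comm,
                                 litter = litter_comm,
                                 sources = src_comm),
              source_labels = stats::setNames(src_grid$source,
                                              src_grid$sample_id),
              mass = mass,
              below_detection = below_detection,
              truth = truth)
  class(out) <- "dispersal_experiment"
  out
}

# Cumulative fractional dry-mass loss per treatment x collection. The route
# boost multiplies the first-interval loss of above/near-exposed treatments.
cumulative_mass_loss <- function(config) {
  trts <- config$treatments
  n_int <- length(config$collection_days)
  L <- matrix(0, nrow = length(trts), ncol = n_int,
              dimnames = list(trts, NULL))
  for (tr in trts) {
    boosted <- length(intersect(c("above", "near"),
                                route_exposures()[[tr]])) > 0
    li <- config$mass_loss_base
    if (boosted) li[1] <- min(li[1] * config$mass_loss_route_boost, 0.95)
    L[tr, ] <- 1 - cumprod(1 - li)
  }
  L
}

#' @export
print.dispersal_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic dispersal experiment: %d samples, %d taxa, %d collections\n",
    nrow(x$metadata), nrow(x$communities$litter),
    length(unique(x$metadata$day))))
  cat(sprintf("  %d slide sample(s) below detection (no immigration)\n",
              length(x$below_detection)))
  invisible(x)
}

#' Write a synthetic experiment to a directory of TSV/JSON files
#'
#' Writes `metadata.tsv`, `cellcounts.tsv`, `death.tsv`, `mass.tsv`,
#' `community_slides.tsv`, `community_litter.tsv`, `community_sources.tsv`,
#' `source_labels.tsv` and `truth.json`. All numeric output is fixed at 10
#' significant digits so re-runs are byte-identical.
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(experiment$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(experiment$cell_counts, file.path(dir, "cellcounts.tsv"))
  write_tsv(experiment$death_counts, file.path(dir, "death.tsv"))
  write_tsv(experiment$mass, file.path(dir, "mass.tsv"))
  write_community_tsv(experiment$communities$slides,
                      file.path(dir, "community_slides.tsv"))
  write_community_tsv(experiment$communities$litter,
                      file.path(dir, "community_litter.tsv"))
  write_community_tsv(experiment$communities$sources,
                      file.path(dir, "community_sources.tsv"))
  write_tsv(data.frame(sample_id = names(experiment$source_labels),
                       source = unname(experiment$source_labels)),
            file.path(dir, "source_labels.tsv"))
  tr <- experiment$truth
  for (f in c("immigration_per_route", "source_profiles", "mass_loss")) {
    tr[[f]] <- mat_to_df(tr[[f]])
  }
  write_json_report(tr, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

# Matrices round-trip through JSON as data frames keyed by row name.
mat_to_df <- function(m) {
  cbind(data.frame(.row = rownames(m) %||% as.character(seq_len(nrow(m)))),
        as.data.frame(m))
}

df_to_mat <- function(df) {
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read back the generating truth written by [write_experiment()]
#'
#' @param path Path to `truth.json`.
#' @return The truth list with matrices restored.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("immigration_per_route", "source_profiles", "mass_loss")) {
    tr[[f]] <- df_to_mat(tr[[f]])
  }
  tr
}
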