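# End-to-end orchestration: simulate -> rates -> community -> sources ->
# functioning, with seeded stages and a machine-readable JSON report.

#' Estimate death, immigration and route rates from trap data
#'
#' Fits the death rate from the death-slide series, converts slide
#' abundances into per-interval immigration rates per treatment and block
#' (consecutive collections of sister slides within a block, day 0 counted
#' as empty), and decomposes each interval into dispersal routes by nested
#' within-block subtraction.
#'
#' @param cell_counts Data frame `sample_id`, `substrate`, `abundance`.
#' @param death_counts Data frame `block`, `day`, `abundance`.
#' @param metadata Data frame with `sample_id`, `block`, `treatment`,
#'   `substrate`, `day`.
#' @param delta Death rate override; default: fitted from `death_counts`.
#' @param alternative Sidedness of the route t-tests.
#' @param bh Apply Benjamini-Hochberg correction across intervals within
#'   each route.
#' @param floor Passed to [fit_death_rate()] for non-positive counts.
#' @return List with `death_fit`, `interval_rates` (block x treatment x
#'   interval data frame), `routes` (per-interval decompositions),
#'   `route_table` (tidy per-route, per-interval summary), `open_mean_rate`
#'   (mean over intervals of the Open-treatment rate), `resident_abundance`
#'   (mean Open litter abundance) and `pct_of_resident`.
#' @export
estimate_rates <- function(cell_counts, death_counts, metadata,
                           delta = NULL,
                           alternative = c("two.sided", "greater", "less"),
                           bh = FALSE, floor = NULL) {
  alternative <- match.arg(alternative)
  need <- c("sample_id", "block", "treatment", "substrate", "day")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  death_fit <- fit_death_rate(death_counts$abundance, death_counts$day,
                              floor = floor)
  delta <- delta %||% death_fit$delta

  df <- merge(metadata, cell_counts[c("sample_id", "abundance")],
              by = "sample_id")
  slides <- df[df$substrate == "slide", ]
  days <- sort(unique(slides$day))
  prev_day <- c(0, days[-length(days)])
  rows <- lapply(seq_along(days), function(j) {
    cur <- slides[slides$day == days[j], ]
    if (j == 1) {
      N1 <- rep(0, nrow(cur))
    } else {
      prev <- slides[slides$day == days[j - 1], ]
      key <- paste(prev$block, prev$treatment)
      N1 <- prev$abundance[match(paste(cur$block, cur$treatment), key)]
    }
    data.frame(block = cur$block, treatment = cur$treatment,
               interval = j, day_start = prev_day[j], day_end = days[j],
               I = invert_interval_immigration(N1, cur$abundance,
                                               days[j] - prev_day[j], delta))
  })
  interval_rates <- do.call(rbind, rows)

  routes <- lapply(seq_along(days), function(j) {
    decompose_routes(interval_rates[interval_rates$interval == j, ],
                     alternative = alternative)
  })
  names(routes) <- paste0("interval", seq_along(days))
  route_table <- do.call(rbind, lapply(seq_along(routes), function(j) {
    cbind(interval = j, as.data.frame(routes[[j]]))
  }))
  rownames(route_table) <- NULL
  if (bh) {
    route_table$p_adj <- stats::ave(route_table$p, route_table$route,
                                    FUN = function(p) stats::p.adjust(p, "BH"))
  }

  open <- interval_rates[interval_rates$treatment == "Open", ]
  open_by_int <- tapply(open$I, open$interval, mean)
  open_mean_rate <- mean(open_by_int)
  litter <- df[df$substrate == "litter" & df$treatment == "Open", ]
  resident <- if (nrow(litter)) mean(litter$abundance) else NA_real_
  list(death_fit = death_fit,
       interval_rates = interval_rates,
       routes = routes,
       route_table = route_table,
       open_mean_rate = open_mean_rate,
       resident_abundance = resident,
       pct_of_resident = if (is.na(resident)) NA_real_ else
         percent_of_resident(open_mean_rate, resident))
}

#' Run the full dispersal-inference pipeline on a synthetic experiment
#'
#' Generates (or accepts) a synthetic experiment, writes its files, then
#' runs every analysis stage: death/immigration/route rates, community
#' statistics on the litter communities of the final collection
#' (rarefaction-averaged Bray-Curtis, PERMANOVA with post-hoc pairs,
#' PERMDISP, NMDS, Shannon ANOVA), source attribution of the Overhead and
#' Open slide communities, and decomposition statistics for the first
#' collection (route contrasts, ANOVA + Tukey letters, Spearman of
#' abundance vs mass loss). All stochastic stages are seeded from the
#' master seed; re-running with the same seed reproduces byte-identical
#' outputs.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory; simulated inputs, `report.json` and
#'   stage outputs are written there.
#' @param seed Master seed (default: the config seed).
#' @param experiment Optional pre-generated [generate_experiment()] bundle.
#' @param depth Rarefaction depth.
#' @param n_resamplings Rarefaction resamplings for the averaged distances.
#' @param n_perm Permutations for PERMANOVA/PERMDISP/Mantel.
#' @param quiet Suppress stage progress messages.
#' @return The run report (list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = experiment_config(), out_dir,
                         seed = config$seed, experiment = NULL,
                         depth = 200, n_resamplings = 25, n_perm = 199,
                         quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) {
    message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)
  }
  warnings_log <- character(0)
  capture <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  seeds <- derive_seeds(seed, 8)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: generating experiment")
  ex <- experiment %||% generate_experiment(config, seed = seeds[[1]])
  write_experiment(ex, out_dir)

  say("rates: death fit, immigration inversion, route decomposition")
  rates <- capture(estimate_rates(ex$cell_counts, ex$death_counts,
                                  ex$metadata))

  say("community: rarefaction, distances, permutation tests")
  final_day <- max(ex$metadata$day)
  lit_meta <- ex$metadata[ex$metadata$substrate == "litter" &
                            ex$metadata$day == final_day, ]
  lit <- ex$communities$litter[, lit_meta$sample_id, drop = FALSE]
  depth_used <- min(depth, min(colSums(lit)))
  D <- rarefied_bray_curtis(lit, depth = depth_used,
                            n_resamplings = n_resamplings,
                            seed = seeds[[2]])
  grp <- lit_meta$treatment
  perm <- permanova(D, grp, n_perm = n_perm, seed = seeds[[3]])
  pw <- pairwise_permanova(D, grp, n_perm = n_perm, seed = seeds[[4]],
                           correction = "BH")
  disp <- permdisp(D, grp, n_perm = n_perm, seed = seeds[[5]])
  ordn <- nmds(D, k = 2, seed = seeds[[6]], n_restarts = 2)
  rar <- capture(rarefy(lit, depth = depth_used, n_resamplings = 10,
                        seed = seeds[[7]]))
  H <- apply(rar$mean, 2, shannon)
  h_anova <- one_way_anova(H, grp)

  say("sources: mixture attribution of Overhead/Open slide communities")
  sl_ids <- colnames(ex$communities$slides)
  sl_meta <- ex$metadata[match(sl_ids, ex$metadata$sample_id), ]
  keep <- sl_meta$treatment %in% c("Overhead", "Open")
  attribution <- if (any(keep)) {
    attribute_samples(ex$communities$slides[, keep, drop = FALSE],
                      ex$communities$sources, ex$source_labels,
                      groups = sl_meta$treatment[keep])
  } else NULL

  say("functioning: mass loss, route contrasts, ANOVA/Tukey, Spearman")
  loss_all <- capture(mass_loss_percent(ex$mass))
  mass <- cbind(ex$mass, loss = loss_all)
  first_day <- min(ex$metadata$day)
  m1 <- mass[mass$day == first_day, ]
  route_loss <- route_mass_loss(m1)
  no_elev <- m1[m1$treatment != "Elevated", ]
  loss_anova <- one_way_anova(no_elev$loss, no_elev$treatment)
  tuk <- tukey_hsd(no_elev$loss, no_elev$treatment)
  lit_ab <- merge(ex$metadata,
                  ex$cell_counts[c("sample_id", "abundance")],
                  by = "sample_id")
  lit_ab <- lit_ab[lit_ab$substrate == "litter" & lit_ab$day == final_day, ]
  final_loss <- mass[mass$day == final_day, ]
  sp <- spearman(lit_ab$abundance[match(final_loss$sample_id,
                                        lit_ab$sample_id)],
                 final_loss$loss, exact = FALSE)
  mean_final_loss <- mean(final_loss$loss[final_loss$treatment != "Elevated"])

  report <- list(
    seed = seed,
    config_digest = config_digest(config),
    n_samples = nrow(ex$metadata),
    warnings = warnings_log,
    death = list(delta = rates$death_fit$delta, m = rates$death_fit$m,
                 ci = rates$death_fit$ci,
                 r_squared = rates$death_fit$r_squared),
    immigration = list(
      open_mean_rate = rates$open_mean_rate,
      pct_of_resident = rates$pct_of_resident,
      routes = rates$route_table),
    community = list(
      depth = depth_used, n_resamplings = n_resamplings, n_perm = n_perm,
      permanova = list(F = perm$F, R2 = perm$R2, p = perm$p),
      pairwise = pw,
      permdisp = list(F = disp$F, p = disp$p,
                      dispersion = as.list(disp$dispersion)),
      nmds_stress = ordn$stress,
      shannon_anova = list(F = h_anova$F, p = h_anova$p,
                           means = as.list(tapply(H, grp, mean)))),
    sources = if (!is.null(attribution)) {
      list(group_means = attribution$group_means)
    },
    functioning = list(
      mean_final_mass_loss = mean_final_loss,
      first_interval_routes = route_loss,
      anova = list(F = loss_anova$F, p = loss_anova$p,
                   r_squared = loss_anova$r_squared),
      tukey_letters = as.list(tuk$letters),
      spearman = list(rho = sp$rho, p = sp$p))
  )
  write_json_report(report, file.path(out_dir, "report.json"))
  say("done: report written")
  invisible(report)
}

# Stable digest of the configuration: serialized at fixed precision and
# hashed with a small FNV-1a, so reports record which config produced them.
config_digest <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 10)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
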