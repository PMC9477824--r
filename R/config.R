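#' Dispersal-route exposure of each trap treatment
#'
#' The four bag treatments expose the trap substrate to strictly nested
#' subsets of the three dispersal routes: Closed admits none, Elevated only
#' deposition from the air column above the vegetation ("above"), Overhead
#' additionally lateral transfer from surrounding vegetation and litter
#' ("near"), and Open additionally upward transfer from the bulk soil and
#' litter layer ("below"). The nesting is what makes per-route rates
#' identifiable by within-block subtraction of adjacent treatments.
#'
#' @return Named list mapping treatment to a character vector of routes.
#' @export
#' @examples
#' route_exposures()$Overhead
route_exposures <- function() {
  list(
    Closed   = character(0),
    Elevated = "above",
    Overhead = c("above", "near"),
    Open     = c("above", "near", "below")
  )
}

# Environmental source community sampled by each route, and the resident
# (phyllosphere) pool seeding the litterbags.
route_sources <- function() {
  c(above = "air", near = "litter", below = "soil")
}

#' Default Dirichlet concentration vectors for the source communities
#'
#' Each source (air, litter, soil, phyllosphere) gets a block of taxa with
#' high concentration plus a small baseline over all taxa, so the sources
#' overlap enough to be realistic but remain identifiable in mixtures.
#'
#' @param n_taxa Total number of taxa in the simulated pool.
#' @return Numeric matrix, sources in rows, taxa in columns, all entries > 0.
#' @export
default_source_concentrations <- function(n_taxa = 120) {
  sources <- c("air", "litter", "soil", "phyllosphere")
  if (n_taxa < 4 * 8) stop("n_taxa too small for four distinct sources")
  conc <- matrix(0.02, nrow = length(sources), ncol = n_taxa,
                 dimnames = list(sources, sprintf("t%03d", seq_len(n_taxa))))
  block <- floor(n_taxa / 5)  # a fifth of the taxa is left as shared tail
  for (i in seq_along(sources)) {
    own <- ((i - 1) * block + 1):(i * block)
    conc[i, own] <- 1
  }
  conc
}

#' Configuration of a synthetic dispersal-trap experiment
#'
#' Assembles and validates all generating parameters of the simulated field
#' experiment: the blocked treatment design, collection schedule, the
#' immigration-with-death dynamics on glass slides, source community
#' profiles, litterbag succession and mass loss. Defaults reproduce the
#' scale of a seven-block Mediterranean grassland deployment sampled five
#' times over six months.
#'
#' @param n_blocks Number of replicate experimental blocks.
#' @param treatments Dispersal-bag treatments (must be a subset of the four
#'   nested treatments, see [route_exposures()]).
#' @param collection_days Strictly increasing day offsets of the collections.
#' @param slide_area Trap slide area in cm^2.
#' @param death_rate_delta Instantaneous cell death rate on slides, per day.
#'   Default corresponds to a daily death fraction of 3.34%.
#' @param immigration_per_route Routes x intervals matrix of immigration
#'   rates (cells/cm^2/day); rows named above/near/below. A single value per
#'   route is recycled across intervals.
#' @param rain_intervals Logical per interval; the below-surface route is
#'   active only in intervals with rainfall.
#' @param n_taxa Number of taxa in the simulated pool.
#' @param source_concentration Dirichlet concentration matrix (sources x
#'   taxa); default built by [default_source_concentrations()].
#' @param count_noise_cv Lognormal coefficient of variation of cell counts.
#' @param seq_depth Multinomial read depth of community profiles.
#' @param succession_mixing Fraction of the litter community replaced by the
#'   immigrant pool per interval, in `[0, 1]`.
#' @param mass_loss_base Fractional dry-mass loss per interval (recycled).
#' @param mass_loss_route_boost Multiplier on first-interval mass loss for
#'   treatments exposed to the above/near routes.
#' @param resident_abundance Baseline resident litter community abundance
#'   (cells/cm^2 equivalent). Treatments exposed to the near-surface route
#'   carry a 10% abundance boost, so the default puts Open litter at about
#'   1.68e6 cells/cm^2 and total Open immigration at about 0.47% of the
#'   resident community per day.
#' @param death_slide_n0 Initial cell load of death-rate slides (cells/cm^2).
#' @param wet_initial_g Initial wet mass of litterbags (g).
#' @param dry_ratio_initial Initial dry:wet mass ratio of litter.
#' @param seed Master RNG seed for the generator.
#' @return Object of class `experiment_config` (a validated list).
#' @export
#' @examples
#' cfg <- experiment_config(n_blocks = 3, n_taxa = 40, seq_depth = 200)
#' cfg$collection_days
experiment_config <- function(n_blocks = 7,
                              treatments = c("Closed", "Elevated",
                                             "Overhead", "Open"),
                              collection_days = c(39, 60, 100, 151, 195),
                              slide_area = 18.75,
                              death_rate_delta = -log(1 - 0.0334),
                              immigration_per_route = c(above = 2750,
                                                        near = 2750,
                                                        below = 4000),
                              rain_intervals = c(TRUE, TRUE, FALSE,
                                                 FALSE, TRUE),
                              n_taxa = 120,
                              source_concentration = NULL,
                              count_noise_cv = 0.2,
                              seq_depth = 1000,
                              succession_mixing = 0.2,
                              mass_loss_base = c(0.04, 0.067, 0.067,
                                                 0.067, 0.067),
                              mass_loss_route_boost = 2.5,
                              resident_abundance = 1.528e6,
                              death_slide_n0 = 1e6,
                              wet_initial_g = 5,
                              dry_ratio_initial = 0.4,
                              seed = 1L) {
  n_int <- length(collection_days)
  if (n_int < 1L) stop_field("collection_days", "needs at least one day")
  if (any(diff(collection_days) <= 0) || any(collection_days <= 0)) {
    stop_field("collection_days", "must be positive and strictly increasing")
  }
  if (!all(treatments %in% names(route_exposures()))) {
    stop_field("treatments", "must be among Closed/Elevated/Overhead/Open")
  }
  assert_scalar_num(n_blocks, "n_blocks", lower = 1)
  assert_scalar_num(slide_area, "slide_area", lower = 0, strict = TRUE)
  assert_scalar_num(death_rate_delta, "death_rate_delta", lower = 0)
  assert_scalar_num(count_noise_cv, "count_noise_cv", lower = 0)
  assert_scalar_num(seq_depth, "seq_depth", lower = 1)
  assert_scalar_num(resident_abundance, "resident_abundance",
                    lower = 0, strict = TRUE)
  assert_scalar_num(death_slide_n0, "death_slide_n0", lower = 0, strict = TRUE)
  assert_scalar_num(wet_initial_g, "wet_initial_g", lower = 0, strict = TRUE)
  assert_scalar_num(mass_loss_route_boost, "mass_loss_route_boost", lower = 0)
  if (dry_ratio_initial <= 0 || dry_ratio_initial > 1) {
    stop_field("dry_ratio_initial", "must be in (0, 1]")
  }

  imm <- immigration_per_route
  if (is.null(dim(imm))) {
    if (is.null(names(imm)) || !setequal(names(imm), c("above", "near", "below"))) {
      stop_field("immigration_per_route",
                 "must be named above/near/below")
    }
    imm <- matrix(rep(imm[c("above", "near", "below")], n_int),
                  nrow = 3, dimnames = list(c("above", "near", "below"), NULL))
  }
  if (nrow(imm) != 3 || ncol(imm) != n_int) {
    stop_field("immigration_per_route",
               "must be 3 routes x n_intervals")
  }
  if (any(imm < 0)) stop_field("immigration_per_route", "rates must be >= 0")
  colnames(imm) <- paste0("interval", seq_len(n_int))

  if (length(rain_intervals) != n_int || !is.logical(rain_intervals)) {
    stop_field("rain_intervals", "must be logical, one per interval")
  }
  succ <- rep_len(succession_mixing, n_int)
  if (any(succ < 0) || any(succ > 1)) {
    stop_field("succession_mixing", "must lie in [0, 1]")
  }
  mloss <- rep_len(mass_loss_base, n_int)
  if (any(mloss < 0) || any(mloss >= 1)) {
    stop_field("mass_loss_base", "per-interval losses must lie in [0, 1)")
  }
  if (is.null(source_concentration)) {
    source_concentration <- default_source_concentrations(n_taxa)
  }
  if (ncol(source_concentration) != n_taxa) {
    stop_field("source_concentration", "needs one column per taxon")
  }
  if (any(source_concentration <= 0)) {
    stop_field("source_concentration", "Dirichlet concentrations must be > 0")
  }

  cfg <- list(
    n_blocks = as.integer(n_blocks),
    treatments = treatments,
    collection_days = as.numeric(collection_days),
    slide_area = slide_area,
    death_rate_delta = death_rate_delta,
    immigration_per_route = imm,
    rain_intervals = rain_intervals,
    n_taxa = as.integer(n_taxa),
    source_concentration = source_concentration,
    count_noise_cv = count_noise_cv,
    seq_depth = as.integer(seq_depth),
    succession_mixing = succ,
    mass_loss_base = mloss,
    mass_loss_route_boost = mass_loss_route_boost,
    resident_abundance = resident_abundance,
    death_slide_n0 = death_slide_n0,
    wet_initial_g = wet_initial_g,
    dry_ratio_initial = dry_ratio_initial,
    seed = as.integer(seed)
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Synthetic dispersal experiment configuration\n")
  cat(sprintf("  %d blocks x %d treatments x %d collections (days %s)\n",
              x$n_blocks, length(x$treatments), length(x$collection_days),
              paste(x$collection_days, collapse = ", ")))
  cat(sprintf("  death rate delta = %.4f /day (daily fraction %.2f%%)\n",
              x$death_rate_delta, 100 * (1 - exp(-x$death_rate_delta))))
  cat(sprintf("  mean immigration (above/near/below): %s cells/cm2/day\n",
              paste(signif(rowMeans(x$immigration_per_route), 4),
                    collapse = "/")))
  invisible(x)
}

# Effective total immigration rate of a treatment in one interval: the sum
# of its exposed routes, with the below route silenced in rain-free
# intervals.
treatment_rate <- function(config, treatment, interval) {
  routes <- route_exposures()[[treatment]]
  if (!length(routes)) return(0)
  active <- routes
  if (!config$rain_intervals[interval]) active <- setdiff(active, "below")
  if (!length(active)) return(0)
  sum(config$immigration_per_route[active, interval])
}
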