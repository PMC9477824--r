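#' Fit the cell death rate from death-slide decay
#'
#' Slides loaded with a known number of cells and closed to dispersal lose
#' cells over time. Assuming first-order (exponential) loss, the
#' instantaneous death rate delta is minus the slope of an ordinary
#' least-squares fit of log abundance against time; the daily death
#' fraction is `m = 1 - exp(-delta)`.
#'
#' @param counts Positive cell counts (cells/cm^2), one per slide.
#' @param days Days since deployment, same length; must include day 0 data.
#' @param floor Optional positive replacement for zero counts. With the
#'   default `NULL`, any non-positive count is an error; the message points
#'   to this argument. A common choice is half the minimum positive count.
#' @return Object of class `death_rate_fit` with fields `delta`,
#'   `m` (daily death fraction), `ci` (95% t-interval on delta), `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
#' @examples
#' fit_death_rate(c(1000, 500, 250), c(0, 1, 2))$m  # exact halving: 0.5
fit_death_rate <- function(counts, days, floor = NULL) {
  if (length(counts) != length(days)) stop("counts and days differ in length")
  keep <- is.finite(counts) & is.finite(days)
  counts <- counts[keep]; days <- days[keep]
  if (any(counts <= 0)) {
    if (is.null(floor)) {
      stop("non-positive counts cannot enter the log-linear fit; ",
           "supply `floor` (e.g. half the minimum positive count) ",
           "to replace them", call. = FALSE)
    }
    if (floor <= 0) stop("`floor` must be positive")
    warning(sprintf("%d non-positive count(s) floored at %g",
                    sum(counts <= 0), floor))
    counts[counts <= 0] <- floor
  }
  if (length(counts) < 3) stop("death-rate fit needs at least 3 points")
  fit <- stats::lm(log(counts) ~ days)
  delta <- -unname(stats::coef(fit)["days"])
  ci <- quiet_perfect_fit(
    sort(-unname(stats::confint(fit, "days", level = 0.95))))
  out <- list(
    delta = delta,
    m = 1 - exp(-delta),
    ci = ci,
    ci_m = sort(1 - exp(-ci)),
    r_squared = quiet_perfect_fit(summary(fit)$r.squared),
    n = length(counts),
    fit = fit
  )
  class(out) <- "death_rate_fit"
  out
}

#' @export
print.death_rate_fit <- function(x, ...) {
  cat(sprintf(
    "Death rate: delta = %.5f /day (daily fraction %.2f%%)\n",
    x$delta, 100 * x$m))
  cat(sprintf("  95%% CI on delta: [%.5f, %.5f]; R2 = %.3f; n = %d\n",
              x$ci[1], x$ci[2], x$r_squared, x$n))
  invisible(x)
}

# 1 - exp(-delta * t) computed stably near delta = 0.
one_minus_exp <- function(delta, t) -expm1(-delta * t)

#' Expected trap abundance under constant immigration and death
#'
#' Solution of `dN/dt = I - delta * N` from `N(0) = N0`:
#' `N(t) = N0 * exp(-delta t) + (I/delta) * (1 - exp(-delta t))`,
#' continuous at `delta = 0` where it reduces to `N0 + I * t`.
#'
#' @param I Immigration rate, cells/cm^2/day.
#' @param delta Death rate, per day.
#' @param t Elapsed days.
#' @param N0 Initial abundance.
#' @return Expected abundance, cells/cm^2. Vectorised over all arguments.
#' @export
accumulate_immigration <- function(I, delta, t, N0 = 0) {
  n <- max(length(I), length(delta), length(t), length(N0))
  I <- rep_len(I, n); delta <- rep_len(delta, n)
  t <- rep_len(t, n); N0 <- rep_len(N0, n)
  out <- N0 + I * t
  d <- delta > 0
  out[d] <- N0[d] * exp(-delta[d] * t[d]) +
    I[d] * one_minus_exp(delta[d], t[d]) / delta[d]
  out
}

#' Invert cumulative trap abundance into an immigration rate
#'
#' Solves the immigration-death balance `N(t) = (I/delta)(1 - exp(-delta t))`
#' for the constant immigration rate `I` given the abundance a trap
#' accumulated since deployment: `I = delta * N / (1 - exp(-delta t))`,
#' with the continuous `delta -> 0` limit `I = N/t`.
#'
#' @param N Accumulated abundance, cells/cm^2 (>= 0).
#' @param t Days since deployment (> 0).
#' @param delta Death rate, per day (>= 0).
#' @return Immigration rate, cells/cm^2/day. Vectorised.
#' @export
#' @examples
#' invert_cumulative_immigration(100, 10, 0)  # 10 cells/cm2/day
invert_cumulative_immigration <- function(N, t, delta) {
  if (any(t <= 0)) stop("t must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  if (any(N < 0)) stop("N must be >= 0")
  n <- max(length(N), length(t), length(delta))
  N <- rep_len(N, n); t <- rep_len(t, n); delta <- rep_len(delta, n)
  out <- N / t
  d <- delta > 0
  out[d] <- delta[d] * N[d] / one_minus_exp(delta[d], t[d])
  out
}

#' Invert an abundance change over one interval into an immigration rate
#'
#' Given trap abundances at the start and end of an interval (from
#' destructively sampled sister slides of the same block), the
#' constant-rate update `N2 = N1 exp(-delta dt) + (I/delta)(1 - exp(-delta
#' dt))` yields `I = delta (N2 - N1 exp(-delta dt)) / (1 - exp(-delta dt))`.
#' Sampling noise can make the estimate negative; it is returned signed.
#'
#' @param N1,N2 Abundances at interval start and end, cells/cm^2.
#' @param dt Interval length in days (> 0).
#' @param delta Death rate, per day (>= 0).
#' @return Signed immigration rate, cells/cm^2/day. Vectorised.
#' @export
invert_interval_immigration <- function(N1, N2, dt, delta) {
  if (any(dt <= 0)) stop("dt must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  n <- max(length(N1), length(N2), length(dt), length(delta))
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  dt <- rep_len(dt, n); delta <- rep_len(delta, n)
  out <- (N2 - N1) / dt
  d <- delta > 0
  out[d] <- delta[d] * (N2[d] - N1[d] * exp(-delta[d] * dt[d])) /
    one_minus_exp(delta[d], dt[d])
  out
}

#' One-sample t-test with explicit degenerate handling
#'
#' Standard one-sample t-test of `mean(values) == mu0`. Zero-variance input
#' is flagged degenerate: p = 1 when the common value equals `mu0`, p = 0
#' otherwise (the data are then perfectly (in)consistent with `mu0`).
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null mean.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return List with `t`, `df`, `p`, `mean`, `ci` (95%), `degenerate`.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3))$t  # 3.4641
one_sample_t <- function(values, mu0 = 0,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("one-sample t-test needs n >= 2")
  if (stats::sd(values) == 0) {
    same <- isTRUE(all.equal(mean(values), mu0))
    return(list(t = if (same) 0 else Inf * sign(mean(values) - mu0),
                df = n - 1, p = if (same) 1 else 0,
                mean = mean(values), ci = rep(mean(values), 2),
                degenerate = TRUE))
  }
  ht <- stats::t.test(values, mu = mu0, alternative = alternative,
                      conf.level = 0.95)
  ci <- stats::t.test(values, mu = mu0, conf.level = 0.95)$conf.int
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values),
       ci = as.numeric(ci), degenerate = FALSE)
}

#' Decompose treatment immigration rates into dispersal routes
#'
#' The nested design isolates each route as the within-block difference of
#' two adjacent treatments: above = Elevated - Closed, near = Overhead -
#' Elevated, below = Open - Overhead. Per route the block-level differences
#' give a mean, a 95% t-interval, and a one-sample t-test against zero.
#' Blocks missing any of the four treatments are dropped. The three route
#' estimates telescope exactly to Open - Closed within each block.
#'
#' @param rates Data frame with columns `block`, `treatment`, `I`
#'   (cells/cm^2/day), one row per block x treatment for one interval.
#' @param alternative Sidedness of the t-tests (default two-sided).
#' @return Object of class `route_decomposition`: a data frame with one row
#'   per route (`mean`, `ci_lo`, `ci_hi`, `t`, `df`, `p`, `n_blocks`) and the
#'   per-block differences as attribute `"blocks"`.
#' @export
decompose_routes <- function(rates,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  need <- c("block", "treatment", "I")
  if (!all(need %in% names(rates))) {
    stop("`rates` needs columns block, treatment, I")
  }
  wide <- stats::reshape(rates[need], idvar = "block",
                         timevar = "treatment", direction = "wide")
  names(wide) <- sub("^I\\.", "", names(wide))
  trts <- c("Closed", "Elevated", "Overhead", "Open")
  missing_trt <- setdiff(trts, names(wide))
  if (length(missing_trt)) {
    stop("route decomposition needs all four treatments; missing: ",
         paste(missing_trt, collapse = ", "))
  }
  complete <- stats::complete.cases(wide[trts])
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2) {
    stop("fewer than 2 complete blocks; no confidence interval possible")
  }
  diffs <- cbind(above = wide$Elevated - wide$Closed,
                 near  = wide$Overhead - wide$Elevated,
                 below = wide$Open - wide$Overhead)
  rownames(diffs) <- wide$block
  rows <- lapply(colnames(diffs), function(r) {
    tt <- one_sample_t(diffs[, r], mu0 = 0, alternative = alternative)
    data.frame(route = r, mean = tt$mean, ci_lo = tt$ci[1], ci_hi = tt$ci[2],
               t = tt$t, df = tt$df, p = tt$p, n_blocks = nrow(diffs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$route
  attr(out, "blocks") <- diffs
  class(out) <- c("route_decomposition", "data.frame")
  out
}

#' @export
print.route_decomposition <- function(x, ...) {
  cat("Dispersal-route immigration estimates (within-block subtraction)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Immigration rate as a percentage of the resident community
#'
#' @param I Immigration rate, cells/cm^2/day.
#' @param resident_areal Resident community abundance, cells/cm^2 (> 0).
#' @return Percent of the resident community arriving per day.
#' @export
percent_of_resident <- function(I, resident_areal) {
  if (any(resident_areal <= 0)) stop("resident abundance must be > 0")
  100 * I / resident_areal
}
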