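test_that("death-rate fit recovers exact exponential decay", {
  # constant counts: no death
  f0 <- fit_death_rate(c(1000, 1000, 1000), c(0, 7, 14))
  expect_equal(f0$delta, 0)
  expect_equal(f0$m, 0)

  # exact halving per day
  fh <- fit_death_rate(c(1000, 500, 250), c(0, 1, 2))
  expect_equal(fh$delta, log(2), tolerance = 1e-12)
  expect_equal(fh$m, 0.5, tolerance = 1e-12)

  # noiseless exponential at arbitrary delta: machine-precision recovery
  delta <- 0.0337
  t <- c(0, 39, 60, 100, 151, 195)
  f <- fit_death_rate(1e6 * exp(-delta * t), t)
  expect_equal(f$delta, delta, tolerance = 1e-10)
  expect_true(f$ci[1] <= f$delta && f$delta <= f$ci[2])
})

test_that("death-rate fit rejects bad input and floors zeros on request", {
  expect_error(fit_death_rate(c(10, 0, 5), c(0, 1, 2)), "floor")
  expect_error(fit_death_rate(c(10, 5), c(0, 1)), "at least 3")
  expect_warning(f <- fit_death_rate(c(100, 10, 0, 1), 0:3, floor = 0.5),
                 "floored")
  expect_true(f$delta > 0)
})

test_that("delta and daily fraction convert as a bijection on [0, 1)", {
  deltas <- c(0, 1e-6, 0.034, 0.2, 2)
  m <- 1 - exp(-deltas)
  expect_true(all(m >= 0 & m < 1))
  expect_true(all(diff(m) > 0))
  expect_equal(-log(1 - m), deltas, tolerance = 1e-12)
})

test_that("cumulative inversion has the right limits", {
  expect_equal(invert_cumulative_immigration(100, 10, 0), 10)
  expect_equal(invert_cumulative_immigration(0, 5, 0.1), 0)
  # continuity at delta -> 0
  expect_equal(invert_cumulative_immigration(100, 10, 1e-12), 10,
               tolerance = 1e-6)
  expect_error(invert_cumulative_immigration(10, 0, 0.1), "t must be")
})

test_that("interval inversion matches pure decay and equilibrium", {
  delta <- 0.05; N1 <- 2000; dt <- 21
  expect_equal(invert_interval_immigration(N1, N1 * exp(-delta * dt),
                                           dt, delta), 0, tolerance = 1e-9)
  expect_equal(invert_interval_immigration(N1, N1, dt, delta),
               delta * N1, tolerance = 1e-9)
  expect_equal(invert_interval_immigration(100, 150, 5, 0), 10)
  expect_error(invert_interval_immigration(1, 1, -1, 0.1), "dt must be")
})

test_that("closed-form inversion round-trips an RK4 forward simulation", {
  skip_if_not_installed("deSolve")
  for (delta in c(0, 1e-6, 0.01, 0.034, 0.2)) {
    for (tf in c(1, 30, 180)) {
      I <- 7900
      sol <- deSolve::ode(c(N = 0), times = c(0, tf),
                          function(t, y, p) list(I - delta * y[1]),
                          parms = NULL, method = "rk4",
                          hini = min(tf / 2000, 0.05))
      N <- sol[nrow(sol), "N"]
      expect_equal(invert_cumulative_immigration(N, tf, delta), I,
                   tolerance = 1e-6)
      expect_equal(invert_interval_immigration(0, N, tf, delta), I,
                   tolerance = 1e-6)
    }
  }
})

test_that("cumulative and interval inversions agree from an empty trap", {
  set.seed(7)
  for (i in 1:20) {
    N <- runif(1, 0, 1e5); t <- runif(1, 1, 200); d <- runif(1, 0, 0.3)
    expect_equal(invert_cumulative_immigration(N, t, d),
                 invert_interval_immigration(0, N, t, d), tolerance = 1e-10)
  }
})

test_that("one-sample t matches the hand-computed statistic", {
  tt <- one_sample_t(c(1, 2, 3))
  expect_equal(tt$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(tt$p, 0.0742, tolerance = 1e-3)
  # degenerate cases
  expect_equal(one_sample_t(c(2, 2, 2), mu0 = 2)$p, 1)
  expect_equal(one_sample_t(c(2, 2, 2), mu0 = 0)$p, 0)
  expect_true(one_sample_t(c(2, 2, 2), mu0 = 0)$degenerate)
  expect_error(one_sample_t(5), "n >= 2")
})

test_that("route decomposition subtracts nested treatments within block", {
  blocks <- 1:5
  df <- expand.grid(block = blocks,
                    treatment = c("Closed", "Elevated", "Overhead", "Open"),
                    stringsAsFactors = FALSE)
  # all treatments equal: every route zero
  df$I <- 7
  dec <- decompose_routes(df)
  expect_equal(dec$mean, c(0, 0, 0))

  # noiseless nested values: above 10, near 0, below 15 with zero-width CI
  vals <- c(Closed = 0, Elevated = 10, Overhead = 10, Open = 25)
  df$I <- vals[df$treatment]
  dec <- decompose_routes(df)
  expect_equal(dec["above", "mean"], 10)
  expect_equal(dec["near", "mean"], 0)
  expect_equal(dec["below", "mean"], 15)
  expect_equal(dec$ci_hi - dec$ci_lo, c(0, 0, 0))
})

test_that("route estimates telescope exactly to Open minus Closed", {
  set.seed(11)
  df <- expand.grid(block = 1:7,
                    treatment = c("Closed", "Elevated", "Overhead", "Open"),
                    stringsAsFactors = FALSE)
  df$I <- rnorm(nrow(df), 100, 30)
  dec <- decompose_routes(df)
  blocks <- attr(dec, "blocks")
  wide <- reshape(df, idvar = "block", timevar = "treatment",
                  direction = "wide")
  expect_equal(unname(rowSums(blocks)),
               wide$I.Open - wide$I.Closed, tolerance = 1e-12)
})

test_that("route decomposition requires complete treatments and >= 2 blocks", {
  df <- expand.grid(block = 1:3,
                    treatment = c("Closed", "Elevated", "Overhead"),
                    stringsAsFactors = FALSE)
  df$I <- 1
  expect_error(decompose_routes(df), "Open")
  df2 <- expand.grid(block = 1,
                     treatment = c("Closed", "Elevated", "Overhead", "Open"),
                     stringsAsFactors = FALSE)
  df2$I <- 1
  expect_error(decompose_routes(df2), "blocks")
})

test_that("percent of resident community computes and validates", {
  expect_equal(percent_of_resident(5, 1000), 0.5)
  expect_equal(percent_of_resident(0, 1000), 0)
  expect_error(percent_of_resident(5, 0), "must be > 0")
})

test_that("one-sample t-test holds its nominal type-I error", {
  set.seed(101)
  reps <- 4000
  x <- matrix(rnorm(7 * reps), nrow = 7)
  p <- apply(x, 2, function(v) one_sample_t(v)$p)
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})
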