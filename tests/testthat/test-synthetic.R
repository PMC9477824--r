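test_that("config validation names the offending field", {
  expect_error(experiment_config(collection_days = c(10, 5)),
               "collection_days")
  expect_error(experiment_config(immigration_per_route =
                                   c(above = -1, near = 0, below = 0)),
               "immigration_per_route")
  expect_error(experiment_config(succession_mixing = 1.2),
               "succession_mixing")
  expect_error(experiment_config(treatments = c("Closed", "Sideways")),
               "treatments")
  expect_error(experiment_config(rain_intervals = c(TRUE, FALSE)),
               "rain_intervals")
})

test_that("route exposures are strictly nested", {
  ex <- route_exposures()
  expect_identical(ex$Closed, character(0))
  expect_identical(ex$Elevated, "above")
  expect_true(all(ex$Elevated %in% ex$Overhead))
  expect_true(all(ex$Overhead %in% ex$Open))
  expect_setequal(ex$Open, c("above", "near", "below"))
})

test_that("expected slide abundance is monotone across nested treatments", {
  cfg <- experiment_config()
  exps <- sapply(c("Closed", "Elevated", "Overhead", "Open"), function(tr) {
    soildispersal:::slide_expectation(cfg, tr)$expected
  })
  for (j in seq_len(nrow(exps))) {
    expect_true(all(diff(exps[j, ]) >= 0))
  }
})

test_that("no immigration means no slide accumulation", {
  cfg <- experiment_config(immigration_per_route =
                             c(above = 0, near = 0, below = 0))
  ex <- generate_experiment(cfg, seed = 3)
  slide <- ex$cell_counts[ex$cell_counts$substrate == "slide", ]
  expect_true(all(slide$abundance == 0))
  litter <- ex$cell_counts[ex$cell_counts$substrate == "litter", ]
  expect_true(all(litter$abundance > 0))
  expect_setequal(ex$below_detection, slide$sample_id)
})

test_that("Closed slides carry no community and are flagged below detection", {
  ex <- generate_experiment(small_config(), seed = 2)
  closed_ids <- ex$metadata$sample_id[ex$metadata$treatment == "Closed" &
                                        ex$metadata$substrate == "slide"]
  expect_setequal(ex$below_detection, closed_ids)
  expect_false(any(closed_ids %in% colnames(ex$communities$slides)))
})

test_that("death slides decay exponentially with the configured rate", {
  # delta = 0: constant expectation
  cfg0 <- experiment_config(death_rate_delta = 0, count_noise_cv = 0)
  d0 <- generate_death_slides(cfg0, seed = 1)
  expect_true(all(d0$abundance == cfg0$death_slide_n0))

  # halving per day: m = 0.5
  cfg_half <- experiment_config(death_rate_delta = log(2),
                                count_noise_cv = 0,
                                collection_days = c(1, 2, 3),
                                rain_intervals = rep(TRUE, 3),
                                mass_loss_base = 0.05,
                                death_slide_n0 = 1000)
  dh <- generate_death_slides(cfg_half, seed = 1)
  expect_equal(dh$abundance[dh$day == 1], rep(500, cfg_half$n_blocks))

  # Monte-Carlo mean vs closed form N0 * exp(-1.02) at t = 30
  cfg <- experiment_config(death_rate_delta = 0.034, death_slide_n0 = 1e6,
                           collection_days = 30, rain_intervals = TRUE,
                           mass_loss_base = 0.1, succession_mixing = 0.2,
                           n_blocks = 10000, count_noise_cv = 0.2)
  dm <- generate_death_slides(cfg, seed = 42)
  mc <- mean(dm$abundance[dm$day == 30])
  expect_equal(mc, 1e6 * exp(-1.02), tolerance = 0.01)
})

test_that("community draws conserve depth and mixture weights sum to one", {
  cfg <- small_config()
  ex <- generate_experiment(cfg, seed = 4)
  expect_true(all(colSums(ex$communities$slides) == cfg$seq_depth))
  expect_true(all(colSums(ex$communities$litter) == cfg$seq_depth))
  shares <- soildispersal:::slide_expectation(cfg, "Open")$route_shares
  expect_equal(colSums(shares), rep(1, ncol(shares)))
})

test_that("same seed and config reproduce identical experiments and files", {
  cfg <- small_config()
  e1 <- generate_experiment(cfg, seed = 42)
  e2 <- generate_experiment(cfg, seed = 42)
  expect_identical(e1, e2)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_experiment(e1, d1); write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generating truth round-trips through its JSON serialization", {
  cfg <- small_config()
  ex <- generate_experiment(cfg, seed = 9)
  dir <- file.path(tempdir(), "truth_rt")
  write_experiment(ex, dir)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$delta, ex$truth$delta)
  expect_equal(tr$m, ex$truth$m)
  expect_equal(tr$mean_open_rate, ex$truth$mean_open_rate)
  expect_equal(unname(tr$immigration_per_route),
               unname(ex$truth$immigration_per_route))
  expect_equal(rownames(tr$source_profiles),
               rownames(ex$truth$source_profiles))
  expect_equal(unname(tr$source_profiles), unname(ex$truth$source_profiles),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("simulate_sink validates weights and hits the requested depth", {
  prof <- generate_source_profiles(small_config(), seed = 1)
  s <- simulate_sink(prof, c(1, 1, 0, 0), depth = 500, seed = 1)
  expect_equal(sum(s), 500)
  expect_error(simulate_sink(prof, c(-1, 1, 0, 0), 100), "non-negative")
})
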