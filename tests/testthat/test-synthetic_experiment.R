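test_that("plates are reproducible under a fixed seed", {
  cfg <- experiment_config(days = 3, conditions = c(1, 8), f0 = c(1, 10),
                           seed = 42)
  p1 <- simulate_plate(cfg, cf_params())
  p2 <- simulate_plate(cfg, cf_params())
  expect_identical(p1, p2)
  p3 <- simulate_plate(experiment_config(days = 3, conditions = c(1, 8),
                                         f0 = c(1, 10), seed = 43),
                       cf_params())
  expect_false(identical(p1$od, p3$od))
})

test_that("unsupplemented monocultures decay tenfold per day to the floor", {
  cfg <- experiment_config(days = 8, conditions = 0, f0 = 1,
                           od_noise_sd = 0, seed = 1)
  plate <- simulate_plate(cfg, cf_params())
  mx <- plate[plate$culture_type == "mono_x", ]
  live <- mx$od > 2 * cfg$od_floor
  if (sum(live) >= 2) {
    ratios <- mx$od[live][-1] / mx$od[live][-sum(live)]
    expect_equal(ratios, rep(0.1, length(ratios)), tolerance = 1e-6)
  }
  expect_equal(mx$od[nrow(mx)], cfg$od_floor)  # eventually at the floor
  expect_true(all(is.na(mx$fraction_y)))
})

test_that("the noise-free infinite-sample limit equals the deterministic map", {
  cfg <- experiment_config(days = 4, conditions = 2, f0 = 3,
                           od_noise_sd = 0, cytometer_sample = Inf,
                           monocultures = FALSE, seed = 9)
  plate <- simulate_plate(cfg, cf_params())
  p <- cf_params(a = conc_to_a(2, cfg$conc_scale))
  track <- iterate_dilution(p, c(cfg$n0 * 0.75, cfg$n0 * 0.25),
                            days = 4, t_day = cfg$t_day)
  track <- track[track$day >= 1, ]
  expect_equal(plate$od, track$n, tolerance = 1e-12)
  expect_equal(plate$fraction_y, track$Y / track$n, tolerance = 1e-12)
})

test_that("cytometer draws are binomially consistent with the true fraction", {
  cfg <- experiment_config(days = 1, conditions = 2, f0 = 1,
                           od_noise_sd = 0, cytometer_sample = 10000,
                           monocultures = FALSE, seed = 2)
  draws <- vapply(1:200, function(i) {
    cfg$seed <- i
    simulate_plate(cfg, cf_params())$fraction_y[1]
  }, 0)
  truth <- attr(simulate_plate(cfg, cf_params()), "truth")
  p_y <- truth$Y[1] / (truth$X[1] + truth$Y[1])
  expect_equal(mean(draws), p_y, tolerance = 4 * sqrt(p_y / 4e4 / 200) / p_y)
  expect_equal(sd(draws), sqrt(p_y * (1 - p_y) / 10000), tolerance = 0.25)
})

test_that("noise-free monoculture fate switches at the mapped closed-form threshold", {
  a_x <- monoculture_viability_threshold(cf_params(), "X")   # 0.12
  trp_crit <- a_x / 0.1                                      # 1.2 uM
  cfg <- experiment_config(days = 10, f0 = 1, od_noise_sd = 0,
                           conditions = trp_crit * c(0.9, 1.1), seed = 3)
  plate <- simulate_plate(cfg, cf_params())
  mx <- plate[plate$culture_type == "mono_x", ]
  below <- mx$od[mx$trp_uM < trp_crit]
  above <- mx$od[mx$trp_uM > trp_crit]
  # below threshold growth cannot balance dilution: OD decays geometrically,
  # the day-over-day ratio staying bounded away from 1
  expect_true(all(diff(below) < 0))
  expect_lt(below[length(below)] / below[length(below) - 1], 0.9)
  # above threshold the monoculture approaches a positive fixed point:
  # the day-over-day ratio tends to 1 and OD stays high
  expect_gt(above[length(above)], 0.1)
  expect_gt(above[length(above)] / above[length(above) - 1], 0.95)
})

test_that("the full-factorial default design yields 16 x 6 x 7 co-culture records", {
  cfg <- experiment_config(monocultures = FALSE, cytometer_sample = 1000,
                           seed = 4)
  plate <- simulate_plate(cfg, cf_params())
  expect_equal(nrow(plate), 16L * 6L * 7L)
})

test_that("plate CSVs round-trip bit-exactly and reject corrupt input", {
  cfg <- experiment_config(days = 3, conditions = c(0, 1, 32), f0 = c(1, 10),
                           seed = 11)
  plate <- simulate_plate(cfg, cf_params())
  f <- file.path(tempdir(), "plate.csv")
  write_plate(plate, f)
  back <- read_plate(f)
  for (col in names(back))
    expect_identical(back[[col]], plate[[col]], label = col)
  # empty table round-trips as header-only
  write_plate(plate[0, ], f)
  expect_equal(nrow(read_plate(f)), 0L)
  # invariant enforcement on read
  txt <- readLines(f)
  writeLines(c(txt[1:2], "w001,1,0,co,0.5,100,900,1.5"), f)
  expect_error(read_plate(f), "fraction_y")
  writeLines(c(txt[1:2], "w001,1,0,co,0.5,100,900,0.5"), f)
  expect_error(read_plate(f), "cells_y")
})
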