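test_that("relative fitness behaves as an odds ratio", {
  expect_equal(relative_fitness(0.3, 0.3), 1)
  # Leu- grows 8-fold while Trp- grows 10-fold from a 1:1 start
  expect_equal(relative_fitness(0.5, 8 / 18), 0.8)
  # strain relabeling symmetry: W -> 1/W
  set.seed(8)
  f0 <- runif(10, 0.05, 0.95); f1 <- runif(10, 0.05, 0.95)
  expect_equal(relative_fitness(1 - f0, 1 - f1),
               1 / relative_fitness(f0, f1))
  # scale-free in counts: fractions from k-scaled counts are unchanged
  cx <- c(400, 300); cy <- c(600, 700)
  f <- cy / (cx + cy); fk <- (7 * cy) / (7 * cx + 7 * cy)
  expect_identical(relative_fitness(f[1], f[2]),
                   relative_fitness(fk[1], fk[2]))
  expect_error(relative_fitness(0, 0.5), "strictly in")
  expect_error(relative_fitness(0.5, 1), "strictly in")
})

test_that("fitness records pair consecutive days after burn-in", {
  plate <- data.frame(
    well = "w1", day = 1:5, trp_uM = 1, culture_type = "co",
    od = 0.3, cells_x = NA, cells_y = NA,
    fraction_y = c(0.40, 0.45, 0.50, 0.52, 0.53))
  rec <- day_fitness_records(plate, burn_in = 2)
  expect_equal(rec$day, 3:5)
  expect_equal(rec$f_start, c(0.45, 0.50, 0.52))
  expect_equal(rec$logW[1], log(relative_fitness(0.45, 0.50)))
})

test_that("bootstrap crossing recovers an exact linear relation", {
  # noise-free linear records: crossing at f = 0.6 exactly
  rec <- data.frame(f_start = seq(0.2, 0.9, by = 0.1))
  rec$logW <- -0.8 * (rec$f_start - 0.6)
  b <- equilibrium_fraction_bootstrap(rec, n_boot = 200, seed = 1)
  expect_equal(b$estimate, 0.6, tolerance = 1e-10)
  expect_lt(diff(b$ci), 1e-8)  # degenerate bootstrap: zero-width interval
  # one-sided records: no crossing, explicit error
  rec$logW <- abs(rec$logW) + 0.1
  expect_error(equilibrium_fraction_bootstrap(rec, n_boot = 50),
               class = "cf_no_equilibrium")
  expect_error(equilibrium_fraction_bootstrap(rec[1:3, ]), "at least 4")
})

test_that("equilibrium detection separates converged, drifting and dying tracks", {
  const <- data.frame(day = 1:7, od = rep(0.42, 7),
                      fraction_y = rep(0.55, 7))
  d <- detect_equilibrium(const)
  expect_true(d$converged)
  expect_equal(d$od, 0.42)
  expect_equal(d$fraction_y, 0.55)
  dying <- data.frame(day = 1:7, od = 0.4 * 0.1^(0:6))
  d <- detect_equilibrium(dying)
  expect_true(d$extinct || !d$converged)
  drifting <- data.frame(day = 1:7, od = seq(0.1, 0.7, length.out = 7),
                         fraction_y = rep(0.5, 7))
  expect_false(detect_equilibrium(drifting)$converged)
  expect_error(detect_equilibrium(const[1:3, ]), "insufficient data")
})

test_that("the bootstrap crossing matches the generator's interior equilibrium", {
  p <- cf_params()
  trp <- 1.6  # a = 0.16: facultative window with a stable interior point
  cfg <- experiment_config(days = 7, conditions = trp, f0 = c(1 / 3, 1, 3),
                           monocultures = FALSE, od_noise_sd = 0.02,
                           cytometer_sample = 10000, seed = 21)
  plate <- simulate_plate(cfg, p)
  rec <- day_fitness_records(plate)
  b <- equilibrium_fraction_bootstrap(rec, n_boot = 500, seed = 2)
  pb <- p; pb$a <- conc_to_a(trp, cfg$conc_scale)
  eqb <- batch_equilibrium(pb, c(cfg$n0 / 2, cfg$n0 / 2))
  truth <- eqb$state[["Y"]] / sum(eqb$state)
  expect_equal(b$estimate, truth, tolerance = 0.1)
})

test_that("saturating-supplementation competition recovers the growth-rate asymmetry", {
  p <- cf_params()  # r_y/r_x = 0.925: a 7.5% intrinsic disadvantage
  cfg <- experiment_config(days = 7, conditions = 200,
                           f0 = c(1 / 3, 1, 3), n0 = 0.05,
                           monocultures = FALSE, od_noise_sd = 0.02,
                           cytometer_sample = 10000, seed = 31)
  plate <- simulate_plate(cfg, p)
  rec <- day_fitness_records(plate)
  est <- estimate_growth_disadvantage(rec, dilution_factor = 10,
                                      n_boot = 500, seed = 3)
  expect_equal(est$estimate, 0.075, tolerance = 0.15)
  expect_true(est$ci[1] <= 0.08 && est$ci[2] >= 0.07)
})

test_that("experimental regime calls agree with trivial plate patterns", {
  dead <- data.frame(day = 1:7, od = 1e-4)
  co_dead <- data.frame(well = "c1", day = 1:7, od = 1e-4,
                        fraction_y = NA_real_)
  r <- classify_experimental_regime(dead, dead, co_dead)
  expect_equal(r$name, "collapse_extinction")
})
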