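test_that("trajectories stay in the simplex and respect trivial fixed points", {
  p <- default_params(0.2)
  tr <- integrate_continuous(p, c(0, 0), t_end = 10)
  expect_true(all(tr$X == 0 & tr$Y == 0))
  expect_equal(attr(tr, "terminal_fate"), "extinction")
  # started inside the unit simplex, total density never exceeds 1
  set.seed(3)
  for (i in 1:5) {
    n0 <- runif(1, 0.05, 0.95); fr <- runif(1, 0.05, 0.95)
    tr <- integrate_continuous(p, c(n0 * fr, n0 * (1 - fr)), t_end = 60)
    expect_true(all(tr$n <= 1 + 1e-9))
    expect_true(all(tr$X >= 0 & tr$Y >= 0))
  }
})

test_that("relaxation towards the stable node follows the slow eigenvalue", {
  p <- default_params(0.1)
  eq <- stable_interior(p)
  v <- Re(eq$eigenvectors[, 1])
  start <- eq$state + 0.02 * v / sqrt(sum(v^2))
  tr <- integrate_continuous(p, start, t_end = 40, dt_out = 1)
  d <- sqrt((tr$X - eq$state[["X"]])^2 + (tr$Y - eq$state[["Y"]])^2)
  keep <- tr$time >= 5 & d > 1e-8
  slope <- coef(lm(log(d[keep]) ~ tr$time[keep]))[[2]]
  expect_equal(slope, Re(eq$eigenvalues[1]), tolerance = 0.05)
})

test_that("below the fold every trajectory is attracted to extinction", {
  p <- default_params(0.08)
  for (init in list(c(0.1, 0.1), c(0.4, 0.2), c(0.05, 0.3))) {
    tr <- integrate_continuous(p, init, t_end = 400, dt_out = 50)
    expect_equal(attr(tr, "terminal_fate"), "extinction")
  }
})

test_that("the daily dilution map has the expected limits", {
  p <- default_params(0)
  z <- batch_dilution_map(p, c(0, 0))
  expect_equal(unname(z$next_day), c(0, 0))
  # no nutrients: a monoculture only gets diluted, exactly 10x per day
  m <- batch_dilution_map(p, c(0.2, 0), dilution_factor = 10)
  expect_equal(m$end_of_day[["X"]], 0.2, tolerance = 1e-9)
  expect_equal(m$next_day[["X"]], 0.02, tolerance = 1e-9)
  # saturating supplementation: the culture persists across iterated days
  tr <- iterate_dilution(cf_params(a = 5), c(0.05, 0), days = 8)
  expect_gt(tr$n[nrow(tr)], 0.5)
  # growth covers at least log2(10) doublings per surviving day
  doublings <- log2(tr$X[-1] / (tr$X[-nrow(tr)] / 10))[-1]
  expect_true(all(doublings >= log2(10) - 1e-6))
})

test_that("iterated dilution matches the continuous fate classification", {
  # collapse condition: both protocols go extinct
  lo <- iterate_dilution(default_params(0.02), c(0.025, 0.025), days = 10)
  expect_lt(lo$n[nrow(lo)], 1e-4)
  # coexistence condition: both protocols settle at an interior state
  hi <- iterate_dilution(default_params(0.23), c(0.025, 0.025), days = 30)
  expect_gt(hi$X[nrow(hi)], 0.01)
  expect_gt(hi$Y[nrow(hi)], 0.01)
})

test_that("fate grids show all-extinct, all-coexist and size-dependent zones", {
  n_vals <- 10^seq(-4, -0.5, length.out = 6)
  f_vals <- c(0.01, 1, 100)
  fg_low <- fate_grid(default_params(0.08), n_vals, f_vals, t_end = 400)
  expect_true(all(fg_low$fate == "extinction"))
  fg_mid <- fate_grid(default_params(0.23), n_vals, f_vals, t_end = 400)
  expect_true(all(fg_mid$fate == "coexistence"))
  # just above the fold, survival needs size and balance
  fg <- fate_grid(default_params(0.084), n_vals, c(1, 100), t_end = 600)
  surv_n <- function(fr) {
    s <- fg[fg$f0 == fr & fg$fate == "coexistence", "n0"]
    if (length(s)) min(s) else Inf
  }
  expect_lt(surv_n(1), surv_n(100))  # balanced cultures survive smaller
  # within each ratio column the coexistence set is a contiguous upper tail
  for (fr in unique(fg$f0)) {
    col <- fg[fg$f0 == fr, ]
    col <- col[order(col$n0), ]
    coex <- col$fate == "coexistence"
    if (any(coex)) expect_true(all(coex[which.max(coex):length(coex)]))
  }
})

test_that("relaxation anisotropy flips between the two collapse boundaries", {
  # near the fold: total density n is slow, the ratio f relaxes fast
  near_fold <- relaxation_diagnostics(default_params(0.084))
  expect_gt(near_fold$align_constant_f, 0.95)
  expect_gt(near_fold$timescale_ratio, 1)
  # near exclusion: n is fast, f is slow
  near_ex <- relaxation_diagnostics(default_params(0.73))
  expect_gt(near_ex$align_constant_n, 0.95)
  # mid-range: no separation of timescales
  mid <- relaxation_diagnostics(default_params(0.1))
  expect_lt(mid$timescale_ratio, 3)
  expect_error(relaxation_diagnostics(default_params(0.05)),
               "no stable interior")
})
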