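test_that("regime labels at the reference phase-portrait conditions", {
  expect_equal(classify_regime(default_params(0.09))$name, "obligatory_mutualism")
  expect_equal(classify_regime(default_params(0.13))$name, "obligatory_facultative")
  expect_equal(classify_regime(default_params(0.23))$name, "competition")
  expect_equal(classify_regime(default_params(0.9))$name, "competitive_exclusion")
  expect_equal(classify_regime(default_params(0.02))$name, "collapse_extinction")
})

test_that("effect codes are consistent with the regime name", {
  r <- classify_regime(default_params(0.16))
  expect_equal(r$name, "facultative_mutualism")
  expect_equal(c(r$effect_x, r$effect_y), c("+", "+"))
  r <- classify_regime(default_params(0.19))
  expect_equal(r$name, "parasitism")
  expect_setequal(c(r$effect_x, r$effect_y), c("+", "-"))
  expect_equal(r$effect_y, "+")   # Leu- benefits, Trp- is harmed
  r <- classify_regime(default_params(0.3))
  expect_equal(c(r$name, r$effect_x, r$effect_y), c("competition", "-", "-"))
  r <- classify_regime(default_params(0.9))
  expect_equal(c(r$effect_x, r$effect_y), c("0", "X"))
  r <- classify_regime(default_params(0.02))
  expect_equal(c(r$effect_x, r$effect_y), c("X", "X"))
})

test_that("amensalism appears only as a boundary band, with Leu- unaffected", {
  # the parasitism/competition boundary: Trp- harmed, Leu- neutral
  band <- vapply(seq(0.221, 0.227, by = 0.001),
                 function(a) classify_regime(default_params(a))$name, "")
  expect_true("amensalism" %in% band)
  r <- classify_regime(default_params(0.224))
  if (r$name == "amensalism")
    expect_equal(c(r$effect_x, r$effect_y), c("-", "0"))
})

test_that("the 1-D scan returns the seven broad regimes in the expected order", {
  sc <- regime_scan(default_params(), seq(0.005, 1, by = 0.005))
  expect_equal(regime_sequence(sc),
               c("collapse_extinction", "obligatory_mutualism",
                 "obligatory_facultative", "facultative_mutualism",
                 "parasitism", "competition", "competitive_exclusion"))
  # a grid entirely below the fold is one collapse interval
  low <- regime_scan(default_params(), seq(0.005, 0.05, by = 0.005))
  expect_equal(nrow(low), 1L)
  expect_equal(low$label, "collapse_extinction")
})

test_that("symmetric strains produce only symmetric outcomes", {
  sym <- cf_params(r_y = 1, beta = 1)
  sc <- regime_scan(sym, seq(0.02, 1, by = 0.02))
  expect_false(any(sc$label %in% c("parasitism", "competitive_exclusion")))
})

test_that("classification away from boundaries is invariant to the neutrality band", {
  for (a in c(0.09, 0.16, 0.19, 0.4, 0.9)) {
    l1 <- classify_regime(default_params(a), rel_tol = 0.005)$name
    l2 <- classify_regime(default_params(a), rel_tol = 0.02)$name
    expect_equal(l1, l2)
  }
})

test_that("label sequence is stable under grid refinement", {
  coarse <- regime_scan(default_params(), seq(0.01, 1, by = 0.01))
  fine <- regime_scan(default_params(), seq(0.0025, 1, by = 0.0025))
  expect_equal(regime_sequence(coarse), regime_sequence(fine))
  # boundary positions shift by less than one coarse step
  for (lab in regime_sequence(coarse)) {
    lo_c <- min(coarse$a_lo[coarse$label == lab])
    lo_f <- min(fine$a_lo[fine$label == lab])
    expect_lt(abs(lo_c - lo_f), 0.01 + 1e-9)
  }
})

test_that("2-D maps respect the canonical regime order on every row", {
  p <- default_params()
  a_grid <- seq(0.02, 1, by = 0.02)
  # death-rate axis: same order of regimes across a wide delta range
  m <- regime_map_2d(p, a_grid, c(0.3, 0.5, 0.7), "delta")
  for (d in unique(m$delta)) {
    row <- m[m$delta == d, ]
    seqs <- rle(row$label[row$label != "amensalism"])$values
    expect_true(all(seqs %in% regime_order()))
    pos <- match(seqs, regime_order())
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
  # delta = 0: nothing dies without dilution, so no collapse at any a > 0
  m0 <- regime_map_2d(p, c(0.05, 0.2, 0.5), c(0, 0.5), "delta")
  expect_false(any(m0$label[m0$delta == 0] == "collapse_extinction"))
})

test_that("smaller niche overlap enlarges the mutualistic region", {
  p <- default_params()
  a_grid <- seq(0.02, 1, by = 0.02)
  m <- regime_map_2d(p, a_grid, c(0.4, 0.7, 1.0), "c")
  mut_area <- vapply(unique(m$c), function(cc)
    sum(m$label[m$c == cc] %in%
          c("obligatory_mutualism", "obligatory_facultative",
            "facultative_mutualism")), 0L)
  expect_false(is.unsorted(rev(mut_area)))  # non-increasing in c
})

test_that("regime map exports tidy CSV with a legend", {
  sc <- regime_scan(default_params(), seq(0.05, 0.3, by = 0.05))
  csv <- file.path(tempdir(), "reg.csv"); js <- file.path(tempdir(), "leg.json")
  write_regime_map(attr(sc, "per_a"), csv, js)
  re <- utils::read.csv(csv)
  expect_named(re, c("a", "label", "effect_x", "effect_y"))
  expect_length(jsonlite::read_json(js), 8L)
})
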