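test_that("every returned fixed point satisfies the equilibrium condition", {
  for (a in c(0, 0.05, 0.09, 0.13, 0.23, 0.5, 0.9)) {
    p <- default_params(a)
    for (e in find_equilibria(p))
      expect_lt(rhs_norm(e$state, p), 1e-9)
  }
})

test_that("equilibrium sets match the reference phase portraits", {
  # a = 0.08: extinction only - no stable interior, origin stable
  eqs <- find_equilibria(default_params(0.08))
  kinds <- vapply(eqs, function(e) e$kind, "")
  expect_false(any(kinds == "interior" &
                     vapply(eqs, function(e) e$stable, TRUE)))
  expect_true(eqs[[which(kinds == "origin")]]$stable)
  # a = 0.09: stable co-culture node plus an interior saddle
  eqs <- find_equilibria(default_params(0.09))
  ints <- Filter(function(e) e$kind == "interior", eqs)
  expect_length(ints, 2L)
  expect_setequal(vapply(ints, function(e) e$stable, TRUE), c(TRUE, FALSE))
  # a = 0: only the origin, doubly stable at rate -delta
  eqs <- find_equilibria(default_params(0))
  expect_length(eqs, 1L)
  expect_equal(Re(eqs[[1]]$eigenvalues), c(-0.5, -0.5))
})

test_that("origin eigenvalues follow the closed form r*a/(a+kappa) - delta", {
  p <- default_params(0.13)
  e <- jacobian_eigen(c(0, 0), p)
  g <- 0.13 / 0.25
  expect_equal(sort(Re(e$values), decreasing = TRUE),
               sort(c(1 * g - 0.5, 0.925 * g - 0.5), decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(Re(e$values), c(0.02, -0.019), tolerance = 1e-10)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(42)
  for (i in 1:30) {
    st <- runif(2, 0.01, 0.9)
    p <- cf_params(a = runif(1, 0, 1), c = runif(1, 0, 1),
                   delta = runif(1, 0.1, 0.8))
    expect_equal(unname(cf_jacobian(st, p)), fd_jacobian(st, p),
                 tolerance = 1e-4)
  }
})

test_that("eigen-pairs are slow-first with unit eigenvectors", {
  e <- jacobian_eigen(c(0.1, 0.15), default_params(0.1))
  expect_gte(Re(e$values[1]), Re(e$values[2]))
  expect_equal(colSums(Mod(e$vectors)^2), c(1, 1), tolerance = 1e-12)
})

test_that("saddle-node location falls in the expected bracket and is a fold", {
  a_star <- saddle_node_point(default_params())
  expect_gt(a_star, 0.08)
  expect_lt(a_star, 0.09)
  # slow eigenvalue approaches zero just above the fold
  eq <- stable_interior(cf_params(a = a_star + 1e-6))
  expect_false(is.null(eq))
  expect_lt(abs(Re(eq$eigenvalues[1])), 1e-2)
  # the two interior points annihilate across the fold
  below <- Filter(function(e) e$kind == "interior",
                  find_equilibria(cf_params(a = a_star - 1e-4)))
  above <- Filter(function(e) e$kind == "interior",
                  find_equilibria(cf_params(a = a_star + 1e-4)))
  expect_length(below, 0L)
  expect_length(above, 2L)
  # without death the mutualism cannot collapse
  expect_error(saddle_node_point(cf_params(delta = 0), bracket = c(0.05, 1)),
               "bracketing error")
})

test_that("exclusion threshold falls in the expected bracket; Y leaves continuously", {
  a_ex <- exclusion_threshold(default_params())
  expect_gt(a_ex, 0.23)
  expect_lt(a_ex, 0.9)
  y_near <- stable_interior(cf_params(a = a_ex - 1e-3))$state[["Y"]]
  y_far <- stable_interior(cf_params(a = a_ex - 0.05))$state[["Y"]]
  expect_lt(y_near, y_far)         # Y* shrinks towards the boundary
  expect_lt(y_near, 0.01)          # and is already tiny close to it
  expect_null(stable_interior(cf_params(a = a_ex + 1e-3)))
  # symmetric strains coexist at any supplementation: no exclusion to find
  sym <- cf_params(r_y = 1, beta = 1)
  expect_error(exclusion_threshold(sym, bracket = c(0.23, 0.9)),
               "bracketing error")
})

test_that("critical points are invariant under interior-grid refinement", {
  p <- default_params()
  a1 <- saddle_node_point(p)
  pred_fine <- function(a) !is.null(stable_interior(cf_params(a = a),
                                                    n_grid = 30000L))
  # re-bisect with a 3x finer interior scan
  lo <- 0.05; hi <- 0.15
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (pred_fine(mid)) hi <- mid else lo <- mid
  }
  expect_equal(a1, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("bifurcation scan orders the four boundaries and matches closed forms", {
  p <- default_params()
  bs <- bifurcation_scan(p, seq(0.01, 1, by = 0.01))
  b <- bs$boundaries
  expect_setequal(b$boundary,
                  c("saddle_node", "x_viability", "y_viability", "exclusion"))
  expect_equal(b$boundary[order(b$a)],
               c("saddle_node", "x_viability", "y_viability", "exclusion"))
  expect_equal(b$a[b$boundary == "x_viability"], 0.12, tolerance = 1e-6)
  expect_equal(b$a[b$boundary == "y_viability"], 0.06 / 0.425,
               tolerance = 1e-6)
  # the scan's axis-branch appearance brackets the closed-form threshold
  xa <- bs$grid[bs$grid$kind == "X-axis", ]
  expect_gt(min(xa$a), 0.12 - 1e-9)
  # grid entirely below the fold: no interior branch anywhere
  low <- bifurcation_scan(p, seq(0.01, 0.07, by = 0.01))
  expect_false(any(low$grid$kind == "interior"))
  # export round-trip
  csv <- file.path(tempdir(), "bif.csv"); js <- file.path(tempdir(), "bif.json")
  write_bifurcation(bs, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), nrow(bs$grid))
  expect_named(jsonlite::read_json(js),
               c("saddle_node", "x_viability", "y_viability", "exclusion"),
               ignore.order = TRUE)
})
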