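#' Analytic Jacobian of the cross-feeding model
#'
#' Exact partial derivatives of [cf_rhs()] at an arbitrary state (finite
#' differences are used only as a cross-check in the test suite).
#'
#' @param state Numeric length-2 vector `c(X, Y)`.
#' @param params A [cf_params()] object.
#' @return A 2x2 numeric matrix, rows = (dX, dY), columns = (X, Y).
#' @export
cf_jacobian <- function(state, params) {
  X <- state[[1]]; Y <- state[[2]]
  a <- params$a; k <- params$kappa; cc <- params$c; b <- params$beta
  g_x <- (Y + a) / (Y + a + k)
  g_y <- (b * X + a) / (b * X + a + k)
  dgx <- k / (Y + a + k)^2          # d g_x / dY
  dgy <- b * k / (b * X + a + k)^2  # d g_y / dX
  L1 <- 1 - X - cc * Y
  L2 <- 1 - cc * X - Y
  matrix(c(params$r_x * g_x * (L1 - X) - params$delta,
           params$r_x * X * (dgx * L1 - g_x * cc),
           params$r_y * Y * (dgy * L2 - cc * g_y),
           params$r_y * g_y * (L2 - Y) - params$delta),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dX", "dY"), c("X", "Y")))
}

#' Jacobian eigen-analysis at a state
#'
#' Eigenvalues and unit eigenvectors of the analytic Jacobian, ordered
#' slow-first (larger real part first: for a stable point the slow eigenvalue
#' is the one closer to zero from below). Complex pairs are permitted and
#' classified by real part.
#'
#' @inheritParams cf_jacobian
#' @return List with `jacobian`, `values` (length 2, slow first),
#'   `vectors` (2x2, unit columns matching `values`).
#' @export
jacobian_eigen <- function(state, params) {
  J <- cf_jacobian(state, params)
  e <- eigen(J)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (j in 1:2) vecs[, j] <- vecs[, j] / sqrt(sum(Mod(vecs[, j])^2))
  if (all(abs(Im(vals)) < 1e-12)) {
    vals <- Re(vals)
    if (all(abs(Im(vecs)) < 1e-12)) vecs <- Re(vecs)
  }
  list(jacobian = J, values = vals, vectors = vecs)
}

# Interior equilibria: eliminate X through the X-balance condition
# r_x g_x(Y) (1 - X - cY) = delta  =>  X(Y) = 1 - cY - delta/(r_x g_x(Y)),
# then scan the residual of the Y-balance condition on a fine Y grid and
# bisect every sign change. O(n_grid) evaluations; guarantees all roots at
# desk scale.
.interior_equilibria <- function(params, n_grid = 10000L) {
  a <- params$a; k <- params$kappa; cc <- params$c
  X_of <- function(Y) {
    g_x <- (Y + a) / (Y + a + k)
    X <- 1 - cc * Y - params$delta / (params$r_x * g_x)
    X[g_x <= 0] <- NA_real_
    X
  }
  resid <- function(Y) {
    X <- X_of(Y)
    g_y <- (params$beta * X + a) / (params$beta * X + a + k)
    r <- params$r_y * g_y * (1 - cc * X - Y) - params$delta
    r[!is.finite(X) | X <= 0] <- NA_real_
    r
  }
  Ys <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  v <- resid(Ys)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1L)) {
    if (is.na(v[i]) || is.na(v[i + 1L])) next
    if (v[i] == 0) {
      # exact zeros only count when isolated: with delta = 0 the balance
      # conditions degenerate to a continuum (resid vanishes identically),
      # which is a line attractor, not a set of isolated fixed points
      if ((i == 1L || is.na(v[i - 1L]) || v[i - 1L] != 0) && v[i + 1L] != 0)
        roots <- c(roots, Ys[i])
    } else if (v[i] * v[i + 1L] < 0)
      roots <- c(roots, stats::uniroot(resid, c(Ys[i], Ys[i + 1L]),
                                       tol = 1e-13)$root)
  }
  out <- lapply(roots, function(Y) c(X = X_of(Y), Y = Y))
  Filter(function(s) s[["X"]] > 0, out)
}

.make_equilibrium <- function(state, kind, params) {
  eig <- jacobian_eigen(state, params)
  structure(list(state = c(X = unname(state[[1]]), Y = unname(state[[2]])),
                 kind = kind,
                 eigenvalues = eig$values,
                 eigenvectors = eig$vectors,
                 stable = all(Re(eig$values) < 1e-10)),
            class = "cf_equilibrium")
}

#' @export
print.cf_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (X=%.6g, Y=%.6g) %s; eigenvalues (%.4g, %.4g)\n",
              x$kind, x$state[["X"]], x$state[["Y"]],
              if (x$stable) "stable" else "unstable",
              Re(x$eigenvalues[1]), Re(x$eigenvalues[2])))
  invisible(x)
}

#' Find all fixed points of the model
#'
#' Returns the origin, the monoculture (axis) fixed points where viable, and
#' every interior fixed point (0, 1 or 2 for the default parameters),
#' each with its Jacobian eigen-data and stability call. Interior points are
#' located by reducing the two balance conditions to a scalar equation in Y
#' and bisecting all sign changes on a fine grid (see Details).
#'
#' @param params A [cf_params()] object.
#' @param n_grid Number of Y grid points for the interior scan.
#' @return A list of `cf_equilibrium` objects. An empty interior set is a
#'   valid outcome (e.g. below the saddle-node point).
#' @examples
#' eqs <- find_equilibria(cf_params(a = 0.09))
#' vapply(eqs, function(e) e$kind, "")
#' @export
find_equilibria <- function(params, n_grid = 10000L) {
  params <- validate_params(params)
  pts <- list(.make_equilibrium(c(0, 0), "origin", params))
  xm <- monoculture_equilibrium(params, "X")
  if (xm > 0) pts <- c(pts, list(.make_equilibrium(c(xm, 0), "X-axis", params)))
  ym <- monoculture_equilibrium(params, "Y")
  if (ym > 0) pts <- c(pts, list(.make_equilibrium(c(0, ym), "Y-axis", params)))
  for (s in .interior_equilibria(params, n_grid))
    pts <- c(pts, list(.make_equilibrium(s, "interior", params)))
  pts
}

#' Stable interior (co-culture) equilibrium, or NULL
#'
#' @inheritParams find_equilibria
#' @param y_min Minimum Y density for the point to count as interior
#'   (guards the transcritical merge with the X axis).
#' @return A `cf_equilibrium`, or `NULL` when no stable coexistence exists.
#' @export
stable_interior <- function(params, n_grid = 10000L, y_min = 1e-9) {
  eqs <- find_equilibria(params, n_grid)
  for (e in eqs)
    if (e$kind == "interior" && e$stable && e$state[["Y"]] > y_min) return(e)
  NULL
}

.bisect_a <- function(params, bracket, predicate, tol = 1e-8, what = "boundary") {
  lo <- bracket[[1]]; hi <- bracket[[2]]
  p_lo <- predicate(lo); p_hi <- predicate(hi)
  if (p_lo == p_hi)
    stop("bracketing error locating the ", what, ": predicate is ",
         p_lo, " at both a=", lo, " and a=", hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (predicate(mid) == p_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Locate the saddle-node bifurcation point in a
#'
#' Bisection on the predicate "a stable interior equilibrium exists" over the
#' given bracket. Below the returned `a*` the co-culture has no stable
#' coexistence state and all trajectories are attracted to extinction; at
#' `a*` the stable node and the interior saddle coincide and the slow
#' eigenvalue crosses zero (critical slowing down).
#'
#' @param params A [cf_params()] object (its `a` is ignored).
#' @param bracket Length-2 vector `(a_lo, a_hi)` with existence differing at
#'   the two ends.
#' @param tol Bisection tolerance in a.
#' @return The critical supplementation level `a*`.
#' @examples
#' \donttest{saddle_node_point(cf_params())  # ~0.082 for the defaults}
#' @export
saddle_node_point <- function(params, bracket = c(0.05, 0.15), tol = 1e-8) {
  pred <- function(a) {
    params$a <- a
    !is.null(stable_interior(params))
  }
  .bisect_a(params, bracket, pred, tol, what = "saddle-node point")
}

#' Locate the competitive-exclusion threshold in a
#'
#' Bisection on the predicate "a stable interior equilibrium with Y > 0
#' exists". Above the returned value the stable attractor lies on the X axis:
#' the slower-growing Leu- strain is competitively excluded. The interior
#' point leaves the positive quadrant continuously (a transcritical passage
#' through the X-axis fixed point), unlike the fold at the saddle-node end.
#'
#' @inheritParams saddle_node_point
#' @return The exclusion threshold in a.
#' @examples
#' \donttest{exclusion_threshold(cf_params())  # ~0.73 for the defaults}
#' @export
exclusion_threshold <- function(params, bracket = c(0.2, 1.0), tol = 1e-8) {
  pred <- function(a) {
    params$a <- a
    !is.null(stable_interior(params, y_min = 1e-9))
  }
  .bisect_a(params, bracket, pred, tol, what = "exclusion threshold")
}

#' Bifurcation scan over a grid of supplementation levels
#'
#' Computes all fixed points at every grid value and locates the four
#' boundary types (saddle-node, X and Y monoculture viability, competitive
#' exclusion) — the viability thresholds from their closed forms, the other
#' two by bisection between bracketing grid points. Total stable-interior
#' density is checked for monotone increase between boundaries; violations
#' are reported as warnings, never errors.
#'
#' @param params A [cf_params()] object (its `a` is scanned over).
#' @param a_grid Increasing grid of supplementation levels (>= 2 points).
#' @return A `cf_bifurcation` list: `grid` (tidy data.frame with columns
#'   a, kind, X, Y, stable, eig_slow, eig_fast) and `boundaries` (data.frame
#'   with columns boundary, a).
#' @export
bifurcation_scan <- function(params, a_grid) {
  stopifnot(length(a_grid) >= 2L, !is.unsorted(a_grid, strictly = TRUE))
  rows <- list()
  has_stable_int <- logical(length(a_grid))
  for (i in seq_along(a_grid)) {
    params$a <- a_grid[i]
    eqs <- find_equilibria(params)
    for (e in eqs) {
      rows[[length(rows) + 1L]] <- data.frame(
        a = a_grid[i], kind = e$kind,
        X = e$state[["X"]], Y = e$state[["Y"]], stable = e$stable,
        eig_slow = Re(e$eigenvalues[1]), eig_fast = Re(e$eigenvalues[2]))
      if (e$kind == "interior" && e$stable && e$state[["Y"]] > 1e-9)
        has_stable_int[i] <- TRUE
    }
  }
  grid_df <- do.call(rbind, rows)

  bnd <- list()
  flips <- which(diff(has_stable_int) != 0)
  for (i in flips) {
    br <- c(a_grid[i], a_grid[i + 1L])
    lab <- if (has_stable_int[i + 1L]) "saddle_node" else "exclusion"
    a_c <- tryCatch(
      if (lab == "saddle_node") saddle_node_point(params, br)
      else exclusion_threshold(params, br),
      error = function(e) { warning(conditionMessage(e)); NA_real_ })
    bnd[[length(bnd) + 1L]] <- data.frame(boundary = lab, a = a_c)
  }
  for (s in c("X", "Y")) {
    th <- tryCatch(monoculture_viability_threshold(params, s),
                   error = function(e) NA_real_)
    if (is.finite(th) && th > min(a_grid) && th < max(a_grid))
      bnd[[length(bnd) + 1L]] <- data.frame(
        boundary = if (s == "X") "x_viability" else "y_viability", a = th)
  }
  boundaries <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(boundary = character(0), a = numeric(0))
  boundaries <- boundaries[order(boundaries$a), , drop = FALSE]
  rownames(boundaries) <- NULL

  si <- grid_df[grid_df$kind == "interior" & grid_df$stable, , drop = FALSE]
  if (nrow(si) > 1L) {
    n_tot <- si$X + si$Y
    cuts <- findInterval(si$a, sort(boundaries$a))
    for (seg in unique(cuts)) {
      d <- diff(n_tot[cuts == seg])
      if (any(d < -1e-8))
        warning("stable-interior total density is not monotone in a within ",
                "a boundary-free segment (largest drop ", min(d), ")")
    }
  }
  structure(list(grid = grid_df, boundaries = boundaries,
                 params = params), class = "cf_bifurcation")
}

#' Export a bifurcation diagram to CSV (+ optional JSON boundary summary)
#'
#' @param x A `cf_bifurcation` from [bifurcation_scan()].
#' @param csv_path Destination for the tidy grid CSV.
#' @param json_path Optional destination for the boundary summary JSON.
#' @return `csv_path`, invisibly.
#' @export
write_bifurcation <- function(x, csv_path, json_path = NULL) {
  stopifnot(inherits(x, "cf_bifurcation"))
  utils::write.csv(x$grid, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    bl <- as.list(stats::setNames(x$boundaries$a, x$boundaries$boundary))
    jsonlite::write_json(bl, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
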