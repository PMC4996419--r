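#' Integrate the continuous-culture model
#'
#' Solves the two-strain ODE with a stiff-capable adaptive integrator
#' (`deSolve::ode`, lsoda; relative tolerance 1e-9, absolute 1e-12).
#' Densities are clamped non-negative inside the derivative call and in the
#' output, and densities below the extinction snap threshold 1e-10 are set
#' to exactly 0 to prevent underflow chatter; no negative overshoot beyond
#' 1e-12 survives into the returned trajectory.
#'
#' @param params A [cf_params()] object.
#' @param initial Numeric length-2 `c(X, Y)` starting densities.
#' @param t_end End time (> 0), in units of the Trp- strain's division time.
#' @param dt_out Output sampling interval.
#' @param classify_fate Attach the `terminal_fate` attribute (requires a
#'   full fixed-point search; turn off for inner loops that classify
#'   separately).
#' @return A `cf_trajectory`: data frame with columns `time, X, Y, n, f`
#'   (`f = NA` where `Y = 0`) and attribute `terminal_fate`, one of
#'   `coexistence`, `extinction`, `exclusion_x` (collapsed onto the X axis),
#'   `exclusion_y` (Y axis) or `unresolved`. The fate is assigned by
#'   proximity (1e-4) of the final state to a stable fixed point.
#' @examples
#' tr <- integrate_continuous(cf_params(a = 0.23), c(0.05, 0.05), t_end = 200)
#' attr(tr, "terminal_fate")
#' @export
integrate_continuous <- function(params, initial, t_end, dt_out = 0.5,
                                 classify_fate = TRUE) {
  params <- validate_params(params)
  stopifnot(t_end > 0, length(initial) == 2L, all(initial >= 0))
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(unname(cf_rhs(y, params)))
  }
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(y = c(X = initial[[1]], Y = initial[[2]]), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; last valid state: X=",
         sol[nrow(sol), "X"], " Y=", sol[nrow(sol), "Y"])
  X <- pmax(sol[, "X"], 0); Y <- pmax(sol[, "Y"], 0)
  X[X < 1e-10] <- 0; Y[Y < 1e-10] <- 0
  out <- data.frame(time = sol[, "time"], X = X, Y = Y,
                    n = X + Y, f = ifelse(Y > 0, X / Y, NA_real_))
  if (classify_fate)
    attr(out, "terminal_fate") <- .terminal_fate(c(X[length(X)],
                                                   Y[length(Y)]), params)
  class(out) <- c("cf_trajectory", "data.frame")
  out
}

# Classify a final state by proximity to a stable fixed point. An
# (essentially) empty state is extinct no matter whether the origin is
# stable: extinction is absorbing even where it is dynamically repelling.
.terminal_fate <- function(state, params, tol = 1e-4, equilibria = NULL) {
  if (sum(state) <= tol) return("extinction")
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  for (e in equilibria) {
    if (!e$stable) next
    if (sqrt(sum((state - e$state)^2)) <= tol)
      return(switch(e$kind,
                    origin = "extinction",
                    "X-axis" = "exclusion_x",
                    "Y-axis" = "exclusion_y",
                    interior = "coexistence"))
  }
  "unresolved"
}

#' One day of the batch growth-dilution map
#'
#' The serial-dilution analogue of the continuous model: grow for `t_day`
#' time units with the death rate forced to zero (dilution is the only death
#' process in batch culture), then divide both densities by
#' `dilution_factor`. Iterating this map emulates the daily protocol; a
#' population must divide at least log2(dilution_factor) times per day to
#' persist.
#'
#' @param params A [cf_params()] object; its `delta` is ignored (set to 0
#'   within the day).
#' @param state Numeric length-2 `c(X, Y)` at the start of the day.
#' @param dilution_factor Daily dilution (> 1; the experiments use 10).
#' @param t_day Length of the growth period in model time units.
#' @return List with `end_of_day` (densities after growth, before dilution)
#'   and `next_day` (after dilution).
#' @export
batch_dilution_map <- function(params, state, dilution_factor = 10,
                               t_day = log(10) / 0.5) {
  stopifnot(dilution_factor > 1)
  p <- params; p$delta <- 0
  tr <- integrate_continuous(p, state, t_end = t_day, dt_out = t_day,
                             classify_fate = FALSE)
  grown <- c(X = tr$X[nrow(tr)], Y = tr$Y[nrow(tr)])
  list(end_of_day = grown, next_day = grown / dilution_factor)
}

#' Iterate the daily dilution map for several days
#'
#' @inheritParams batch_dilution_map
#' @param days Number of growth-dilution cycles.
#' @return Data frame with columns `day` (0..days), `X`, `Y`, `n`, `f`:
#'   row `day = d` holds the end-of-day (pre-dilution) densities of day d;
#'   row 0 is the initial state.
#' @export
iterate_dilution <- function(params, state, days, dilution_factor = 10,
                             t_day = log(10) / 0.5) {
  out <- data.frame(day = 0:days, X = NA_real_, Y = NA_real_)
  out$X[1] <- state[[1]]; out$Y[1] <- state[[2]]
  cur <- c(state[[1]], state[[2]])
  for (d in seq_len(days)) {
    step <- batch_dilution_map(params, cur, dilution_factor, t_day)
    out$X[d + 1L] <- step$end_of_day[["X"]]
    out$Y[d + 1L] <- step$end_of_day[["Y"]]
    cur <- unname(step$next_day)
  }
  out$n <- out$X + out$Y
  out$f <- ifelse(out$Y > 0, out$X / out$Y, NA_real_)
  out
}

#' Fate grid over initial total density and strain ratio
#'
#' Integrates one trajectory per cell of an (n0, f0) grid of initial
#' conditions (n = X + Y total density, f = X / Y ratio) and records the
#' terminal fate. Near the saddle-node point, populations that start too
#' small or too imbalanced are fated to extinction while balanced, large
#' ones reach the co-culture equilibrium.
#'
#' @param params A [cf_params()] object.
#' @param n_values Positive initial total densities.
#' @param f_values Positive initial ratios X/Y.
#' @param t_end Integration horizon (default 500 time units); trajectories
#'   still unresolved at the horizon are labeled, not extended.
#' @return Data frame with columns `n0`, `f0`, `fate`.
#' @export
fate_grid <- function(params, n_values, f_values, t_end = 500) {
  stopifnot(all(n_values > 0), all(f_values > 0))
  equilibria <- find_equilibria(params)
  grid <- expand.grid(n0 = n_values, f0 = f_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$fate <- vapply(seq_len(nrow(grid)), function(i) {
    n0 <- grid$n0[i]; f0 <- grid$f0[i]
    init <- c(n0 * f0 / (1 + f0), n0 / (1 + f0))
    tr <- integrate_continuous(params, init, t_end, dt_out = t_end / 4,
                               classify_fate = FALSE)
    .terminal_fate(c(tr$X[nrow(tr)], tr$Y[nrow(tr)]), params,
                   equilibria = equilibria)
  }, character(1))
  grid
}

#' Relaxation-anisotropy diagnostics at the co-culture equilibrium
#'
#' The early-warning signature of the model: near the saddle-node collapse
#' the slow eigenvector points radially (constant strain ratio f — total
#' density n is the slow variable), whereas near competitive exclusion it
#' points along (1, -1)/sqrt(2) (constant n — the ratio f is slow).
#'
#' @param params A [cf_params()] object with a stable interior equilibrium.
#' @return List with `timescale_ratio` (|fast| / |slow| eigenvalue, >= 1 at
#'   a stable node), `align_constant_f` (|cos| of the angle between the slow
#'   eigenvector and the radial direction through the equilibrium) and
#'   `align_constant_n` (|cos| against (1, -1)/sqrt(2)).
#' @export
relaxation_diagnostics <- function(params) {
  eq <- stable_interior(params)
  if (is.null(eq))
    stop("no stable interior equilibrium at a=", params$a,
         "; relaxation diagnostics undefined")
  v_slow <- Re(eq$eigenvectors[, 1])
  v_slow <- v_slow / sqrt(sum(v_slow^2))
  radial <- eq$state / sqrt(sum(eq$state^2))
  const_n <- c(1, -1) / sqrt(2)
  list(timescale_ratio = abs(Re(eq$eigenvalues[2])) / abs(Re(eq$eigenvalues[1])),
       align_constant_f = abs(sum(v_slow * radial)),
       align_constant_n = abs(sum(v_slow * const_n)),
       equilibrium = eq)
}

#' Write a trajectory to CSV
#'
#' @param tr A `cf_trajectory` (or the data frame from [iterate_dilution()]).
#' @param path Destination CSV with columns as in the trajectory.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  utils::write.csv(as.data.frame(tr), path, row.names = FALSE)
  invisible(path)
}
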