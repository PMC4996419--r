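#' Exact stochastic simulation of the cross-feeding birth-death process
#'
#' Gillespie (direct-method) simulation of the individual-based process
#' whose mean-field limit is the deterministic model: births at the
#' Monod-saturating logistic rates, deaths at rate `delta`, on a lattice
#' with `omega` individuals at carrying capacity. Demographic noise scales
#' as 1/sqrt(omega); near the saddle-node point small systems can collapse
#' even where the deterministic model coexists. The origin is absorbing.
#'
#' @param params A [cf_params()] object.
#' @param initial_counts Integer pair `c(x, y)` of starting individuals
#'   (non-negative, at most `2 * omega`).
#' @param omega System size: individuals at carrying capacity (>= 10).
#' @param t_max Simulation horizon (> 0).
#' @param record_dt Output sampling interval for the piecewise-constant path.
#' @param seed Optional RNG seed; a fixed seed gives a bit-identical event
#'   sequence. Leave `NULL` to continue the session RNG stream.
#' @return A `cf_trajectory` data frame: `time, x, y` (counts),
#'   `X, Y` (densities, counts / omega), `n, f`; attribute `absorbed` is
#'   TRUE when the walk hit (0, 0).
#' @examples
#' tr <- gillespie_simulate(cf_params(a = 0.23), c(500, 500), omega = 5000,
#'                          t_max = 20, seed = 1)
#' @export
gillespie_simulate <- function(params, initial_counts, omega = 10000,
                               t_max = 50, record_dt = 0.1, seed = NULL) {
  params <- validate_params(params)
  if (omega < 10) stop("omega must be >= 10")
  if (t_max <= 0) stop("t_max must be > 0")
  if (length(initial_counts) != 2L || any(initial_counts < 0) ||
      any(initial_counts != round(initial_counts)) ||
      any(initial_counts > 2 * omega))
    stop("initial_counts must be non-negative integers <= 2*omega")
  if (!is.null(seed)) set.seed(seed)
  m <- gillespie_core(params$r_x, params$r_y, params$kappa, params$beta,
                      params$delta, params$a, params$c, omega,
                      initial_counts[[1]], initial_counts[[2]],
                      t_max, record_dt)
  out <- data.frame(time = m[, "time"], x = m[, "x"], y = m[, "y"],
                    X = m[, "x"] / omega, Y = m[, "y"] / omega)
  out$n <- out$X + out$Y
  out$f <- ifelse(out$y > 0, out$x / out$y, NA_real_)
  attr(out, "absorbed") <- out$x[nrow(out)] == 0 && out$y[nrow(out)] == 0
  attr(out, "omega") <- omega
  class(out) <- c("cf_trajectory", "data.frame")
  out
}

#' Ensemble statistics over stochastic replicates
#'
#' Runs `n_replicates` independent simulations under distinct derived seeds
#' and aggregates them on the common sampling grid: per-time mean and
#' variance of the densities, of n and of f, and the fraction of replicates
#' absorbed at extinction by the horizon.
#'
#' @inheritParams gillespie_simulate
#' @param n_replicates Number of replicates (>= 2).
#' @param seeds Either a single base seed (replicate i uses `seed + i`) or a
#'   vector of one seed per replicate; duplicated seeds are rejected so two
#'   "replicates" can never share an event sequence.
#' @return List with `time`, `mean_X`, `mean_Y`, `mean_n`, `var_n`, `var_f`,
#'   `extinction_fraction`, `n_replicates`.
#' @export
gillespie_ensemble <- function(params, initial_counts, omega = 10000,
                               t_max = 50, record_dt = 0.5,
                               n_replicates = 10, seeds = 1) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (length(seeds) == 1L) seeds <- seeds + seq_len(n_replicates)
  if (length(seeds) != n_replicates)
    stop("need one seed per replicate (got ", length(seeds), " for ",
         n_replicates, ")")
  if (anyDuplicated(seeds))
    stop("seed collision: replicate seeds must be distinct")
  Xs <- Ys <- fs <- NULL
  absorbed <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    tr <- gillespie_simulate(params, initial_counts, omega, t_max,
                             record_dt, seed = seeds[i])
    if (is.null(Xs)) {
      Xs <- matrix(NA_real_, nrow(tr), n_replicates)
      Ys <- fs <- Xs
      time <- tr$time
    }
    Xs[, i] <- tr$X; Ys[, i] <- tr$Y; fs[, i] <- tr$f
    absorbed[i] <- attr(tr, "absorbed")
  }
  ns <- Xs + Ys
  list(time = time,
       mean_X = rowMeans(Xs), mean_Y = rowMeans(Ys),
       mean_n = rowMeans(ns),
       var_n = apply(ns, 1, stats::var),
       var_f = apply(fs, 1, stats::var),
       extinction_fraction = mean(absorbed),
       n_replicates = n_replicates)
}
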