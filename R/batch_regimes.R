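#' Fixed point of the daily growth-dilution protocol
#'
#' Iterates the batch map from a starting state until the post-dilution
#' state stops changing (relative tolerance `tol`) or the culture dies out.
#' Returns the end-of-day (pre-dilution) densities — the quantity a plate
#' reader measures.
#'
#' @param params A [cf_params()] object (its `delta` is ignored in-day).
#' @param init Numeric length-2 starting densities.
#' @param dilution_factor Daily dilution.
#' @param t_day Growth period per day.
#' @param max_days Iteration cap; non-converged runs return the last state
#'   with `converged = FALSE`.
#' @param tol Relative day-to-day change defining convergence.
#' @return List with `state` (end-of-day `c(X, Y)`), `converged`, `days`.
#' @export
batch_equilibrium <- function(params, init, dilution_factor = 10,
                              t_day = log(10) / 0.5, max_days = 400, tol = 1e-8) {
  cur <- c(init[[1]], init[[2]])
  prev_end <- NULL
  for (d in seq_len(max_days)) {
    step <- batch_dilution_map(params, cur, dilution_factor, t_day)
    endd <- unname(step$end_of_day)
    if (sum(endd) < 1e-7)  # safely below any viability cut: call it extinct
      return(list(state = c(X = 0, Y = 0), converged = TRUE, days = d))
    if (!is.null(prev_end) &&
        all(abs(endd - prev_end) <= tol * pmax(prev_end, 1e-9)))
      return(list(state = c(X = endd[1], Y = endd[2]), converged = TRUE,
                  days = d))
    prev_end <- endd
    cur <- unname(step$next_day)
  }
  list(state = c(X = prev_end[1], Y = prev_end[2]), converged = FALSE,
       days = max_days)
}

#' Predicted interaction regime under the daily-dilution protocol
#'
#' The batch-culture counterpart of [classify_regime()]: monoculture and
#' co-culture equilibria are computed by iterating the deterministic daily
#' growth-dilution map (the same dynamics the synthetic plate generator
#' uses, with no measurement noise) and fed through the same decision
#' table. This is the model prediction to compare pipeline estimates
#' against, since the continuous-culture equilibria sit at slightly
#' shifted boundary positions.
#'
#' @param params A [cf_params()] object.
#' @param dilution_factor,t_day Protocol parameters, see
#'   [batch_dilution_map()].
#' @param n0 Starting total density.
#' @param f0 Starting ratio X/Y of the co-culture.
#' @param rel_tol Neutrality band, as in [classify_regime()].
#' @param ext_tol Density below which a culture counts as extinct.
#' @return A `cf_regime` object.
#' @export
classify_regime_batch <- function(params, dilution_factor = 10, t_day = log(10) / 0.5,
                                  n0 = 0.05, f0 = 1, rel_tol = 0.01,
                                  ext_tol = 1e-6) {
  mx <- batch_equilibrium(params, c(n0, 0), dilution_factor, t_day)
  my <- batch_equilibrium(params, c(0, n0), dilution_factor, t_day)
  co <- batch_equilibrium(params, c(n0 * f0 / (1 + f0), n0 / (1 + f0)),
                          dilution_factor, t_day)
  x_mono <- mx$state[["X"]]; y_mono <- my$state[["Y"]]
  x_co <- co$state[["X"]]; y_co <- co$state[["Y"]]
  coexists <- x_co > ext_tol && y_co > ext_tol
  winner <- if (!coexists) {
    if (x_co > ext_tol) "X" else if (y_co > ext_tol) "Y"
    else if (x_mono > ext_tol || y_mono > ext_tol) {
      if (x_mono >= y_mono) "X" else "Y"
    } else NA_character_
  } else NA_character_
  out <- .regime_from_densities(x_co, y_co, x_mono, y_mono, coexists,
                                winner = winner, rel_tol = rel_tol,
                                ext_tol = ext_tol)
  out$details <- list(x_co = x_co, y_co = y_co, x_mono = x_mono,
                      y_mono = y_mono, protocol = "batch")
  out
}
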