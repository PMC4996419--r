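#' Parameters for the four-strain invasion extension
#'
#' Extends the two single-producer auxotrophs (X, Y) with a double producer
#' D (makes both amino acids, pays a growth-rate cost, gains nothing from
#' supplementation) and a non-producer N (makes neither, grows fastest, is
#' completely dependent on the medium and on the other strains). The rate
#' ordering `r_d < r_y < r_x < r_n` encodes cost of production. Only these inequalities are
#' biologically constrained; the default magnitudes are package
#' conventions chosen so that all three invasion zones (see
#' [invasion_scan()]) fall inside a reasonable supplementation range.
#'
#' @param base A [cf_params()] object for the X/Y pair.
#' @param r_d Double-producer maximum growth rate (< r_y).
#' @param r_n Non-producer maximum growth rate (> r_x).
#' @param w Weight of D's contribution to the tryptophan pool.
#' @param w_beta Weight of D's contribution to the leucine pool.
#' @return A `cf_four_params` list.
#' @export
four_strain_params <- function(base = cf_params(), r_d = 0.7, r_n = 1.2,
                               w = 1, w_beta = 1) {
  base <- validate_params(base)
  if (!(r_d > 0 && r_n > 0 && w >= 0 && w_beta >= 0))
    stop("rates must be positive and production weights non-negative")
  if (!(r_d < base$r_y && base$r_x < r_n))
    stop("rate ordering violated: need r_d < r_y < r_x < r_n, got r_d=", r_d,
         " r_y=", base$r_y, " r_x=", base$r_x, " r_n=", r_n)
  structure(list(base = base, r_d = r_d, r_n = r_n, w = w, w_beta = w_beta),
            class = "cf_four_params")
}

#' Time derivatives of the four-strain model
#'
#' All four strains share one carrying capacity (total density `n_total`
#' crowds everyone). The tryptophan pool available to X and N is
#' `(Y + D) * w + a`; the leucine pool available to Y and N is
#' `beta * X + D * w_beta + a`. D needs no amino acids (logistic with
#' death); N needs both pools (product of two saturation factors). Setting
#' D = N = 0 recovers [cf_rhs()] on the X, Y components exactly.
#'
#' @param state Numeric length-4 `c(X, Y, D, N)` of densities (>= 0).
#' @param fparams A [four_strain_params()] object.
#' @return Named numeric vector of four derivatives.
#' @export
four_strain_rhs <- function(state, fparams) {
  stopifnot(length(state) == 4L)
  if (any(!is.finite(state)) || any(state < 0))
    stop("densities must be finite and >= 0")
  p <- fparams$base
  X <- state[[1]]; Y <- state[[2]]; D <- state[[3]]; N <- state[[4]]
  n_tot <- X + Y + D + N
  trp <- (Y + D) * fparams$w + p$a
  leu <- p$beta * X + D * fparams$w_beta + p$a
  g_trp <- saturation_factor(trp, p$kappa)
  g_leu <- saturation_factor(leu, p$kappa)
  room <- 1 - n_tot
  c(dX = p$r_x * X * g_trp * room - p$delta * X,
    dY = p$r_y * Y * g_leu * room - p$delta * Y,
    dD = fparams$r_d * D * room - p$delta * D,
    dN = fparams$r_n * N * g_trp * g_leu * room - p$delta * N)
}

.integrate_four <- function(fparams, initial, t_end, dt_out) {
  deriv <- function(t, y, parms) list(unname(four_strain_rhs(pmax(y, 0), fparams)))
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(y = c(X = initial[[1]], Y = initial[[2]],
                            D = initial[[3]], N = initial[[4]]),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  st <- pmax(sol[nrow(sol), c("X", "Y", "D", "N")], 0)
  st[st < 1e-10] <- 0
  st
}

#' Invasion scan of the mutualism by double producers and non-producers
#'
#' For every supplementation level, starts from the X-Y co-culture
#' equilibrium (or a standard co-culture inoculum where none exists),
#' adds small invader inocula of D and N, and integrates to a long horizon.
#' Three zones are expected along `a`: at low supplementation the double
#' producer takes over (the pair cannot sustain itself, D needs no amino
#' acids); at intermediate supplementation the mutualism repels both
#' invaders; at high supplementation the fast-growing non-producer
#' dominates.
#'
#' @param fparams A [four_strain_params()] object.
#' @param a_grid Increasing supplementation grid.
#' @param inoculum Invader starting density (default 1e-4).
#' @param t_end Integration horizon.
#' @return Data frame with columns `a`, final densities `X, Y, D, N`,
#'   `dominant` (largest final density), and per-invader outcomes
#'   `outcome_D`, `outcome_N`: `"established"` (> 10x inoculum),
#'   `"repelled"` (< 0.1x inoculum) or `"unresolved"`.
#' @export
invasion_scan <- function(fparams, a_grid, inoculum = 1e-4, t_end = 2000) {
  stopifnot(!is.unsorted(a_grid, strictly = TRUE), inoculum > 0)
  outcome <- function(dens) {
    if (dens > 10 * inoculum) "established"
    else if (dens < 0.1 * inoculum) "repelled"
    else "unresolved"
  }
  rows <- lapply(a_grid, function(a) {
    p <- fparams$base; p$a <- a
    eq <- stable_interior(p)
    start_xy <- if (!is.null(eq)) eq$state else c(X = 0.1, Y = 0.1)
    fparams$base$a <- a
    fin <- .integrate_four(fparams,
                           c(start_xy[["X"]], start_xy[["Y"]],
                             inoculum, inoculum),
                           t_end, dt_out = t_end / 8)
    data.frame(a = a, X = fin[["X"]], Y = fin[["Y"]],
               D = fin[["D"]], N = fin[["N"]],
               dominant = c("X", "Y", "D", "N")[which.max(fin)],
               outcome_D = outcome(fin[["D"]]),
               outcome_N = outcome(fin[["N"]]))
  })
  do.call(rbind, rows)
}
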