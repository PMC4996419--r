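#' Monod saturation factor
#'
#' The saturating benefit term `s / (s + kappa)`: growth of each auxotroph
#' saturates in the combined level of its partner and the supplemented amino
#' acid. Bounded in \[0, 1), strictly increasing, half-maximal at `s = kappa`.
#'
#' @param s Effective nutrient level (partner density plus supplementation;
#'   >= 0, vectorized).
#' @param kappa Monod constant (> 0).
#' @return Saturation factor(s) in \[0, 1).
#' @examples
#' saturation_factor(0.12, 0.12)  # 0.5 by definition
#' @export
saturation_factor <- function(s, kappa) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
    stop("nutrient level s must be finite and >= 0")
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a positive scalar")
  s / (s + kappa)
}

#' Time derivatives of the two-strain cross-feeding model
#'
#' The deterministic model: each strain grows at a Monod-saturating rate in
#' the pool formed by its partner and the supplemented amino acid, is crowded
#' logistically against the shared carrying capacity (1), and dies at rate
#' `delta`:
#' \deqn{dX/dt = r_x X \frac{Y + a}{Y + a + \kappa} (1 - X - cY) - \delta X}
#' \deqn{dY/dt = r_y Y \frac{\beta X + a}{\beta X + a + \kappa} (1 - cX - Y) - \delta Y}
#' With `c = 1` (the default, complete niche overlap) this is the base
#' two-equation model; `c < 1` weakens the crowding each strain imposes on
#' its partner (the niche-overlap extension). `c` enters only the logistic
#' term, never the cross-feeding pool.
#'
#' @param state Numeric length-2 vector `c(X, Y)` of strain densities (>= 0).
#' @param params A [cf_params()] object.
#' @return Named numeric vector `c(dX, dY)`.
#' @examples
#' cf_rhs(c(X = 0.25, Y = 0.25), cf_params(a = 0.09))
#' @export
cf_rhs <- function(state, params) {
  stopifnot(length(state) == 2L)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state densities must be finite and >= 0")
  X <- state[[1]]; Y <- state[[2]]
  g_x <- saturation_factor(Y + params$a, params$kappa)
  g_y <- saturation_factor(params$beta * X + params$a, params$kappa)
  c(dX = params$r_x * X * g_x * (1 - X - params$c * Y) - params$delta * X,
    dY = params$r_y * Y * g_y * (1 - params$c * X - Y) - params$delta * Y)
}

#' Total density n = X + Y of a population state
#' @param state Numeric length-2 vector `c(X, Y)`.
#' @return Scalar total density.
#' @export
total_density <- function(state) state[[1]] + state[[2]]

#' Strain ratio f = X / Y of a population state
#'
#' Returns `NA_real_` (not +/-Inf) when `Y = 0`; consumers must handle the
#' sentinel.
#'
#' @param state Numeric length-2 vector `c(X, Y)`.
#' @return Scalar ratio, or `NA_real_` when Y is zero.
#' @export
strain_ratio <- function(state) {
  if (state[[2]] == 0) return(NA_real_)
  state[[1]] / state[[2]]
}

#' Closed-form monoculture equilibrium density
#'
#' With the partner absent, a strain's equation reduces to logistic growth
#' with death fed only by the supplemented amino acid; its nonzero root is
#' `1 - delta / (r * a/(a + kappa))`, floored at 0 when supplementation
#' cannot balance dilution.
#'
#' @param params A [cf_params()] object.
#' @param strain `"X"` (Trp-) or `"Y"` (Leu-).
#' @return Equilibrium density >= 0.
#' @examples
#' monoculture_equilibrium(cf_params(a = 0.48), "X")  # 0.375
#' @export
monoculture_equilibrium <- function(params, strain = c("X", "Y")) {
  strain <- match.arg(strain)
  r <- if (strain == "X") params$r_x else params$r_y
  if (params$a == 0) return(if (params$delta > 0) 0 else 1)
  g <- saturation_factor(params$a, params$kappa)
  max(0, 1 - params$delta / (r * g))
}

#' Closed-form monoculture viability threshold in a
#'
#' The supplementation level below which a strain alone cannot survive
#' dilution: `a_crit = delta * kappa / (r - delta)`. The monoculture
#' equilibrium is 0 for `a <= a_crit` and positive above it.
#'
#' @param params A [cf_params()] object.
#' @param strain `"X"` or `"Y"`.
#' @return Critical supplementation level (0 when `delta = 0`).
#' @examples
#' monoculture_viability_threshold(cf_params(), "X")  # 0.12
#' @export
monoculture_viability_threshold <- function(params, strain = c("X", "Y")) {
  strain <- match.arg(strain)
  r <- if (strain == "X") params$r_x else params$r_y
  if (params$delta == 0) return(0)
  if (r <= params$delta)
    stop("no finite viability threshold: maximum growth rate (", r,
         ") does not exceed the death rate (", params$delta,
         "); the monoculture is inviable at any supplementation")
  params$delta * params$kappa / (r - params$delta)
}
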