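#' Relative fitness of the Leu- strain over one growth cycle
#'
#' The odds-ratio fold change of the Leu- fraction over a day:
#' `W = [f1/(1-f1)] / [f0/(1-f0)]`. This form needs only cytometry
#' fractions, is symmetric under strain relabeling (swapping both fractions
#' maps W to 1/W), and equals the ratio of the strains' fold-growths when
#' the two strains share the day's total growth. `log W > 0` means the Leu-
#' strain gained. The formula is a package convention (the originating
#' experiments define relative fitness in supplementary material only).
#'
#' @param f0 Leu- fraction at the start of the day, strictly in (0, 1).
#' @param f1 Leu- fraction at the end of the day, strictly in (0, 1).
#' @return Relative fitness W (vectorized).
#' @examples
#' relative_fitness(0.5, 8 / 18)  # Leu- grew 8x while Trp- grew 10x: W = 0.8
#' @export
relative_fitness <- function(f0, f1) {
  if (any(!is.finite(f0)) || any(!is.finite(f1)) ||
      any(f0 <= 0) || any(f0 >= 1) || any(f1 <= 0) || any(f1 >= 1))
    stop("undefined fitness: fractions must lie strictly in (0, 1)")
  (f1 / (1 - f1)) / (f0 / (1 - f0))
}

#' Per-day fitness records from co-culture plate tracks
#'
#' Builds the (start-of-day Leu- fraction, log relative fitness) pairs used
#' by the bootstrap equilibrium-fraction estimator: the fraction measured at
#' the end of day d-1 is the start fraction of day d (dilution does not
#' change composition). Days with undefined or boundary fractions are
#' dropped. Records from the first `burn_in` days are excluded (cultures
#' are given time to reach carrying capacity so fitness differences reflect
#' composition, not transient growth).
#'
#' @param plate Plate records (see [read_plate()]); only `co` wells are used.
#' @param burn_in Number of initial days to drop (default 2).
#' @return Data frame with columns `well`, `day`, `f_start`, `logW`.
#' @export
day_fitness_records <- function(plate, burn_in = 2) {
  co <- plate[plate$culture_type == "co", , drop = FALSE]
  out <- list()
  for (w in unique(co$well)) {
    tr <- co[co$well == w, , drop = FALSE]
    tr <- tr[order(tr$day), , drop = FALSE]
    for (i in seq_len(nrow(tr) - 1L)) {
      f0 <- tr$fraction_y[i]; f1 <- tr$fraction_y[i + 1L]
      if (tr$day[i + 1L] != tr$day[i] + 1L) next
      if (tr$day[i + 1L] <= burn_in) next
      if (is.na(f0) || is.na(f1) || f0 <= 0 || f0 >= 1 || f1 <= 0 || f1 >= 1)
        next
      out[[length(out) + 1L]] <- data.frame(
        well = w, day = tr$day[i + 1L], f_start = f0,
        logW = log(relative_fitness(f0, f1)))
    }
  }
  if (!length(out))
    return(data.frame(well = character(0), day = integer(0),
                      f_start = numeric(0), logW = numeric(0)))
  do.call(rbind, out)
}

#' Bootstrap estimate of the equilibrium Leu- fraction
#'
#' Fits log relative fitness against the start-of-day Leu- fraction
#' (linear, working on the log scale where fitness
#' ratios compose additively) and solves for the zero crossing — the composition at which
#' both strains have equal fitness. Uncertainty comes from refitting on
#' `n_boot` resamples of the records (with replacement); the interval is
#' the percentile CI.
#'
#' @param records Data frame with columns `f_start` and `logW` (>= 4 rows
#'   spanning both signs of fitted logW).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional RNG seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci` (length 2), `slope`, `n_records`,
#'   `n_boot_ok` (resamples yielding a finite crossing).
#' @export
equilibrium_fraction_bootstrap <- function(records, n_boot = 2000,
                                           seed = NULL, conf = 0.95) {
  if (nrow(records) < 4) stop("need at least 4 fitness records")
  crossing <- function(d) {
    fit <- stats::lm(logW ~ f_start, data = d)
    b <- stats::coef(fit)
    rng <- range(d$f_start)
    pred <- b[1] + b[2] * rng
    if (pred[1] * pred[2] > 0) return(NA_real_)  # no sign change in range
    -b[[1]] / b[[2]]
  }
  est <- crossing(records)
  if (is.na(est)) {
    fit <- stats::lm(logW ~ f_start, data = records)
    sign_all <- if (mean(stats::fitted(fit)) > 0) "Leu- sweeps" else "Trp- sweeps"
    err <- simpleError(paste0("no equilibrium fraction: fitted log fitness ",
                              "does not change sign over the observed ",
                              "fractions (", sign_all, ")"))
    class(err) <- c("cf_no_equilibrium", class(err))
    stop(err)
  }
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(records), replace = TRUE)
    tryCatch(crossing(records[idx, , drop = FALSE]), error = function(e) NA_real_)
  }, numeric(1))
  ok <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- if (length(ok) >= 2) unname(stats::quantile(ok, c(alpha, 1 - alpha)))
        else c(est, est)
  list(estimate = unname(est), ci = ci,
       slope = unname(stats::coef(stats::lm(logW ~ f_start, records))[2]),
       n_records = nrow(records), n_boot_ok = length(ok))
}

#' Detect equilibrium in a single well's day series
#'
#' A track has converged when the relative change of both OD and (for
#' co-cultures) the Leu- fraction over the last `window` days stays below
#' `rel_change_tol`; the equilibrium is then the mean over that window.
#' A track decaying towards the OD floor is flagged extinct.
#'
#' @param track One well's records, columns `day`, `od` and optionally
#'   `fraction_y`, ordered or orderable by day; length >= window + 1.
#' @param window Number of trailing days examined (default 3).
#' @param rel_change_tol Maximum relative day-to-day change (default 0.1).
#' @param od_floor OD level treated as the detection floor.
#' @return List with `converged`, `extinct`, `od` (mean OD over the window,
#'   0 when extinct), `fraction_y` (mean fraction, NA for monocultures or
#'   extinct wells).
#' @export
detect_equilibrium <- function(track, window = 3, rel_change_tol = 0.1,
                               od_floor = 1e-4) {
  track <- track[order(track$day), , drop = FALSE]
  if (nrow(track) < window + 1)
    stop("insufficient data: track has ", nrow(track),
         " days, need at least ", window + 1)
  tail_idx <- (nrow(track) - window):nrow(track)
  od <- track$od[tail_idx]
  if (all(od <= 2 * od_floor))
    return(list(converged = TRUE, extinct = TRUE, od = 0,
                fraction_y = NA_real_))
  rel_od <- abs(diff(od)) / pmax(od[-length(od)], od_floor)
  ok <- all(rel_od < rel_change_tol)
  fr <- if ("fraction_y" %in% names(track)) track$fraction_y[tail_idx] else NULL
  if (!is.null(fr) && !all(is.na(fr))) {
    if (anyNA(fr)) ok <- FALSE
    else {
      rel_fr <- abs(diff(fr)) / pmax(fr[-length(fr)], 1e-3)
      ok <- ok && all(rel_fr < rel_change_tol)
    }
  }
  # monotone ~dilution-factor decay means the well is dying, not equilibrating
  dying <- all(diff(od) < 0) && od[length(od)] < 0.02 * od[1]
  list(converged = ok && !dying, extinct = FALSE,
       od = mean(od), fraction_y = if (is.null(fr)) NA_real_ else mean(fr))
}

#' Estimate the per-day growth-rate disadvantage of the Leu- strain
#'
#' From co-culture fitness records at saturating amino-acid supplementation
#' (where cross-feeding adds nothing and fitness differences reflect the
#' intrinsic rates), estimates `1 - r_y/r_x`. Per record, the log relative
#' fitness over a day at carrying capacity satisfies
#' `logW = -(r_x - r_y) * I` with `I` the integrated open-niche factor;
#' at the growth-dilution balance `log(dilution) = r_mean * I` where
#' `r_mean` is the abundance-weighted mean rate. Solving the pair gives
#' `r_y/r_x = (1 - q fx) / (1 + q (1 - fx))` with `q = -logW / log(dilution)`
#' and `fx` the mean Trp- fraction — a first-order correction for the
#' composition of the culture. The bootstrap CI resamples records.
#'
#' @param records Data frame from [day_fitness_records()] (needs `f_start`
#'   and `logW`; `f_start` is the Leu- fraction).
#' @param dilution_factor Daily dilution of the protocol (default 10).
#' @param n_boot Bootstrap resamples.
#' @param seed Optional RNG seed.
#' @param conf Confidence level.
#' @return List with `estimate` (fractional disadvantage, ~0.075 for the
#'   reference strains), `ci`, `n_records`.
#' @export
estimate_growth_disadvantage <- function(records, dilution_factor = 10,
                                         n_boot = 2000, seed = NULL,
                                         conf = 0.95) {
  if (nrow(records) < 2) stop("need at least 2 fitness records")
  one <- function(d) {
    q <- -mean(d$logW) / log(dilution_factor)
    fx <- mean(1 - d$f_start)  # Trp- fraction
    rho <- (1 - q * fx) / (1 + q * (1 - fx))
    1 - rho
  }
  est <- one(records)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    one(records[sample.int(nrow(records), replace = TRUE), , drop = FALSE]),
    numeric(1))
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_records = nrow(records))
}

#' Classify the interaction regime from plate tracks at one condition
#'
#' The experimental analogue of [classify_regime()]: estimates equilibrium
#' densities of the two monocultures and the co-culture from their day
#' series and applies the same decision table. Co-culture equilibria come
#' from converged tracks directly; tracks that have not converged in
#' composition defer to the bootstrap equilibrium-fraction crossing when
#' enough fitness records exist. The neutrality band is widened by the
#' spread among replicate co-culture wells.
#'
#' @param mono_x_track,mono_y_track Day series (columns `day`, `od`) of the
#'   two monoculture wells at the condition.
#' @param co_tracks Plate records of the co-culture wells at the condition
#'   (columns `well`, `day`, `od`, `fraction_y`).
#' @param rel_tol Base neutrality band (default 0.05: estimated equilibria
#'   are noisier than model equilibria).
#' @param od_per_density OD units per unit density, to put estimates on the
#'   model's density scale.
#' @param window,rel_change_tol Passed to [detect_equilibrium()].
#' @param od_floor OD detection floor.
#' @return A `cf_regime` object (name + effect codes + details).
#' @export
classify_experimental_regime <- function(mono_x_track, mono_y_track,
                                         co_tracks, rel_tol = 0.05,
                                         od_per_density = 1, window = 3,
                                         rel_change_tol = 0.1,
                                         od_floor = 1e-4) {
  ext_tol <- 1e-3  # density floor for "viable" on the estimated scale
  # a monoculture whose OD declines geometrically day over day is on its way
  # out even if it has not yet hit the floor: growth cannot balance the
  # dilution, so its fate is extrapolated to extinction ("estimated based
  # on growth" rather than waiting for the track to bottom out)
  mono_density <- function(track) {
    d <- detect_equilibrium(track, window, rel_change_tol, od_floor)
    if (d$extinct || (!d$converged && d$od < 2 * od_floor)) return(0)
    track <- track[order(track$day), , drop = FALSE]
    tail_od <- utils::tail(track$od, window + 1)
    ratios <- tail_od[-1] / tail_od[-length(tail_od)]
    if (all(diff(tail_od) < 0) && mean(ratios) < 1 - rel_change_tol / 2)
      return(0)
    d$od / od_per_density
  }
  x_mono <- mono_density(mono_x_track)
  y_mono <- mono_density(mono_y_track)

  wells <- unique(co_tracks$well)
  ests <- lapply(wells, function(w) {
    tr <- co_tracks[co_tracks$well == w, , drop = FALSE]
    detect_equilibrium(tr, window, rel_change_tol, od_floor)
  })
  live <- Filter(function(e) !e$extinct, ests)
  conv <- Filter(function(e) e$converged && !is.na(e$fraction_y), live)

  if (!length(live)) {
    co_n <- 0; co_fy <- NA_real_
  } else if (length(conv)) {
    co_n <- mean(vapply(conv, `[[`, 0, "od")) / od_per_density
    co_fy <- mean(vapply(conv, `[[`, 0, "fraction_y"))
  } else {
    # composition not settled: extrapolate via the fitness-crossing estimator
    co_n <- mean(vapply(live, `[[`, 0, "od")) / od_per_density
    rec <- day_fitness_records(
      transform(co_tracks, culture_type = "co"), burn_in = 1)
    co_fy <- tryCatch(
      equilibrium_fraction_bootstrap(rec, n_boot = 200)$estimate,
      error = function(e) NA_real_)
    if (is.na(co_fy)) {
      # no crossing within the observed fractions: a materially one-signed
      # drift is the exclusion evidence (one strain sweeps); a flat drift
      # means the composition is simply already settled
      drift <- if (nrow(rec)) mean(rec$logW) else 0
      co_fy <- if (abs(drift) > 0.05) (if (drift > 0) 1 else 0)
               else mean(vapply(live, `[[`, 0, "fraction_y"), na.rm = TRUE)
    }
  }

  coexists <- co_n > ext_tol && !is.na(co_fy) &&
    co_fy > 0.02 && co_fy < 0.98
  winner <- if (!coexists && co_n > ext_tol && !is.na(co_fy)) {
    if (co_fy <= 0.02) "X" else "Y"
  } else if (!coexists && co_n <= ext_tol) {
    NA_character_
  } else NA_character_
  # an extinct co-culture alongside a viable monoculture cannot happen in
  # the model; report exclusion towards the viable strain in that case
  if (!coexists && is.na(winner) && (x_mono > ext_tol || y_mono > ext_tol))
    winner <- if (x_mono >= y_mono) "X" else "Y"

  x_co <- if (coexists) co_n * (1 - co_fy) else NA_real_
  y_co <- if (coexists) co_n * co_fy else NA_real_
  out <- .regime_from_densities(x_co, y_co, x_mono, y_mono, coexists,
                                winner = winner, rel_tol = rel_tol,
                                ext_tol = ext_tol)
  out$details <- list(x_co = x_co, y_co = y_co, x_mono = x_mono,
                      y_mono = y_mono, co_fraction_y = co_fy)
  out
}
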