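#' Configuration of a synthetic daily-dilution plate experiment
#'
#' Describes the protocol the generator emulates: co-cultures and
#' monocultures grown in wells for `days` growth-dilution cycles with a
#' 10x dilution each day, across a grid of amino-acid conditions with
#' leucine supplied at 8x the tryptophan concentration (so a single
#' tryptophan coordinate labels each condition), measured daily by
#' spectrophotometry (optical density, multiplicative lognormal noise) and
#' flow cytometry (a finite draw of cells classified by strain).
#'
#' Default conditions are 16 concentrations from 0 to 200 uM tryptophan and
#' six starting ratios spanning two orders of magnitude either side of 1:1.
#' The growth period default `t_day = log(10)/0.5 ~ 4.6` time units makes
#' the daily 10x dilution equivalent to the continuous model's death rate
#' delta = 0.5 (so the batch monoculture viability threshold coincides with
#' the closed form exactly) and gives a nutrient-saturated monoculture about
#' 6.6 doublings per day, comfortably above the log2(10) = 3.3 survival
#' minimum.
#'
#' @param days Number of growth-dilution cycles (default 7).
#' @param dilution_factor Daily dilution (default 10).
#' @param conditions Tryptophan concentrations in uM (leucine is 8x).
#' @param n0 Initial total density of every well (normalized units).
#' @param f0 Starting ratios X/Y of the co-culture wells.
#' @param monocultures Also include one mono_x and one mono_y well per
#'   condition (started at the same total density).
#' @param od_noise_sd Lognormal sd of the optical-density reading (0 = none).
#' @param cytometer_sample Cells drawn per cytometry measurement; use `Inf`
#'   for exact fractions (the infinite-sample limit).
#' @param od_per_density OD units per unit model density (1 = one OD at
#'   carrying capacity; an instrument convention).
#' @param od_floor OD reading reported for an extinct well (detection floor).
#' @param t_day Growth period per day in model time units.
#' @param conc_scale uM-to-dimensionless conversion, see [conc_to_a()].
#' @param seed RNG seed; fixed seed gives byte-identical plates.
#' @return An `cf_experiment_config` list.
#' @export
experiment_config <- function(days = 7, dilution_factor = 10,
                              conditions = c(0, 200 / 2^(14:0)),
                              n0 = 0.05,
                              f0 = c(0.01, 0.1, 1 / 3, 3, 10, 100),
                              monocultures = TRUE,
                              od_noise_sd = 0.05, cytometer_sample = 10000,
                              od_per_density = 1, od_floor = 1e-4,
                              t_day = log(10) / 0.5, conc_scale = 0.1, seed = 1) {
  stopifnot(days >= 1, dilution_factor > 1, all(conditions >= 0), n0 > 0,
            all(f0 > 0), od_noise_sd >= 0, cytometer_sample >= 1,
            od_per_density > 0, t_day > 0, conc_scale > 0)
  structure(list(days = as.integer(days), dilution_factor = dilution_factor,
                 conditions = conditions, n0 = n0, f0 = f0,
                 monocultures = monocultures, od_noise_sd = od_noise_sd,
                 cytometer_sample = cytometer_sample,
                 od_per_density = od_per_density, od_floor = od_floor,
                 t_day = t_day, conc_scale = conc_scale, seed = seed),
            class = "cf_experiment_config")
}

# stable short hash of a config (no external digest dependency)
.config_hash <- function(config) {
  s <- paste(vapply(unclass(config), function(x)
    paste(format(x, digits = 15), collapse = ","), ""), collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate a daily-dilution plate experiment
#'
#' Runs every well (monocultures and co-cultures at all conditions and
#' starting ratios) through `days` iterations of the deterministic batch
#' growth-dilution map, then overlays the measurement process: OD with
#' multiplicative lognormal noise, and strain fractions from a binomial
#' cytometer draw of `cytometer_sample` cells. Wells that have gone extinct
#' (density below 1e-6) report the OD floor and an undefined (NA) fraction —
#' never a divide-by-zero. The full noise-free densities are attached as
#' attribute `"truth"` for parameter-recovery studies.
#'
#' @param config An [experiment_config()].
#' @param params A [cf_params()] object; its `a` is overridden per condition
#'   via [conc_to_a()], and its `delta` is ignored within the day (dilution
#'   is the death process).
#' @return Data frame of plate records with columns
#'   `well, day, trp_uM, culture_type, od, cells_x, cells_y, fraction_y`
#'   (days 1..days; `culture_type` one of mono_x, mono_y, co).
#' @examples
#' cfg <- experiment_config(days = 3, conditions = c(1, 32), f0 = 1,
#'                          cytometer_sample = 1000, seed = 7)
#' plate <- simulate_plate(cfg, cf_params())
#' @export
simulate_plate <- function(config, params) {
  stopifnot(inherits(config, "cf_experiment_config"))
  params <- validate_params(params)
  set.seed(config$seed)
  ext_tol <- 1e-6

  wells <- list()
  for (trp in config$conditions) {
    if (config$monocultures) {
      wells[[length(wells) + 1L]] <- list(trp = trp, type = "mono_x",
                                          init = c(config$n0, 0))
      wells[[length(wells) + 1L]] <- list(trp = trp, type = "mono_y",
                                          init = c(0, config$n0))
    }
    for (f in config$f0)
      wells[[length(wells) + 1L]] <- list(trp = trp, type = "co",
        init = c(config$n0 * f / (1 + f), config$n0 / (1 + f)))
  }

  rec <- vector("list", length(wells))
  truth <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    p <- params
    p$a <- conc_to_a(w$trp, config$conc_scale)
    track <- iterate_dilution(p, w$init, config$days,
                              config$dilution_factor, config$t_day)
    track <- track[track$day >= 1L, , drop = FALSE]  # measured days only
    nd <- nrow(track)
    wid <- sprintf("w%03d", i)
    od <- numeric(nd); cx <- cy <- rep(NA_real_, nd); fy <- rep(NA_real_, nd)
    for (d in seq_len(nd)) {
      n_end <- track$n[d]
      noise <- if (config$od_noise_sd > 0)
        exp(stats::rnorm(1, 0, config$od_noise_sd)) else 1
      if (n_end < ext_tol) {
        od[d] <- config$od_floor * noise
      } else {
        od[d] <- n_end * config$od_per_density * noise
        if (w$type == "co") {
          p_y <- track$Y[d] / n_end
          if (is.finite(config$cytometer_sample)) {
            cy[d] <- stats::rbinom(1, config$cytometer_sample, p_y)
            cx[d] <- config$cytometer_sample - cy[d]
            fy[d] <- cy[d] / config$cytometer_sample
          } else {
            fy[d] <- p_y
          }
        }
      }
    }
    rec[[i]] <- data.frame(well = wid, day = track$day, trp_uM = w$trp,
                           culture_type = w$type, od = od,
                           cells_x = cx, cells_y = cy, fraction_y = fy)
    truth[[i]] <- data.frame(well = wid, day = track$day, trp_uM = w$trp,
                             culture_type = w$type,
                             X = track$X, Y = track$Y)
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "config_hash") <- .config_hash(config)
  attr(out, "seed") <- config$seed
  out
}

.plate_cols <- c("well", "day", "trp_uM", "culture_type", "od",
                 "cells_x", "cells_y", "fraction_y")

#' Write a plate-record table to CSV
#'
#' Tidy CSV with a one-line header comment carrying the config hash and
#' seed; numeric fields are written at full precision so
#' `read_plate(write_plate(x))` round-trips bit-exactly. Undefined
#' fractions (extinct wells) are written as empty fields.
#'
#' @param plate Plate records from [simulate_plate()] (or the same schema).
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  miss <- setdiff(.plate_cols, names(plate))
  if (length(miss)) stop("plate table missing column(s): ",
                         paste(miss, collapse = ", "))
  hdr <- sprintf("# crossfeedr-plate config_hash=%s seed=%s",
                 attr(plate, "config_hash") %||% "NA",
                 format(attr(plate, "seed") %||% NA))
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.17g", x)) else as.character(x)
  }
  body <- do.call(paste, c(lapply(plate[.plate_cols], fmt), sep = ","))
  writeLines(c(hdr, paste(.plate_cols, collapse = ","), body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a plate-record table from CSV
#'
#' Validates the schema and the record invariants (fractions in \[0, 1\],
#' cytometer counts consistent with the fraction); violations raise a parse
#' error naming the offending column.
#'
#' @param path CSV written by [write_plate()] (or hand-built in the same
#'   schema).
#' @return Plate-record data frame.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("no such plate file: ", path)
  out <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(well = "character", day = "integer",
                                        trp_uM = "numeric",
                                        culture_type = "character",
                                        od = "numeric", cells_x = "numeric",
                                        cells_y = "numeric",
                                        fraction_y = "numeric"))
  miss <- setdiff(.plate_cols, names(out))
  if (length(miss)) stop("parse error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (any(!is.na(out$fraction_y) & (out$fraction_y < 0 | out$fraction_y > 1)))
    stop("parse error in column fraction_y: values outside [0, 1]")
  if (any(!is.na(out$od) & out$od < 0))
    stop("parse error in column od: negative optical density")
  both <- !is.na(out$cells_x) & !is.na(out$cells_y) & !is.na(out$fraction_y)
  if (any(both & abs(out$cells_y / (out$cells_x + out$cells_y) -
                     out$fraction_y) > 1e-12))
    stop("parse error in column cells_y: counts inconsistent with fraction_y")
  if (!all(out$culture_type %in% c("mono_x", "mono_y", "co")))
    stop("parse error in column culture_type: unknown level")
  out
}
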