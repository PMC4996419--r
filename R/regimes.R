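#' Canonical ordering of the qualitative interaction regimes
#'
#' The eight possible outcomes of the pair, in the order they are traversed
#' as amino-acid supplementation increases. Amensalism sits on the boundary
#' between parasitism and competition and is only reportable because the
#' classifier uses a finite neutrality band; generic 1-D scans therefore
#' return seven of the eight labels.
#'
#' @return Character vector of the eight regime names in canonical order.
#' @export
regime_order <- function() {
  c("collapse_extinction", "obligatory_mutualism", "obligatory_facultative",
    "facultative_mutualism", "parasitism", "amensalism", "competition",
    "competitive_exclusion")
}

# Is `x` a subsequence of `full` (order preserved, gaps allowed)?
.is_subsequence <- function(x, full) {
  pos <- match(x, full)
  !anyNA(pos) && !is.unsorted(pos, strictly = TRUE)
}

# Shared decision table: compare co-culture and monoculture equilibria.
# Used both for model equilibria and for plate-estimated equilibria.
# coexists: a stable attractor with both strains present exists.
# winner: which strain the stable attractor retains when coexists is FALSE
#         and at least one monoculture is viable ("X" or "Y").
.regime_from_densities <- function(x_co, y_co, x_mono, y_mono, coexists,
                                   winner = NA_character_, rel_tol = 0.01,
                                   ext_tol = 1e-6) {
  lab <- function(name, ex, ey)
    structure(list(name = name, effect_x = ex, effect_y = ey),
              class = "cf_regime")
  x_viable <- x_mono > ext_tol
  y_viable <- y_mono > ext_tol
  if (!coexists) {
    if (!x_viable && !y_viable) return(lab("collapse_extinction", "X", "X"))
    if (is.na(winner))
      stop("exclusion outcome but no winning strain identified")
    if (winner == "X") return(lab("competitive_exclusion", "0", "X"))
    return(lab("competitive_exclusion", "X", "0"))
  }
  if (!x_viable && !y_viable) return(lab("obligatory_mutualism", "+", "+"))
  if (xor(x_viable, y_viable)) return(lab("obligatory_facultative", "+", "+"))
  band_sign <- function(co, mono) {
    if (co > mono * (1 + rel_tol)) "+"
    else if (co < mono * (1 - rel_tol)) "-"
    else "0"
  }
  sx <- band_sign(x_co, x_mono)
  sy <- band_sign(y_co, y_mono)
  # amensalism requires one strictly harmed partner; any other neutral call
  # is a band artefact and is re-resolved by the raw sign of the difference
  if (sx == "0" && sy != "-") sx <- if (x_co >= x_mono) "+" else "-"
  if (sy == "0" && sx != "-") sy <- if (y_co >= y_mono) "+" else "-"
  key <- paste0(sx, sy)
  switch(key,
         "++" = lab("facultative_mutualism", "+", "+"),
         "--" = lab("competition", "-", "-"),
         "+-" = ,
         "-+" = lab("parasitism", sx, sy),
         "0-" = ,
         "-0" = lab("amensalism", sx, sy),
         stop("unreachable sign pair: ", key))
}

#' Classify the qualitative interaction regime at a parameter set
#'
#' Compares the stable co-culture attractor against the two monoculture
#' equilibria and assigns one of the eight regime labels with per-strain
#' effect codes: `+` benefit, `-` harm, `0` neutral (within `rel_tol`),
#' `X` extinction. When both an interior attractor and a stable axis
#' attractor exist, the interior one defines the label and the bistability
#' is recorded in the `details`. Conflicting stable interior attractors
#' raise an ambiguity error carrying all candidate labels.
#'
#' @param params A [cf_params()] object.
#' @param rel_tol Relative neutrality band (in (0, 0.2)); default 0.01, i.e.
#'   densities within 1% of the monoculture count as unaffected. Amensalism
#'   is a measure-zero boundary and is only reportable thanks to this band.
#' @param ext_tol Absolute density below which an attractor counts as
#'   extinct (normalized scale).
#' @return A `cf_regime` object: `name`, `effect_x`, `effect_y`, plus a
#'   `details` list with the densities used.
#' @examples
#' classify_regime(cf_params(a = 0.09))$name  # obligatory mutualism
#' @export
classify_regime <- function(params, rel_tol = 0.01, ext_tol = 1e-6) {
  params <- validate_params(params)
  if (rel_tol <= 0 || rel_tol >= 0.2) stop("rel_tol must lie in (0, 0.2)")
  eqs <- find_equilibria(params)
  interiors <- Filter(function(e) e$kind == "interior" && e$stable &&
                        e$state[["X"]] > ext_tol && e$state[["Y"]] > ext_tol,
                      eqs)
  axes <- Filter(function(e) e$kind %in% c("X-axis", "Y-axis") && e$stable, eqs)
  x_mono <- monoculture_equilibrium(params, "X")
  y_mono <- monoculture_equilibrium(params, "Y")

  if (length(interiors) > 1L) {
    cand <- lapply(interiors, function(e)
      .regime_from_densities(e$state[["X"]], e$state[["Y"]], x_mono, y_mono,
                             TRUE, rel_tol = rel_tol, ext_tol = ext_tol))
    names_ <- vapply(cand, function(r) r$name, "")
    if (length(unique(names_)) > 1L) {
      err <- simpleError(paste0("ambiguous regime: conflicting stable ",
                                "attractors label as ",
                                paste(unique(names_), collapse = ", ")))
      err$candidates <- cand
      class(err) <- c("cf_ambiguity", class(err))
      stop(err)
    }
    interiors <- interiors[1]
  }

  if (length(interiors) == 1L) {
    e <- interiors[[1]]
    out <- .regime_from_densities(e$state[["X"]], e$state[["Y"]],
                                  x_mono, y_mono, TRUE,
                                  rel_tol = rel_tol, ext_tol = ext_tol)
  } else {
    if (length(axes) == 2L) {
      err <- simpleError("ambiguous regime: both axis attractors are stable")
      class(err) <- c("cf_ambiguity", class(err))
      stop(err)
    }
    winner <- if (length(axes) == 1L) {
      if (axes[[1]]$kind == "X-axis") "X" else "Y"
    } else if (x_mono > ext_tol || y_mono > ext_tol) {
      # no stable axis point yet a viable mono: fall back to the viable strain
      if (x_mono >= y_mono) "X" else "Y"
    } else NA_character_
    out <- .regime_from_densities(NA_real_, NA_real_, x_mono, y_mono, FALSE,
                                  winner = winner, rel_tol = rel_tol,
                                  ext_tol = ext_tol)
  }
  out$details <- list(
    a = params$a,
    x_co = if (length(interiors)) interiors[[1]]$state[["X"]] else NA_real_,
    y_co = if (length(interiors)) interiors[[1]]$state[["Y"]] else NA_real_,
    x_mono = x_mono, y_mono = y_mono,
    bistable = length(interiors) == 1L && length(axes) > 0L)
  out
}

#' @export
print.cf_regime <- function(x, ...) {
  cat(sprintf("regime: %s (Trp- effect %s, Leu- effect %s)\n",
              x$name, x$effect_x, x$effect_y))
  invisible(x)
}

#' Scan the regime label along a grid of supplementation levels
#'
#' Classifies every grid point and merges adjacent identical labels into
#' intervals, giving the ordered regime sequence. Per-point ambiguity errors
#' are downgraded to an `"ambiguous"` annotation, never a failure. On the
#' default parameterization over (0, 1] the scan returns seven distinct labels
#' (all of [regime_order()] except the measure-zero amensalism boundary).
#'
#' @param params A [cf_params()] object (its `a` is scanned over).
#' @param a_grid Increasing grid of supplementation levels.
#' @param rel_tol Neutrality band, see [classify_regime()].
#' @return Data frame with columns `a_lo`, `a_hi`, `label`, `effect_x`,
#'   `effect_y` (one row per merged interval); the full per-point labels are
#'   attached as attribute `"per_a"`.
#' @export
regime_scan <- function(params, a_grid, rel_tol = 0.01) {
  stopifnot(!is.unsorted(a_grid, strictly = TRUE))
  labs <- character(length(a_grid))
  ex <- ey <- character(length(a_grid))
  for (i in seq_along(a_grid)) {
    params$a <- a_grid[i]
    r <- tryCatch(classify_regime(params, rel_tol),
                  cf_ambiguity = function(e) NULL)
    if (is.null(r)) {
      labs[i] <- "ambiguous"; ex[i] <- ey[i] <- NA_character_
    } else {
      labs[i] <- r$name; ex[i] <- r$effect_x; ey[i] <- r$effect_y
    }
  }
  per_a <- data.frame(a = a_grid, label = labs, effect_x = ex, effect_y = ey)
  runs <- rle(labs)
  hi <- cumsum(runs$lengths)
  lo <- hi - runs$lengths + 1L
  out <- data.frame(a_lo = a_grid[lo], a_hi = a_grid[hi], label = runs$values,
                    effect_x = ex[lo], effect_y = ey[lo])
  attr(out, "per_a") <- per_a
  out
}

#' Ordered sequence of distinct regimes from a scan
#'
#' Collapses a [regime_scan()] result to the ordered sequence of distinct
#' regime labels. Amensalism is, by the model's construction, a measure-zero
#' boundary (one strain exactly unaffected); the classifier reports it
#' inside a band of width ~`rel_tol` around two boundaries (the
#' parasitism/competition crossing and the transcritical approach to
#' exclusion, where the surviving strain's co-culture density converges to
#' its monoculture value). By default those boundary bands are attributed
#' to their neighbouring boundary and excluded from the sequence, which is
#' how the seven broad regimes of the default parameterization are counted.
#'
#' @param scan Result of [regime_scan()].
#' @param include_boundary Keep amensalism boundary-band intervals in the
#'   sequence (default FALSE).
#' @return Character vector of distinct labels in scan order.
#' @export
regime_sequence <- function(scan, include_boundary = FALSE) {
  labs <- scan$label
  if (!include_boundary) labs <- labs[labs != "amensalism"]
  labs <- labs[labs != "ambiguous"]
  rle(labs)$values
}

#' Two-dimensional regime map over a and a second parameter
#'
#' Labels every cell of an (a, second parameter) grid; the second axis is
#' either the niche-overlap coefficient `c` or the death rate `delta`.
#' Along every row (fixed second parameter) the label order is expected to
#' be a subsequence of the canonical regime order.
#'
#' @param base_params A [cf_params()] object providing all other parameters.
#' @param a_grid Increasing grid of supplementation levels.
#' @param second_values Increasing grid for the second parameter.
#' @param second_param `"c"` or `"delta"`.
#' @param rel_tol Neutrality band, see [classify_regime()].
#' @return Tidy data frame with columns `a`, `second_param` (named `c` or
#'   `delta`), `label`, `effect_x`, `effect_y`.
#' @export
regime_map_2d <- function(base_params, a_grid, second_values,
                          second_param = c("c", "delta"), rel_tol = 0.01) {
  second_param <- match.arg(second_param)
  stopifnot(!is.unsorted(a_grid, strictly = TRUE),
            !is.unsorted(second_values, strictly = TRUE))
  out <- list()
  for (v in second_values) {
    p <- base_params
    p[[if (second_param == "c") "c" else "delta"]] <- v
    sc <- regime_scan(p, a_grid, rel_tol)
    per_a <- attr(sc, "per_a")
    per_a[[second_param]] <- v
    out[[length(out) + 1L]] <- per_a
  }
  res <- do.call(rbind, out)
  res[, c("a", second_param, "label", "effect_x", "effect_y")]
}

#' Export a regime map as tidy CSV plus a JSON colorbar legend
#'
#' @param map Data frame from [regime_map_2d()] or the `"per_a"` attribute of
#'   [regime_scan()].
#' @param csv_path Destination CSV.
#' @param json_path Optional destination for the label-to-effect legend.
#' @return `csv_path`, invisibly.
#' @export
write_regime_map <- function(map, csv_path, json_path = NULL) {
  utils::write.csv(map, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    legend <- list(
      collapse_extinction = c("X", "X"), obligatory_mutualism = c("+", "+"),
      obligatory_facultative = c("+", "+"), facultative_mutualism = c("+", "+"),
      parasitism = c("-", "+"), amensalism = c("-", "0"),
      competition = c("-", "-"), competitive_exclusion = c("0", "X"))
    jsonlite::write_json(legend, json_path)
  }
  invisible(csv_path)
}
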