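#' Model parameters for the two-strain cross-feeding model
#'
#' Bundles the rate and saturation constants of the saturating-growth model of
#' the Trp- (X) / Leu- (Y) cross-feeding pair, together with the two extension
#' knobs: the amino-acid supplementation level `a` and the niche-overlap
#' coefficient `c`.
#'
#' The defaults are the standard parameterization of the engineered yeast pair: the
#' faster Trp- strain defines the time unit (`r_x = 1`), the Leu- strain has a
#' ~7.5% growth-rate disadvantage (`r_y = 0.925`), both Monod terms share
#' `kappa = 0.12`, the Trp- strain contributes twice the benefit (`beta = 2`),
#' and daily 10x dilution is folded into a continuous death rate
#' `delta = 0.5`. Densities are normalized so the shared carrying capacity
#' is 1. `c = 1` (complete niche overlap) recovers the two-equation model
#' exactly; `c < 1` weakens each strain's crowding effect on its partner.
#'
#' @param r_x Maximum growth rate of the Trp- strain (per unit time; > 0).
#' @param r_y Maximum growth rate of the Leu- strain (> 0).
#' @param kappa Effective Monod constant (> 0, dimensionless units).
#' @param beta Asymmetry of the benefit X provides to Y (> 0).
#' @param delta Death/dilution rate (>= 0).
#' @param a Supplemented amino-acid level (>= 0, dimensionless).
#' @param c Niche-overlap coefficient in \[0, 1\]; 1 = complete overlap.
#' @return An object of class `cf_params` (a validated named list).
#' @examples
#' p <- cf_params()            # standard defaults
#' p2 <- cf_params(a = 0.23)   # competition regime
#' @export
cf_params <- function(r_x = 1, r_y = 0.925, kappa = 0.12, beta = 2,
                      delta = 0.5, a = 0, c = 1) {
  p <- structure(list(r_x = r_x, r_y = r_y, kappa = kappa, beta = beta,
                      delta = delta, a = a, c = c),
                 class = "cf_params")
  validate_params(p)
}

#' Validate a cf_params object
#'
#' @param p A `cf_params` object or bare named list with the same fields.
#' @return The validated object (invisibly usable in pipelines).
#' @export
validate_params <- function(p) {
  fields <- c("r_x", "r_y", "kappa", "beta", "delta", "a", "c")
  if (!all(fields %in% names(p)))
    stop("missing parameter field(s): ",
         paste(setdiff(fields, names(p)), collapse = ", "))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in fields)
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar")
  if (p$r_x <= 0 || p$r_y <= 0) stop("growth rates r_x, r_y must be > 0")
  if (p$kappa <= 0) stop("kappa must be > 0")
  if (p$beta <= 0) stop("beta must be > 0")
  if (p$delta < 0) stop("delta must be >= 0")
  if (p$a < 0) stop("a must be >= 0")
  if (p$c < 0 || p$c > 1) stop("c must lie in [0, 1]")
  if (!inherits(p, "cf_params")) class(p) <- "cf_params"
  p
}

#' @export
print.cf_params <- function(x, ...) {
  cat("Cross-feeding model parameters:\n")
  cat(sprintf("  r_x=%g r_y=%g kappa=%g beta=%g delta=%g a=%g c=%g\n",
              x$r_x, x$r_y, x$kappa, x$beta, x$delta, x$a, x$c))
  invisible(x)
}

#' Read model parameters from a YAML or JSON config file
#'
#' Flat key-value file with keys `r_x, r_y, kappa, beta, delta, a, c`
#' (all optional, defaults fill the rest). Unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A `cf_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("r_x", "r_y", "kappa", "beta", "delta", "a", "c")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(cf_params, vals)
}

#' Write model parameters to a YAML or JSON config file
#'
#' @param p A `cf_params` object.
#' @param path Destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  p <- validate_params(p)
  vals <- unclass(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Map a tryptophan concentration to the dimensionless supplementation level
#'
#' The experiments supplement tryptophan and leucine at a fixed 1:8 ratio, so
#' a single coordinate describes the condition; the model folds it into the
#' dimensionless level `a`. The mapping is linear and configurable. The
#' default scale 0.1 per uM tryptophan is a package convention chosen so the
#' experimental obligate-mutualism condition (1 uM tryptophan, 8 uM leucine)
#' lands near the model's obligate window (a ~ 0.1); no numeric
#' correspondence is fixed by the experimental design.
#'
#' @param trp_uM Tryptophan concentration in uM (>= 0, vectorized). The
#'   caller guarantees leucine was supplied at 8x this value.
#' @param scale Conversion factor, dimensionless `a` per uM tryptophan.
#' @return Dimensionless `a`, same length as `trp_uM`.
#' @examples
#' conc_to_a(c(0, 1, 8))
#' @export
conc_to_a <- function(trp_uM, scale = 0.1) {
  if (!is.numeric(trp_uM) || any(!is.finite(trp_uM)) || any(trp_uM < 0))
    stop("trp_uM must be finite and >= 0")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  scale * trp_uM
}
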