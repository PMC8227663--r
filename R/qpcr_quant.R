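# qPCR absolute quantification: standard-curve fitting (ordinary least
# squares of Ct on log10 CFU), amplification efficiency from the slope,
# Ct-to-CFU inversion with per-gram conversion, and comparison against
# culture plate counts.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 CFU over a dilution series.  The
#' linear range is the span of input levels; efficiency follows
#' E(%) = (10^(-1/slope) - 1) * 100.
#'
#' @param points data.frame with columns `log10_cfu` and `ct` (a
#'   [simulate_qpcr()] table works directly), or a two-column matrix
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct` (1 decimal), `linear_range`, `n_points`
#' @export
fit_standard_curve <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (!all(c("log10_cfu", "ct") %in% names(points))) {
    if (ncol(points) >= 2L) names(points)[1:2] <- c("log10_cfu", "ct")
    else stop("points must carry log10_cfu and ct columns", call. = FALSE)
  }
  lg <- points$log10_cfu
  ct <- points$ct
  if (any(!is.finite(lg)) || any(!is.finite(ct)))
    stop("non-finite calibration values", call. = FALSE)
  if (length(unique(lg)) < 3L)
    stop("need at least 3 distinct log10 CFU levels", call. = FALSE)
  fit <- lm(ct ~ lg)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (slope >= 0)
    stop("fitted slope is non-negative: no amplification relationship",
         call. = FALSE)
  r2 <- suppressWarnings(stats::cor(lg, ct)^2)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency_pct = efficiency(slope),
                 linear_range = range(lg), n_points = length(lg)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f lgCFU + %.3f | R2 = %.4f | E = %.1f%% | range 10^%g-10^%g\n",
    x$slope, x$intercept, x$r_squared, x$efficiency_pct,
    x$linear_range[1L], x$linear_range[2L]))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' E(%) = (10^(-1/slope) - 1) * 100, reported to one decimal.  A slope of
#' -3.3219 (i.e. -1/log10(2)) corresponds to perfect per-cycle doubling,
#' 100%.
#'
#' @param slope Ct change per log10 CFU; must be negative
#' @param digits decimals to round to (NULL for unrounded)
#' @return efficiency in percent
#' @export
efficiency <- function(slope, digits = 1L) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("slope must be negative", call. = FALSE)
  e <- (10^(-1 / slope) - 1) * 100
  if (is.null(digits)) e else round(e, digits)
}

#' Predicted Ct for a known abundance
#'
#' @param log10_cfu log10 CFU per reaction
#' @param curve a [fit_standard_curve()] result
#' @return Ct value(s)
#' @export
predict_ct <- function(log10_cfu, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$slope * log10_cfu + curve$intercept
}

#' Conversion factors from per-reaction CFU to CFU per gram
#'
#' The published protocol does not state its conversion; these factors are
#' explicit inputs with defaults reflecting a typical fecal DNA workflow
#' (100 uL elution, 2 uL template per reaction, 0.1 g feces, no extra
#' dilution) and are recorded in every report.
#'
#' @param elution_uL DNA elution volume (uL)
#' @param template_uL template volume per reaction (uL)
#' @param mass_g sample mass extracted (g)
#' @param dilution extra dilution factor applied to the template
#' @return list of class `quant_factors`
#' @export
quant_factors <- function(elution_uL = 100, template_uL = 2, mass_g = 0.1,
                          dilution = 1) {
  stopifnot(elution_uL > 0, template_uL > 0, mass_g > 0, dilution > 0)
  structure(list(elution_uL = elution_uL, template_uL = template_uL,
                 mass_g = mass_g, dilution = dilution),
            class = "quant_factors")
}

#' Absolute quantification of a sample from its Ct
#'
#' Inverts the standard curve: CFU per reaction = 10^((ct - intercept) /
#' slope); CFU per gram scales by (elution / template) * dilution / mass.
#' Samples whose implied log10 CFU falls outside the curve's linear range
#' are flagged.
#'
#' @param ct observed Ct value(s)
#' @param curve a [fit_standard_curve()] result
#' @param factors a [quant_factors()]
#' @param sample_id optional sample label(s)
#' @return data.frame with `sample_id`, `ct`, `log10_cfu`,
#'   `cfu_per_reaction`, `cfu_per_gram`, `in_linear_range`
#' @export
quantify <- function(ct, curve, factors = quant_factors(),
                     sample_id = NULL) {
  stopifnot(inherits(curve, "standard_curve"),
            inherits(factors, "quant_factors"))
  if (any(!is.finite(ct)))
    stop("non-finite Ct value", call. = FALSE)
  lg <- (ct - curve$intercept) / curve$slope
  per_rx <- 10^lg
  per_g <- per_rx * (factors$elution_uL / factors$template_uL) *
    factors$dilution / factors$mass_g
  data.frame(
    sample_id = sample_id %||% sprintf("sample_%d", seq_along(ct)),
    ct = ct, log10_cfu = lg, cfu_per_reaction = per_rx,
    cfu_per_gram = per_g,
    in_linear_range = lg >= curve$linear_range[1L] &
      lg <= curve$linear_range[2L],
    stringsAsFactors = FALSE)
}

#' Compare qPCR quantification with culture plate counts
#'
#' Per-sample log10(qPCR / plate) ratios with a mean/sd summary; a mean of
#' 1.0 corresponds to plate counts tenfold below the qPCR estimate.
#'
#' @param qpcr [quantify()] output (needs `sample_id`, `cfu_per_gram`)
#' @param plate data.frame with columns `sample_id` and `cfu_per_gram`
#' @return list with `table` (per-sample ratios) and `summary` (mean, sd)
#' @export
compare_with_culture <- function(qpcr, plate) {
  stopifnot(is.data.frame(qpcr), is.data.frame(plate))
  missing_q <- setdiff(qpcr$sample_id, plate$sample_id)
  missing_p <- setdiff(plate$sample_id, qpcr$sample_id)
  if (length(missing_q) || length(missing_p))
    stop("unmatched sample ids: ",
         paste(c(missing_q, missing_p), collapse = ", "), call. = FALSE)
  m <- match(qpcr$sample_id, plate$sample_id)
  ratio <- log10(qpcr$cfu_per_gram / plate$cfu_per_gram[m])
  tab <- data.frame(sample_id = qpcr$sample_id,
                    qpcr_cfu_per_gram = qpcr$cfu_per_gram,
                    plate_cfu_per_gram = plate$cfu_per_gram[m],
                    log10_ratio = ratio, stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(mean_log10_ratio = mean(ratio),
                   sd_log10_ratio = if (length(ratio) > 1L) sd(ratio)
                   else NA_real_))
}
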