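#' Pearson correlation with coefficient of determination and p-value
#'
#' Product-moment correlation of two numeric vectors with the two-sided
#' p-value from the t transform (as used for the panel's
#' aggregation-expression and chaperone-binding scatterplots).
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return Object of class `fbp_cor`: list with `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(3, 2, 1))
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(r = r, r_squared = r^2, p_value = ct$p.value,
                 n = length(x)), class = "fbp_cor")
}

#' @export
print.fbp_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (R^2 = %.4f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Chaperone-binding correlations with aggregation
#'
#' Pearson correlations of HSP70 and HSP90 binding ratios against the
#' percentage of cells with aggregates, over a phenotype panel.
#'
#' @param panel data.frame with columns `aggregation_pct`, `hsp70_ratio`,
#'   `hsp90_ratio` (e.g. [fbp1_panel()]).
#' @return Named list of `fbp_cor` objects: `hsp70`, `hsp90`.
#' @export
hsp_correlations <- function(panel) {
  stopifnot(all(c("aggregation_pct", "hsp70_ratio", "hsp90_ratio") %in% names(panel)))
  list(hsp70 = pearson_cor(panel$hsp70_ratio, panel$aggregation_pct),
       hsp90 = pearson_cor(panel$hsp90_ratio, panel$aggregation_pct))
}

#' FBPase specific activity from an NADP-coupled absorbance series
#'
#' The spectrophotometric assay couples fructose-1,6-bisphosphate
#' hydrolysis to NADPH formation, read as absorbance at 340 nm. The
#' activity is the least-squares slope of A340 against time converted by
#' Beer-Lambert to a molar rate, scaled by the reaction volume and
#' normalized to the protein mass:
#' `slope / (epsilon * path) * volume / protein * 1000` in mmol/min/mg.
#' Defaults follow the assay set-up (300 uL mixture, 40 ug protein, 1 cm
#' path, epsilon(NADPH, 340 nm) = 6220 / M / cm). A negative fitted slope
#' is reported as zero activity with a `clipped` flag and a warning.
#'
#' @param time_min time points in minutes (>= 2, strictly increasing).
#' @param a340 absorbance readings at 340 nm, same length.
#' @param path_cm optical path length in cm.
#' @param volume_l reaction volume in litres.
#' @param protein_mg protein mass in mg.
#' @param epsilon molar extinction coefficient of NADPH at 340 nm
#'   (1/M/cm).
#' @return List with `activity` (mmol/min/mg protein), `slope` (A340/min),
#'   and `clipped` flag.
#' @export
#' @examples
#' fbpase_activity(0:5, 0.1 + 0.0622 * (0:5))
fbpase_activity <- function(time_min, a340, path_cm = 1, volume_l = 300e-6,
                            protein_mg = 0.040, epsilon = 6220) {
  stopifnot(length(time_min) == length(a340), length(time_min) >= 2L,
            all(diff(time_min) > 0),
            path_cm > 0, volume_l > 0, protein_mg > 0, epsilon > 0)
  slope <- unname(coef(stats::lm(a340 ~ time_min))[2])
  clipped <- FALSE
  if (slope < 0) {
    warning("negative fitted slope; activity reported as 0")
    slope_eff <- 0
    clipped <- TRUE
  } else slope_eff <- slope
  # A/min -> mol/L/min -> mol/min -> mmol/min -> per mg
  activity <- slope_eff / (epsilon * path_cm) * volume_l * 1000 / protein_mg
  list(activity = activity, slope = slope, clipped = clipped)
}
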