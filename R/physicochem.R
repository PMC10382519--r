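#' Kyte-Doolittle hydropathy index of an amino acid
#'
#' @param aa one-letter code of a standard amino acid (vectorised).
#' @param scale hydropathy/class table as returned by [kd_scale()]; injectable
#'   for sensitivity analysis with alternative scales.
#' @return Numeric hydropathy index (dimensionless).
#' @export
#' @examples
#' hydropathy("D")  # -3.5
#' hydropathy("V")  #  4.2
hydropathy <- function(aa, scale = kd_scale()) {
  idx <- match(toupper(aa), scale$aa)
  if (anyNA(idx)) stop("unknown amino acid code: ", paste(aa[is.na(idx)], collapse = ", "))
  scale$hydropathy[idx]
}

#' Amino-acid class label
#'
#' Five-way classification used throughout the analysis:
#' hydrophobic-aliphatic, hydrophobic-aromatic, hydrophilic-acidic,
#' hydrophilic-basic, hydrophilic-neutral.
#'
#' @inheritParams hydropathy
#' @return Character class label.
#' @export
aa_class <- function(aa, scale = kd_scale()) {
  idx <- match(toupper(aa), scale$aa)
  if (anyNA(idx)) stop("unknown amino acid code: ", paste(aa[is.na(idx)], collapse = ", "))
  scale$class[idx]
}

#' Hydrophobicity-change predicate for an amino-acid substitution
#'
#' A substitution "changes hydrophobicity" when either (a) it flips the
#' hydrophobic/hydrophilic polarity of the residue class (e.g. G -> D), or
#' (b) the absolute Kyte-Doolittle index shift is at least `theta` even
#' within one polarity (the G294V case: glycine -0.4 to valine 4.2). The
#' default theta = 3.0 is the smallest round value that captures the G/V
#' shift (|delta| = 4.6) while leaving V325A (|delta| = 2.4) unchanged.
#'
#' @param wt,mut one-letter codes of the wild-type and mutant residues.
#' @param theta non-negative index-shift threshold for within-polarity
#'   changes.
#' @inheritParams hydropathy
#' @return An object of class `fbp_hydropathy_change`: list with fields
#'   `wt`, `mut`, `wt_index`, `mut_index`, `delta` (mut - wt), `wt_class`,
#'   `mut_class`, `polarity_flip`, `is_change`.
#' @export
#' @examples
#' hydropathy_change("G", "D")  # polarity flip
#' hydropathy_change("G", "V")  # large shift among hydrophobics
hydropathy_change <- function(wt, mut, theta = 3.0, scale = kd_scale()) {
  stopifnot(length(wt) == 1L, length(mut) == 1L, theta >= 0)
  wt_index  <- hydropathy(wt, scale)
  mut_index <- hydropathy(mut, scale)
  wt_class  <- aa_class(wt, scale)
  mut_class <- aa_class(mut, scale)
  polarity <- function(cl) sub("-.*$", "", cl)
  flip <- polarity(wt_class) != polarity(mut_class)
  delta <- mut_index - wt_index
  structure(list(
    wt = toupper(wt), mut = toupper(mut),
    wt_index = wt_index, mut_index = mut_index, delta = delta,
    wt_class = wt_class, mut_class = mut_class,
    polarity_flip = flip,
    is_change = flip || abs(delta) >= theta
  ), class = "fbp_hydropathy_change")
}

#' @export
print.fbp_hydropathy_change <- function(x, ...) {
  cat(sprintf("%s (%s, %.1f) -> %s (%s, %.1f): delta %+0.1f, %s\n",
              x$wt, x$wt_class, x$wt_index,
              x$mut, x$mut_class, x$mut_index, x$delta,
              if (x$is_change) {
                if (x$polarity_flip) "hydrophobicity change (polarity flip)"
                else "hydrophobicity change (large index shift)"
              } else "no hydrophobicity change"))
  invisible(x)
}
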