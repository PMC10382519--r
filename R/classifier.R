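#' Genotype-side functional classification of a missense mutation
#'
#' Rule cascade, in precedence order:
#' \enumerate{
#'   \item the position is a pivotal residue (annotated metal/substrate/AMP
#'     site or linker) -> Type 1, a direct active-site substitution;
#'   \item the substitution changes hydrophobicity and the position lies
#'     within the substrate-pocket radius -> Type 2, misfolding-prone;
#'   \item otherwise -> Type 3, likely non-pathogenic.
#' }
#' Pivotal-site membership dominates: a charge-flipping substitution at a
#' metal-site residue is still Type 1.
#'
#' @param mutation an `fbp_missense` (see [missense_mutation()] /
#'   [parse_hgvs()]).
#' @param sites an `fbp_sites` annotation.
#' @param ctx an `fbp_context` for the same position ([build_context()]).
#' @param hc an `fbp_hydropathy_change` for the same substitution
#'   ([hydropathy_change()]).
#' @return Object of class `fbp_type`: list with `mutation`, `category`
#'   (integer 1/2/3), flags `pivotal_site_hit`, `hydrophobicity_change`,
#'   `pocket_proximal`, and `rationale` (ordered character trace of the
#'   rule cascade).
#' @export
classify_genotype <- function(mutation, sites, ctx, hc) {
  stopifnot(inherits(mutation, "fbp_missense"), inherits(sites, "fbp_sites"),
            inherits(ctx, "fbp_context"), inherits(hc, "fbp_hydropathy_change"))
  if (ctx$position != mutation$position)
    stop("feature/position mismatch: context is for residue ", ctx$position,
         ", mutation at ", mutation$position)
  if (hc$wt != mutation$wt || hc$mut != mutation$mut)
    stop("feature mismatch: hydropathy change is for ", hc$wt, "->", hc$mut,
         ", mutation is ", format(mutation))

  pivotal <- mutation$position %in% pivotal_positions(sites)
  rationale <- character(0)
  if (pivotal) {
    category <- 1L
    rationale <- sprintf("position %d is a pivotal residue (%s site): Type 1",
                         mutation$position, ctx$pivotal_site)
  } else {
    rationale <- sprintf("position %d is not an annotated functional-site residue",
                         mutation$position)
    if (hc$is_change && ctx$pocket_proximal) {
      category <- 2L
      rationale <- c(rationale, sprintf(
        "hydrophobicity change (%s) and substrate-pocket proximity (%.1f A): Type 2",
        if (hc$polarity_flip) "polarity flip"
        else sprintf("|delta index| = %.1f", abs(hc$delta)),
        ctx$min_dist_substrate))
    } else {
      category <- 3L
      rationale <- c(rationale,
                     if (!hc$is_change)
                       "no hydrophobicity change"
                     else sprintf("hydrophobicity change but pocket-distant (%.1f A)",
                                  ctx$min_dist_substrate),
                     "Type 3 (likely non-pathogenic)")
    }
  }
  structure(list(mutation = mutation, category = category,
                 pivotal_site_hit = pivotal,
                 hydrophobicity_change = hc$is_change,
                 pocket_proximal = ctx$pocket_proximal,
                 rationale = rationale),
            class = "fbp_type")
}

#' @export
print.fbp_type <- function(x, ...) {
  cat(sprintf("%s: Type %d\n", format(x$mutation), x$category))
  cat(paste0("  - ", x$rationale, collapse = "\n"), "\n")
  invisible(x)
}

#' Phenotype classification thresholds
#'
#' Cutoffs used when categorical calls must be derived from the numeric
#' panel columns. The defaults sit in the gaps of the curated panel:
#' expression is "decreased" below 0.7 (misfolding-prone mutants reach at
#' most 0.6, active-site mutants at least 0.9); a mutant is "aggregated" at
#' >= 40% of cells with aggregates (misfolding minimum 42.7 vs 33.6
#' elsewhere); chaperone binding is "elevated" when both HSP70 and HSP90
#' ratios are >= 3.0.
#'
#' @param expression_decreased_below,min_aggregation_pct,hsp_elevated_min
#'   numeric cutoffs.
#' @return Named list of thresholds.
#' @export
phenotype_thresholds <- function(expression_decreased_below = 0.7,
                                 min_aggregation_pct = 40,
                                 hsp_elevated_min = 3.0) {
  list(expression_decreased_below = expression_decreased_below,
       min_aggregation_pct = min_aggregation_pct,
       hsp_elevated_min = hsp_elevated_min)
}

#' Phenotype-side category assignment from biochemical measurements
#'
#' Matches a phenotype record against the three biochemical signatures:
#' Type 1 -- loss of activity, expression not decreased, diffuse cytoplasmic
#' localization; Type 2 -- loss of activity, decreased expression,
#' ER-associated aggregation; Type 3 -- unchanged activity, expression not
#' decreased, diffuse localization. A record matching none of the three is
#' returned as "unclassified", never silently coerced.
#'
#' @param activity_call "decrease" or "no_change".
#' @param expression_ratio mutant/WT protein expression (dimensionless,
#'   >= 0).
#' @param localization "diffuse" or "aggregated_ER"; if `NA`, derived from
#'   `aggregation_pct` and the aggregation threshold.
#' @param aggregation_pct percentage of cells with aggregates (optional
#'   unless `localization` is `NA`).
#' @param thresholds see [phenotype_thresholds()].
#' @return "1", "2", "3" or "unclassified".
#' @export
#' @examples
#' classify_phenotype("decrease", 1.4, "diffuse")         # "1"
#' classify_phenotype("decrease", 0.4, "aggregated_ER")   # "2"
classify_phenotype <- function(activity_call, expression_ratio,
                               localization = NA_character_,
                               aggregation_pct = NA_real_,
                               thresholds = phenotype_thresholds()) {
  stopifnot(activity_call %in% c("decrease", "no_change"),
            is.numeric(expression_ratio), expression_ratio >= 0)
  if (is.na(localization)) {
    if (is.na(aggregation_pct))
      stop("supply localization or aggregation_pct")
    localization <- if (aggregation_pct >= thresholds$min_aggregation_pct)
      "aggregated_ER" else "diffuse"
  }
  stopifnot(localization %in% c("diffuse", "aggregated_ER"))
  expr_decreased <- expression_ratio < thresholds$expression_decreased_below
  if (activity_call == "decrease" && !expr_decreased && localization == "diffuse")
    return("1")
  if (activity_call == "decrease" && expr_decreased && localization == "aggregated_ER")
    return("2")
  if (activity_call == "no_change" && !expr_decreased && localization == "diffuse")
    return("3")
  "unclassified"
}

#' Classify a full mutation panel on both genotype and phenotype sides
#'
#' Runs the genotype rule cascade (hydropathy + structure context) and the
#' phenotype signature match for every panel row, returning one combined
#' table.
#'
#' @param panel data.frame like [fbp1_panel()]: column `mutation`
#'   ("G164D"-style) plus the phenotype columns `activity_call`,
#'   `expression_ratio`, `localization`, `aggregation_pct`.
#' @param sites an `fbp_sites` annotation (default packaged).
#' @param context_table per-position distance/secondary-structure table
#'   (default packaged synthetic curation).
#' @param theta hydropathy-shift threshold (see [hydropathy_change()]).
#' @param radius substrate-pocket radius in Angstrom.
#' @param thresholds phenotype cutoffs ([phenotype_thresholds()]).
#' @param scale hydropathy scale table ([kd_scale()]).
#' @return data.frame with per-mutation genotype category, phenotype
#'   category, rule flags and rationale.
#' @export
#' @examples
#' res <- classify_panel(fbp1_panel())
#' table(res$genotype_category)
classify_panel <- function(panel, sites = fbp1_sites(),
                           context_table = fbp1_context_table(),
                           theta = 3.0, radius = 12,
                           thresholds = phenotype_thresholds(),
                           scale = kd_scale()) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0L, !is.null(panel$mutation))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    p <- panel[i, ]
    mut <- parse_hgvs(paste0("p.", p$mutation))
    hc <- hydropathy_change(mut$wt, mut$mut, theta = theta, scale = scale)
    ctx <- build_context(mut$position, sites, context_table = context_table,
                         radius = radius)
    geno <- classify_genotype(mut, sites, ctx, hc)
    pheno <- if (!is.null(p$activity_call))
      classify_phenotype(p$activity_call, p$expression_ratio,
                         if (is.null(p$localization)) NA_character_ else p$localization,
                         if (is.null(p$aggregation_pct)) NA_real_ else p$aggregation_pct,
                         thresholds = thresholds)
    else NA_character_
    data.frame(mutation = p$mutation, position = mut$position,
               genotype_category = geno$category,
               phenotype_category = pheno,
               pivotal_site_hit = geno$pivotal_site_hit,
               hydrophobicity_change = geno$hydrophobicity_change,
               pocket_proximal = geno$pocket_proximal,
               hydropathy_delta = hc$delta,
               secondary_structure = ctx$secondary_structure,
               rationale = paste(geno$rationale, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype-phenotype concordance over a classified panel
#'
#' @param genotype_category,phenotype_category equal-length vectors of
#'   category labels (integer or character).
#' @return List with `agreement` (fraction concordant), `n_agree`, `n`, and
#'   `table` (per-item comparison).
#' @export
concordance <- function(genotype_category, phenotype_category) {
  if (length(genotype_category) == 0L)
    stop("concordance undefined on an empty panel")
  if (length(genotype_category) != length(phenotype_category))
    stop("category vectors must have equal length")
  agree <- as.character(genotype_category) == as.character(phenotype_category)
  list(agreement = mean(agree), n_agree = sum(agree), n = length(agree),
       table = data.frame(genotype = as.character(genotype_category),
                          phenotype = as.character(phenotype_category),
                          agree = agree, stringsAsFactors = FALSE))
}
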