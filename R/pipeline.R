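#' Configuration for an end-to-end panel run
#'
#' Collects every input path and threshold of the classification and
#' statistics stages. All defaults are the packaged calibrated values:
#' theta = 3.0 (hydropathy-shift threshold), pocket radius 12 Angstrom,
#' and the phenotype cutoffs of [phenotype_thresholds()].
#'
#' @param panel_path TSV of the phenotype panel (default: packaged
#'   15-mutation panel).
#' @param sites_path TSV of the functional-site annotation.
#' @param context_path TSV of the per-position structure context.
#' @param theta,radius classifier thresholds.
#' @param thresholds phenotype cutoffs.
#' @param seed integer seed recorded in the manifest (the panel stages are
#'   deterministic; the seed feeds any simulation stages added around
#'   them).
#' @param out_dir output directory for the reports.
#' @return A list of class `fbp_run_config`.
#' @export
run_config <- function(panel_path = fbp_extdata("fbp1_panel_table.tsv"),
                       sites_path = fbp_extdata("fbp1_site_annotation.tsv"),
                       context_path = fbp_extdata("fbp1_structure_context_synthetic.tsv"),
                       theta = 3.0, radius = 12,
                       thresholds = phenotype_thresholds(),
                       seed = 1L, out_dir = tempfile("fbp_run")) {
  structure(list(panel_path = panel_path, sites_path = sites_path,
                 context_path = context_path, theta = theta, radius = radius,
                 thresholds = thresholds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "fbp_run_config")
}

read_tsv_generic <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             quote = "", stringsAsFactors = FALSE)
}

#' Run the panel classification and statistics stages end to end
#'
#' Reads the phenotype panel, site annotation and structure context named
#' in the config, classifies every mutation on the genotype and phenotype
#' sides, computes the concordance and the panel correlations
#' (aggregation vs expression, HSP70/HSP90 vs aggregation), and writes
#' three artifacts to `config$out_dir`: `classification.tsv`,
#' `statistics.tsv` and `manifest.json` (config values, MD5 of every input
#' file, per-stage row counts). Deterministic: rerunning with the same
#' config reproduces the reports byte for byte.
#'
#' @param config an [run_config()].
#' @return Invisibly, a list with `classification` (data.frame),
#'   `concordance`, `correlations`, and the output `paths`.
#' @export
#' @examples
#' res <- run_panel(run_config())
#' res$concordance$agreement
run_panel <- function(config = run_config()) {
  stopifnot(inherits(config, "fbp_run_config"))
  for (p in c(config$panel_path, config$sites_path, config$context_path))
    if (!file.exists(p)) stop("input does not exist: ", p)
  panel <- read_tsv_generic(config$panel_path)
  sites_tab <- read_tsv_generic(config$sites_path)
  sites <- site_annotation(split(as.integer(sites_tab$position), sites_tab$site))
  context_table <- read_tsv_generic(config$context_path)

  cls <- classify_panel(panel, sites = sites, context_table = context_table,
                        theta = config$theta, radius = config$radius,
                        thresholds = config$thresholds)
  conc <- concordance(cls$genotype_category, cls$phenotype_category)
  cors <- list(
    aggregation_expression = pearson_cor(panel$aggregation_pct,
                                         panel$expression_ratio),
    hsp = hsp_correlations(panel))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cls_path <- file.path(config$out_dir, "classification.tsv")
  write.table(cls, cls_path, sep = "\t", quote = FALSE, row.names = FALSE)

  stats_tab <- data.frame(
    comparison = c("aggregation_vs_expression", "hsp70_vs_aggregation",
                   "hsp90_vs_aggregation"),
    r = c(cors$aggregation_expression$r, cors$hsp$hsp70$r, cors$hsp$hsp90$r),
    r_squared = c(cors$aggregation_expression$r_squared,
                  cors$hsp$hsp70$r_squared, cors$hsp$hsp90$r_squared),
    p_value = c(cors$aggregation_expression$p_value,
                cors$hsp$hsp70$p_value, cors$hsp$hsp90$p_value),
    n = c(cors$aggregation_expression$n, cors$hsp$hsp70$n, cors$hsp$hsp90$n))
  stats_path <- file.path(config$out_dir, "statistics.tsv")
  write.table(stats_tab, stats_path, sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- c(panel = config$panel_path, sites = config$sites_path,
              context = config$context_path)
  manifest <- list(
    config = list(theta = config$theta, radius = config$radius,
                  thresholds = config$thresholds, seed = config$seed),
    inputs = lapply(as.list(inputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    counts = list(panel_rows = nrow(panel), classified = nrow(cls),
                  concordant = conc$n_agree,
                  category_counts = as.list(table(cls$genotype_category))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(classification = cls, concordance = conc, correlations = cors,
                 paths = c(classification = cls_path, statistics = stats_path,
                           manifest = manifest_path)))
}
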