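#' Germline filter configuration
#'
#' Thresholds for the candidate-mutation filter: adoption rules (minimum
#' depth, minimum variant-supporting reads, variant allele fraction either
#' in the heterozygous window or at the homozygous level) and exclusion
#' rules (unidirectional-only support, indels in simple repeats, synonymous
#' SNVs, known variants above a population frequency).
#'
#' The literal homozygous criterion is VAF = 1; exact equality is
#' unrealistic for finite read counts, so "homozygous" is taken as
#' `vaf >= hom_vaf_min` (default 0.95), configurable.
#'
#' @param min_depth minimum read depth (default 8).
#' @param min_alt_reads minimum variant-supporting reads (default 4).
#' @param het_vaf_window two-element numeric, inclusive VAF window for
#'   heterozygous calls (default c(0.4, 0.6)).
#' @param hom_vaf_min minimum VAF treated as homozygous (default 0.95).
#' @param max_known_freq maximum tolerated population allele frequency in
#'   any annotated database (default 0.001).
#' @param exclude named logical vector toggling the exclusion rules
#'   `unidirectional`, `indel_in_repeat`, `synonymous`, `known_variant`.
#' @param vaf_rule_on_parents apply the VAF adoption rule to parental
#'   samples as well as the proband (default TRUE).
#' @return An object of class `fbp_filter_config`.
#' @export
filter_config <- function(min_depth = 8L, min_alt_reads = 4L,
                          het_vaf_window = c(0.4, 0.6), hom_vaf_min = 0.95,
                          max_known_freq = 0.001,
                          exclude = c(unidirectional = TRUE,
                                      indel_in_repeat = TRUE,
                                      synonymous = TRUE,
                                      known_variant = TRUE),
                          vaf_rule_on_parents = TRUE) {
  stopifnot(min_depth >= 0, min_alt_reads >= 0,
            length(het_vaf_window) == 2L,
            het_vaf_window[1] <= het_vaf_window[2],
            all(het_vaf_window >= 0), all(het_vaf_window <= 1),
            hom_vaf_min >= 0, hom_vaf_min <= 1, max_known_freq >= 0)
  defaults <- c(unidirectional = TRUE, indel_in_repeat = TRUE,
                synonymous = TRUE, known_variant = TRUE)
  defaults[names(exclude)] <- exclude
  structure(list(min_depth = min_depth, min_alt_reads = min_alt_reads,
                 het_vaf_window = het_vaf_window, hom_vaf_min = hom_vaf_min,
                 max_known_freq = max_known_freq, exclude = defaults,
                 vaf_rule_on_parents = vaf_rule_on_parents),
            class = "fbp_filter_config")
}

#' Variant allele fraction
#'
#' @param alt_reads variant-supporting read count(s).
#' @param depth total read depth(s); must be positive.
#' @return `alt_reads / depth`, a fraction in `[0, 1]`.
#' @export
#' @examples
#' vaf(15, 30)  # 0.5
vaf <- function(alt_reads, depth) {
  if (any(depth <= 0)) stop("VAF undefined at zero depth")
  if (any(alt_reads < 0) || any(alt_reads > depth))
    stop("alt_reads must lie in [0, depth]")
  alt_reads / depth
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

# Ensure optional annotation columns exist with neutral defaults.
complete_variant_table <- function(v) {
  n <- nrow(v)
  defaults <- list(bidirectional = TRUE, is_indel = FALSE,
                   in_simple_repeat = FALSE, consequence = "missense",
                   gene = NA_character_, hgvs_c = NA_character_)
  for (col in names(defaults))
    if (is.null(v[[col]])) v[[col]] <- rep(defaults[[col]], n)
  v
}

#' Apply the germline candidate-mutation filter
#'
#' Adoption rules: depth >= `min_depth`; variant-supporting reads >=
#' `min_alt_reads`; VAF inside the heterozygous window or at the homozygous
#' level. Exclusion rules: variant supported only by unidirectional reads;
#' insertion/deletion inside a simple repeat; synonymous SNV; known variant
#' with population frequency above `max_known_freq` in any annotated
#' database (columns prefixed `af_`). Every failing rule is reported, in a
#' fixed order, not just the first.
#'
#' @param variants data.frame of variants with columns `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `alt_reads`, and optionally `bidirectional`,
#'   `is_indel`, `in_simple_repeat`, `consequence`, `gene`, and `af_*`
#'   population frequency columns.
#' @param cfg an [filter_config()] object.
#' @return The input with added logical column `pass` and character column
#'   `reasons` (semicolon-separated failing rule codes, "" when passing).
#' @export
germline_filter <- function(variants, cfg = filter_config()) {
  stopifnot(inherits(cfg, "fbp_filter_config"), is.data.frame(variants))
  variants <- complete_variant_table(variants)
  n <- nrow(variants)
  if (n == 0L) {
    variants$pass <- logical(0); variants$reasons <- character(0)
    return(variants)
  }
  vafs <- vaf(variants$alt_reads, variants$depth)
  fail <- list(
    depth       = variants$depth < cfg$min_depth,
    alt_reads   = variants$alt_reads < cfg$min_alt_reads,
    vaf         = !((vafs >= cfg$het_vaf_window[1] & vafs <= cfg$het_vaf_window[2]) |
                      vafs >= cfg$hom_vaf_min)
  )
  if (cfg$exclude[["unidirectional"]])
    fail$unidirectional <- !variants$bidirectional
  if (cfg$exclude[["indel_in_repeat"]])
    fail$indel_in_repeat <- variants$is_indel & variants$in_simple_repeat
  if (cfg$exclude[["synonymous"]])
    fail$synonymous <- variants$consequence == "synonymous"
  if (cfg$exclude[["known_variant"]]) {
    af_cols <- grep("^af_", names(variants), value = TRUE)
    if (length(af_cols)) {
      af <- as.matrix(variants[af_cols])
      af[is.na(af)] <- 0
      fail$known_variant <- apply(af, 1L, max) > cfg$max_known_freq
    } else fail$known_variant <- rep(FALSE, n)
  }
  fail_mat <- do.call(cbind, fail)
  fail_mat[is.na(fail_mat)] <- FALSE
  variants$pass <- rowSums(fail_mat) == 0L
  variants$reasons <- apply(fail_mat, 1L, function(row)
    paste(colnames(fail_mat)[row], collapse = ";"))
  variants
}

genotype_call <- function(v, cfg) {
  vafs <- vaf(v$alt_reads, v$depth)
  ifelse(vafs >= cfg$hom_vaf_min, "hom",
         ifelse(vafs >= cfg$het_vaf_window[1] & vafs <= cfg$het_vaf_window[2],
                "het", "other"))
}

#' Detect compound-heterozygous variant pairs in a trio
#'
#' For every gene, reports each pair of variants (a, b) where `a` is
#' heterozygous in the proband and the father and absent from the mother
#' (the paternal allele), and `b` is heterozygous in the proband and the
#' mother and absent from the father (the maternal allele) -- the trans
#' configuration of a compound heterozygote. Genes carrying a homozygous
#' proband call are not reported by this operation (the recessive-
#' homozygous model is a different analysis). Variants without a gene
#' assignment are ignored with a warning.
#'
#' @param proband,father,mother per-sample variant tables (see
#'   [germline_filter()]), normally already filtered; keyed by
#'   (chrom, pos, ref, alt).
#' @param cfg an [filter_config()] object (supplies the het/hom VAF
#'   criteria used for genotype calls).
#' @return data.frame with one row per call: `gene`, paternal and maternal
#'   variant keys, positions and HGVS strings (when annotated), sorted by
#'   gene then position.
#' @export
detect_compound_het <- function(proband, father, mother, cfg = filter_config()) {
  if (missing(father) || is.null(father) || missing(mother) || is.null(mother))
    stop("incomplete pedigree: compound-heterozygosity detection requires both parents")
  stopifnot(is.data.frame(proband), is.data.frame(father), is.data.frame(mother))
  proband <- complete_variant_table(proband)
  father  <- complete_variant_table(father)
  mother  <- complete_variant_table(mother)

  empty <- data.frame(gene = character(0),
                      paternal_variant = character(0), maternal_variant = character(0),
                      paternal_pos = integer(0), maternal_pos = integer(0),
                      paternal_hgvs = character(0), maternal_hgvs = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(proband) == 0L) return(empty)

  if (anyNA(proband$gene)) {
    warning(sum(is.na(proband$gene)),
            " proband variant(s) without gene assignment ignored")
    proband <- proband[!is.na(proband$gene), , drop = FALSE]
  }
  if (nrow(proband) == 0L) return(empty)

  proband$key <- variant_key(proband)
  father$key  <- variant_key(father)
  mother$key  <- variant_key(mother)
  proband$gt <- genotype_call(proband, cfg)
  father_gt <- setNames(genotype_call(father, cfg), father$key)
  mother_gt <- setNames(genotype_call(mother, cfg), mother$key)
  gt_in <- function(gts, keys) {
    out <- unname(gts[keys])
    out[is.na(out)] <- "absent"
    out
  }
  proband$father_gt <- gt_in(father_gt, proband$key)
  proband$mother_gt <- gt_in(mother_gt, proband$key)

  calls <- list()
  for (g in sort(unique(proband$gene))) {
    pv <- proband[proband$gene == g, , drop = FALSE]
    if (any(pv$gt == "hom")) next
    pv <- pv[pv$gt == "het", , drop = FALSE]
    pat <- pv[pv$father_gt == "het" & pv$mother_gt == "absent", , drop = FALSE]
    mat <- pv[pv$mother_gt == "het" & pv$father_gt == "absent", , drop = FALSE]
    if (nrow(pat) == 0L || nrow(mat) == 0L) next
    pairs <- expand.grid(p = seq_len(nrow(pat)), m = seq_len(nrow(mat)))
    for (i in seq_len(nrow(pairs))) {
      a <- pat[pairs$p[i], ]; b <- mat[pairs$m[i], ]
      if (a$chrom == b$chrom && a$pos == b$pos) next
      calls[[length(calls) + 1L]] <- data.frame(
        gene = g,
        paternal_variant = a$key, maternal_variant = b$key,
        paternal_pos = a$pos, maternal_pos = b$pos,
        paternal_hgvs = a$hgvs_c, maternal_hgvs = b$hgvs_c,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$gene, out$paternal_pos, out$maternal_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pedigree (PED) file
#'
#' @param path PED file with columns family, individual, father, mother,
#'   sex, phenotype ("0" marks a founder's missing parent).
#' @return data.frame with those six columns.
#' @export
read_ped <- function(path) {
  ped <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("family", "id", "father", "mother",
                                  "sex", "phenotype"))
  ped
}

# INFO field helpers for the VCF reader.
info_value <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}
info_flag <- function(info, key) grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)

#' Read a multi-sample trio VCF into per-sample variant tables
#'
#' Parses a VCF v4.2 file (via the `vcfR` package) and the matching PED
#' pedigree, decomposes multi-allelic records into biallelic variants, and
#' returns one variant table per family member containing the columns used
#' by [germline_filter()] and [detect_compound_het()]. Depth and allele
#' counts come from the FORMAT fields (defaults `DP` and `AD`); gene,
#' consequence, HGVS, strand-support and repeat annotations come from the
#' INFO fields `GENE`, `CSQ`, `HGVSC`, `UNIDIR`, `SIMREP`; population
#' frequencies from `AF_*` INFO keys. A sample's table lists the variants
#' with at least one supporting read in that sample.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @param ped_path path to the PED file; the proband is the individual with
#'   both parents present in the file.
#' @return Named list `proband`, `father`, `mother` of variant tables.
#' @export
read_trio_vcf <- function(vcf_path, ped_path) {
  ped <- read_ped(ped_path)
  child <- ped[ped$father != "0" & ped$mother != "0", , drop = FALSE]
  if (nrow(child) != 1L)
    stop("pedigree must contain exactly one individual with both parents; found ",
         nrow(child))
  roles <- c(proband = child$id, father = child$father, mother = child$mother)
  if (!all(roles %in% ped$id))
    stop("incomplete pedigree: parents of ", child$id, " not all present")

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(vcf)
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (!all(roles %in% colnames(dp)))
    stop("VCF is missing samples: ",
         paste(setdiff(roles, colnames(dp)), collapse = ", "))

  af_keys <- unique(unlist(regmatches(info, gregexpr("AF_[A-Za-z0-9]+(?==)",
                                                     info, perl = TRUE))))
  base <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  base$gene <- info_value(info, "GENE")
  base$consequence <- info_value(info, "CSQ")
  base$consequence[is.na(base$consequence)] <- "other"
  base$hgvs_c <- info_value(info, "HGVSC")
  base$bidirectional <- !info_flag(info, "UNIDIR")
  base$in_simple_repeat <- info_flag(info, "SIMREP")
  for (k in af_keys) {
    v <- suppressWarnings(as.numeric(info_value(info, k)))
    base[[tolower(k)]] <- ifelse(is.na(v), 0, v)
  }

  lapply(as.list(roles), function(sample_id) {
    rows <- list()
    for (i in seq_len(nrow(base))) {
      alts <- strsplit(base$alt[i], ",", fixed = TRUE)[[1]]
      ad_i <- suppressWarnings(as.integer(strsplit(ad[i, sample_id], ",",
                                                   fixed = TRUE)[[1]]))
      for (k in seq_along(alts)) {
        alt_reads <- if (length(ad_i) >= k + 1L) ad_i[k + 1L] else 0L
        if (is.na(alt_reads) || alt_reads == 0L) next
        row <- base[i, , drop = FALSE]
        row$alt <- alts[k]
        row$depth <- as.integer(dp[i, sample_id])
        row$alt_reads <- alt_reads
        row$is_indel <- nchar(row$ref) != 1L || nchar(row$alt) != 1L
        rows[[length(rows) + 1L]] <- row
      }
    }
    if (length(rows) == 0L)
      return(complete_variant_table(
        data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), depth = integer(0),
                   alt_reads = integer(0), stringsAsFactors = FALSE)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
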