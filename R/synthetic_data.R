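#' Specification for a simulated trio variant set
#'
#' @param n_genes number of genes variants are scattered over.
#' @param n_variants total variant count (must cover the planted demands).
#' @param n_comphet number of planted compound-heterozygous pairs, one per
#'   gene.
#' @param n_fail number of planted filter violators; each violates exactly
#'   one filter rule, cycling through depth, VAF, unidirectional support,
#'   indel-in-repeat, synonymous and known-variant. (A variant violating
#'   only the minimum-variant-reads rule cannot exist while the VAF rule
#'   holds -- fewer than 4 supporting reads forces the VAF outside both the
#'   heterozygous window and the homozygous level at any admissible depth --
#'   so that rule is exercised jointly with the VAF rule in tests instead.)
#' @param comphet_genes optional character vector of gene names for the
#'   planted pairs (recycled names default to "GENE001", ...).
#' @param seed integer seed; the whole simulation is deterministic given
#'   the spec.
#' @return A list of class `fbp_trio_spec`.
#' @export
trio_sim_spec <- function(n_genes = 20L, n_variants = 60L, n_comphet = 1L,
                          n_fail = 6L, comphet_genes = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, n_variants >= 0, n_comphet >= 0, n_fail >= 0)
  if (n_variants < 2L * n_comphet + n_fail)
    stop("n_variants too small: need at least ", 2L * n_comphet + n_fail,
         " for the planted variants")
  if (n_comphet > n_genes) stop("more planted pairs than genes")
  if (!is.null(comphet_genes) && length(comphet_genes) != n_comphet)
    stop("comphet_genes must have length n_comphet")
  structure(list(n_genes = as.integer(n_genes),
                 n_variants = as.integer(n_variants),
                 n_comphet = as.integer(n_comphet),
                 n_fail = as.integer(n_fail),
                 comphet_genes = comphet_genes,
                 seed = as.integer(seed)),
            class = "fbp_trio_spec")
}

FAIL_RULE_CYCLE <- c("depth", "vaf", "unidirectional", "indel_in_repeat",
                     "synonymous", "known_variant")

# Read counts for a clean heterozygous call: VAF lands inside [0.4, 0.6].
het_counts <- function(n) {
  dp <- sample(24:48, n, replace = TRUE)
  alt <- round(dp / 2)
  list(dp = dp, alt = alt)
}

#' Simulate a trio variant set with planted ground truth
#'
#' Generates a family trio (proband, father, mother) of germline variant
#' tables containing (a) planted compound-heterozygous pairs -- for each
#' selected gene one clean missense variant heterozygous in the proband and
#' the father only and one heterozygous in the proband and the mother only;
#' (b) planted filter violators in the proband, each breaking exactly one
#' filter rule; and (c) clean background variants in Mendelian
#' configurations that are uninformative for compound heterozygosity
#' (shared by the whole trio, present in both parents but untransmitted, or
#' private to one parent). Deterministic for a fixed spec.
#'
#' @param spec a [trio_sim_spec()].
#' @return List with `proband`, `father`, `mother` (variant tables for
#'   [germline_filter()] / [detect_compound_het()]), `variants` (the unified
#'   table with per-sample read counts), and `truth`: `comphet` (data.frame
#'   gene/paternal_variant/maternal_variant) and `fail` (named character
#'   vector, variant key -> violated rule).
#' @export
#' @examples
#' trio <- simulate_trio(trio_sim_spec(seed = 7, comphet_genes = "FBP1"))
#' trio$truth$comphet
simulate_trio <- function(spec) {
  stopifnot(inherits(spec, "fbp_trio_spec"))
  set.seed(spec$seed)
  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
  comphet_genes <- if (is.null(spec$comphet_genes))
    genes[seq_len(spec$n_comphet)] else spec$comphet_genes
  gene_pool <- unique(c(genes, comphet_genes))
  gene_chrom <- setNames(as.character(sample(1:22, length(gene_pool),
                                             replace = TRUE)), gene_pool)
  gene_base <- setNames(seq_along(gene_pool) * 1e6, gene_pool)
  pos_used <- new.env(parent = emptyenv())
  next_pos <- function(gene) {
    repeat {
      p <- as.integer(gene_base[[gene]] + sample.int(50000L, 1L))
      key <- paste(gene_chrom[[gene]], p)
      if (is.null(pos_used[[key]])) { pos_used[[key]] <- TRUE; return(p) }
    }
  }
  bases <- c("A", "C", "G", "T")
  new_variant <- function(gene, consequence = "missense") {
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    data.frame(chrom = gene_chrom[[gene]], pos = next_pos(gene),
               ref = ref, alt = alt, gene = gene,
               consequence = consequence, bidirectional = TRUE,
               is_indel = FALSE, in_simple_repeat = FALSE,
               af_1kg = 0, af_esp = 0, af_hgvd = 0, af_exac = 0,
               hgvs_c = NA_character_,
               p_dp = 0L, p_alt = 0L, f_dp = 0L, f_alt = 0L,
               m_dp = 0L, m_alt = 0L, stringsAsFactors = FALSE)
  }
  set_counts <- function(v, who, kind) {
    h <- het_counts(1L)
    dp <- h$dp; alt <- switch(kind, het = h$alt, hom = dp, absent = 0L)
    v[[paste0(who, "_dp")]] <- dp
    v[[paste0(who, "_alt")]] <- alt
    v
  }

  rows <- list()
  truth_pairs <- list()
  # planted compound-het pairs
  for (g in comphet_genes) {
    a <- new_variant(g)                              # paternal allele
    a <- set_counts(set_counts(set_counts(a, "p", "het"), "f", "het"), "m", "absent")
    b <- new_variant(g)                              # maternal allele
    b <- set_counts(set_counts(set_counts(b, "p", "het"), "m", "het"), "f", "absent")
    rows <- c(rows, list(a, b))
    truth_pairs[[g]] <- data.frame(gene = g,
                                   paternal_variant = variant_key(a),
                                   maternal_variant = variant_key(b),
                                   stringsAsFactors = FALSE)
  }
  # planted single-rule violators, in the proband
  truth_fail <- character(0)
  if (spec$n_fail > 0L) {
    rules <- rep_len(FAIL_RULE_CYCLE, spec$n_fail)
    for (rule in rules) {
      v <- new_variant(sample(genes, 1L))
      v <- set_counts(set_counts(set_counts(v, "p", "het"), "f", "absent"), "m", "absent")
      if (rule == "depth") { v$p_dp <- 7L; v$p_alt <- 7L }        # hom VAF, depth < 8
      else if (rule == "vaf") { v$p_dp <- 30L; v$p_alt <- 9L }    # VAF 0.3
      else if (rule == "unidirectional") v$bidirectional <- FALSE
      else if (rule == "indel_in_repeat") {
        v$is_indel <- TRUE; v$in_simple_repeat <- TRUE
        v$alt <- paste0(v$ref, "T")
      }
      else if (rule == "synonymous") v$consequence <- "synonymous"
      else if (rule == "known_variant") v$af_exac <- 0.01
      rows <- c(rows, list(v))
      truth_fail[variant_key(v)] <- rule
    }
  }
  # uninformative clean background
  n_background <- spec$n_variants - 2L * spec$n_comphet - spec$n_fail
  if (n_background > 0L) {
    configs <- sample(c("trio_het", "parents_het", "father_only", "mother_only"),
                      n_background, replace = TRUE)
    for (cfg in configs) {
      v <- new_variant(sample(genes, 1L))
      v <- switch(cfg,
        trio_het    = set_counts(set_counts(set_counts(v, "p", "het"), "f", "het"), "m", "het"),
        parents_het = set_counts(set_counts(set_counts(v, "p", "absent"), "f", "het"), "m", "het"),
        father_only = set_counts(set_counts(set_counts(v, "p", "absent"), "f", "het"), "m", "absent"),
        mother_only = set_counts(set_counts(set_counts(v, "p", "absent"), "m", "het"), "f", "absent"))
      rows <- c(rows, list(v))
    }
  }

  variants <- do.call(rbind, rows)
  variants <- variants[order(as.integer(variants$chrom), variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  sample_table <- function(prefix) {
    present <- variants[variants[[paste0(prefix, "_alt")]] > 0L, , drop = FALSE]
    out <- present[c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "bidirectional", "is_indel", "in_simple_repeat",
                     "af_1kg", "af_esp", "af_hgvd", "af_exac", "hgvs_c")]
    out$depth <- present[[paste0(prefix, "_dp")]]
    out$alt_reads <- present[[paste0(prefix, "_alt")]]
    rownames(out) <- NULL
    out
  }
  comphet_truth <- if (length(truth_pairs))
    do.call(rbind, truth_pairs) else
    data.frame(gene = character(0), paternal_variant = character(0),
               maternal_variant = character(0), stringsAsFactors = FALSE)
  comphet_truth <- comphet_truth[order(comphet_truth$gene), , drop = FALSE]
  rownames(comphet_truth) <- NULL
  list(proband = sample_table("p"), father = sample_table("f"),
       mother = sample_table("m"), variants = variants,
       truth = list(comphet = comphet_truth, fail = truth_fail))
}

#' Write a simulated trio as a multi-sample VCF v4.2 plus PED
#'
#' @param trio result of [simulate_trio()].
#' @param vcf_path,ped_path output paths.
#' @return Invisibly, the VCF path.
#' @export
write_trio_vcf <- function(trio, vcf_path, ped_path = NULL) {
  v <- trio$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fbppheno-simulate_trio",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
    "##INFO=<ID=UNIDIR,Number=0,Type=Flag,Description=\"Unidirectional read support only\">",
    "##INFO=<ID=SIMREP,Number=0,Type=Flag,Description=\"Indel within a simple repeat\">",
    "##INFO=<ID=AF_1KG,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##INFO=<ID=AF_ESP,Number=1,Type=Float,Description=\"ESP6500 allele frequency\">",
    "##INFO=<ID=AF_HGVD,Number=1,Type=Float,Description=\"HGVD allele frequency\">",
    "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"ExAC allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPROBAND\tFATHER\tMOTHER")
  fmt_sample <- function(dp, alt) {
    gt <- ifelse(alt == 0L, "0/0", ifelse(alt == dp, "1/1", "0/1"))
    sprintf("%s:%d:%d,%d", gt, dp, dp - alt, alt)
  }
  info <- sprintf("GENE=%s;CSQ=%s;AF_1KG=%g;AF_ESP=%g;AF_HGVD=%g;AF_EXAC=%g",
                  v$gene, v$consequence, v$af_1kg, v$af_esp, v$af_hgvd, v$af_exac)
  info <- ifelse(v$bidirectional, info, paste0(info, ";UNIDIR"))
  info <- ifelse(v$in_simple_repeat, paste0(info, ";SIMREP"), info)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t60\tPASS\t%s\tGT:DP:AD\t%s\t%s\t%s",
                  v$chrom, v$pos, v$ref, v$alt, info,
                  fmt_sample(v$p_dp, v$p_alt),
                  fmt_sample(v$f_dp, v$f_alt),
                  fmt_sample(v$m_dp, v$m_alt))
  writeLines(c(header, body), vcf_path)
  if (!is.null(ped_path))
    writeLines(c("FAM1\tPROBAND\tFATHER\tMOTHER\t2\t2",
                 "FAM1\tFATHER\t0\t0\t1\t1",
                 "FAM1\tMOTHER\t0\t0\t2\t1"), ped_path)
  invisible(vcf_path)
}

#' Specification for a simulated phenotype panel
#'
#' @param n number of simulated mutations (>= 3).
#' @param target_r population Pearson correlation between aggregation
#'   percentage and expression ratio, in [-1, 1].
#' @param hsp_target_r population correlation between chaperone binding
#'   and aggregation (default 0.8).
#' @param noise_sd standard deviation (on the standardized latent scale) of
#'   independent measurement noise added to each readout; attenuates the
#'   realized correlation below `target_r` (default 0).
#' @param seed integer seed.
#' @return A list of class `fbp_pheno_spec`.
#' @export
phenotype_sim_spec <- function(n, target_r, hsp_target_r = 0.8,
                               noise_sd = 0, seed = 1L) {
  stopifnot(n >= 3)
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  if (abs(hsp_target_r) > 1) stop("|hsp_target_r| must be <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n = as.integer(n), target_r = target_r,
                 hsp_target_r = hsp_target_r, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fbp_pheno_spec")
}

#' Simulate a biochemical phenotype table with known correlation structure
#'
#' A latent "misfolding severity" per mutation drives both readouts:
#' aggregation percentage increases and expression ratio decreases with
#' severity (for negative `target_r`), mirroring the causal picture in
#' which misfolding produces both aggregation and degradation-driven
#' expression loss. The standardized pair is constructed with population
#' correlation `target_r`, optional measurement noise is added, and the
#' values are mapped to measurement scales: aggregation to a percentage
#' clamped to [0, 100] (location 50, scale 16 -- clamping is therefore
#' rare and attenuates the realized correlation only marginally) and
#' expression to a non-negative mutant/WT ratio (location 0.8, scale 0.3).
#' HSP70/HSP90 binding ratios are generated the same way against
#' aggregation at `hsp_target_r`.
#'
#' @param spec a [phenotype_sim_spec()].
#' @return List with `table` (data.frame `mutation`, `aggregation_pct`,
#'   `expression_ratio`, `hsp70_ratio`, `hsp90_ratio`) and `params` (the
#'   spec).
#' @export
#' @examples
#' sim <- simulate_phenotypes(phenotype_sim_spec(n = 200, target_r = -0.9))
#' cor(sim$table$aggregation_pct, sim$table$expression_ratio)
simulate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "fbp_pheno_spec"))
  set.seed(spec$seed)
  n <- spec$n
  correlated <- function(base, r) r * base + sqrt(1 - r^2) * rnorm(n)
  severity <- rnorm(n)
  agg_std  <- severity
  expr_std <- correlated(severity, spec$target_r)
  h70_std  <- correlated(severity, spec$hsp_target_r)
  h90_std  <- correlated(severity, spec$hsp_target_r)
  if (spec$noise_sd > 0) {
    agg_std  <- agg_std + rnorm(n, sd = spec$noise_sd)
    expr_std <- expr_std + rnorm(n, sd = spec$noise_sd)
    h70_std  <- h70_std + rnorm(n, sd = spec$noise_sd)
    h90_std  <- h90_std + rnorm(n, sd = spec$noise_sd)
  }
  table <- data.frame(
    mutation = sprintf("SIM%04d", seq_len(n)),
    aggregation_pct = pmin(100, pmax(0, 50 + 16 * agg_std)),
    expression_ratio = pmax(0, 0.8 + 0.3 * expr_std),
    hsp70_ratio = pmax(0, 15 + 5 * h70_std),
    hsp90_ratio = pmax(0, 15 + 5 * h90_std),
    stringsAsFactors = FALSE)
  list(table = table, params = spec)
}

#' Build a toy protein structure from explicit coordinates
#'
#' One heavy atom (CA) per residue at the supplied coordinates, plus an
#' optional heteroatom ligand group; intended as a fully controlled fixture
#' for the structure-context geometry.
#'
#' @param resno integer residue numbers (must be unique, non-empty).
#' @param coords numeric matrix `length(resno)` x 3 of coordinates in
#'   Angstrom.
#' @param aa residue name (default "GLY"), recycled.
#' @param chain chain identifier(s), recycled (default "A").
#' @param ligand optional list(resname =, coords = matrix) heteroatom
#'   group.
#' @return An `fbp_structure`.
#' @export
#' @examples
#' s <- toy_structure(1:3, cbind(c(0, 5, 10), 0, 0))
#' min_distance(s, 1, 3)  # 10
toy_structure <- function(resno, coords, aa = "GLY", chain = "A", ligand = NULL) {
  resno <- as.integer(resno)
  if (length(resno) == 0L) stop("residue list must be non-empty")
  if (anyDuplicated(resno)) stop("duplicate residue numbers in toy structure")
  coords <- as.matrix(coords)
  if (nrow(coords) != length(resno) || ncol(coords) != 3L)
    stop("coords must be a length(resno) x 3 matrix")
  atoms <- data.frame(type = "ATOM", chain = rep_len(chain, length(resno)),
                      resno = resno, insert = "",
                      resid = rep_len(toupper(aa), length(resno)),
                      elety = "CA", element = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(ligand)) {
    lc <- as.matrix(ligand$coords)
    het <- data.frame(type = "HETATM", chain = "L",
                      resno = max(resno) + 1L, insert = "",
                      resid = toupper(ligand$resname),
                      elety = paste0("X", seq_len(nrow(lc))), element = "C",
                      x = lc[, 1], y = lc[, 2], z = lc[, 3],
                      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, het)
  }
  structure(list(atoms = atoms, source = "toy"), class = "fbp_structure")
}

#' Write a structure as PDB-format text
#'
#' Fixed-column ATOM/HETATM records at PDB precision (3 decimals), so a
#' round-trip through [parse_structure()] reproduces the coordinates to
#' 1e-3 Angstrom.
#'
#' @param model an `fbp_structure`.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_toy_pdb <- function(model, path) {
  stopifnot(inherits(model, "fbp_structure"))
  a <- model$atoms
  rec <- ifelse(a$type == "HETATM", "HETATM", "ATOM  ")
  name4 <- vapply(a$elety, function(e)
    if (nchar(e) < 4L) sprintf(" %-3s", e) else substr(e, 1, 4), character(1))
  lines <- sprintf("%s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4, a$resid, a$chain, a$resno,
                   a$x, a$y, a$z, 1.0, 0.0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
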