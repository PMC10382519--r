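# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook formulas,
# exhaustive scans.

# Two-pass product-moment correlation with the t-transform p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# Exhaustive all-atom-pairs minimum distance between a query residue and a
# target residue set / ligand name, heavy atoms only.
oracle_min_dist <- function(model, query, target) {
  a <- model$atoms[model$atoms$element != "H", ]
  qa <- a[a$resno == query & a$type == "ATOM", ]
  ta <- if (is.numeric(target)) a[a$resno %in% target, ] else a[a$resid %in% target, ]
  best <- Inf
  for (i in seq_len(nrow(qa))) for (j in seq_len(nrow(ta))) {
    d <- sqrt((qa$x[i] - ta$x[j])^2 + (qa$y[i] - ta$y[j])^2 + (qa$z[i] - ta$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# Brute-force compound-het caller: enumerate every pair of proband-het
# variants per gene and keep the trans configurations.
oracle_comphet <- function(proband, father, mother, cfg = filter_config()) {
  gt <- function(tab) {
    v <- tab$alt_reads / tab$depth
    ifelse(v >= cfg$hom_vaf_min, "hom",
           ifelse(v >= cfg$het_vaf_window[1] & v <= cfg$het_vaf_window[2],
                  "het", "other"))
  }
  key <- function(tab) paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  p <- proband[!is.na(proband$gene), ]
  pk <- key(p); pg <- gt(p)
  fgt <- setNames(gt(father), key(father))
  mgt <- setNames(gt(mother), key(mother))
  lk <- function(map, k) { o <- unname(map[k]); o[is.na(o)] <- "absent"; o }
  out <- list()
  for (g in sort(unique(p$gene))) {
    idx <- which(p$gene == g)
    if (any(pg[idx] == "hom")) next
    idx <- idx[pg[idx] == "het"]
    if (length(idx) < 2L) next
    for (i in idx) for (j in idx) {
      if (p$pos[i] == p$pos[j] && p$chrom[i] == p$chrom[j]) next
      if (lk(fgt, pk[i]) == "het" && lk(mgt, pk[i]) == "absent" &&
          lk(mgt, pk[j]) == "het" && lk(fgt, pk[j]) == "absent")
        out[[length(out) + 1L]] <- data.frame(gene = g, paternal = pk[i],
                                              maternal = pk[j],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(gene = character(0),
                                      paternal = character(0),
                                      maternal = character(0)))
  res <- do.call(rbind, out)
  res[order(res$gene, res$paternal, res$maternal), , drop = FALSE]
}

# Random clean variant table for filter/comphet property tests.
random_variant_table <- function(n, n_genes = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dp <- sample(10:60, n, replace = TRUE)
  data.frame(chrom = as.character(sample(1:5, n, replace = TRUE)),
             pos = sample.int(1e6, n),
             ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
             gene = sprintf("G%02d", sample.int(n_genes, n, replace = TRUE)),
             depth = dp,
             alt_reads = round(dp * runif(n, 0.35, 1)),
             stringsAsFactors = FALSE)
}

random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}
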