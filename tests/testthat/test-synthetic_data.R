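test_that("trio simulation plants the requested compound-het pairs with the trans configuration", {
  trio <- simulate_trio(trio_sim_spec(n_genes = 12, n_variants = 40,
                                      n_comphet = 1, n_fail = 0,
                                      comphet_genes = "FBP1", seed = 7))
  truth <- trio$truth$comphet
  expect_equal(nrow(truth), 1L)
  expect_equal(truth$gene, "FBP1")
  key <- function(tab) paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  pat <- truth$paternal_variant; mat <- truth$maternal_variant
  # paternal allele: het proband + father, absent from mother
  expect_true(pat %in% key(trio$proband) && pat %in% key(trio$father))
  expect_false(pat %in% key(trio$mother))
  expect_true(mat %in% key(trio$proband) && mat %in% key(trio$mother))
  expect_false(mat %in% key(trio$father))
})

test_that("planted violators each map to their single failing rule", {
  trio <- simulate_trio(trio_sim_spec(n_genes = 10, n_variants = 30,
                                      n_comphet = 0, n_fail = 6, seed = 11))
  expect_length(trio$truth$fail, 6L)
  g <- germline_filter(trio$proband, filter_config())
  g$key <- paste(g$chrom, g$pos, g$ref, g$alt, sep = ":")
  got <- g$reasons[match(names(trio$truth$fail), g$key)]
  expect_equal(got, unname(trio$truth$fail))   # exactly one rule each
  # a depth-7 violator is mapped to the depth rule
  expect_true("depth" %in% trio$truth$fail)
  depth_key <- names(trio$truth$fail)[trio$truth$fail == "depth"]
  expect_equal(g$depth[match(depth_key, g$key)], 7L)
})

test_that("trio simulation is deterministic and rejects impossible sizing", {
  spec <- trio_sim_spec(n_genes = 8, n_variants = 25, n_comphet = 2,
                        n_fail = 4, seed = 42)
  t1 <- simulate_trio(spec); t2 <- simulate_trio(spec)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_trio_vcf(t1, f1); write_trio_vcf(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(trio_sim_spec(n_variants = 3, n_comphet = 1, n_fail = 2),
               "too small")
})

test_that("simulated trios round-trip through the VCF/PED reader", {
  trio <- simulate_trio(trio_sim_spec(n_genes = 6, n_variants = 20,
                                      n_comphet = 1, n_fail = 3, seed = 5))
  vcf <- tempfile(fileext = ".vcf"); ped <- tempfile(fileext = ".ped")
  write_trio_vcf(trio, vcf, ped)
  back <- read_trio_vcf(vcf, ped)
  for (who in c("proband", "father", "mother")) {
    a <- trio[[who]][order(trio[[who]]$chrom, trio[[who]]$pos), ]
    b <- back[[who]][order(back[[who]]$chrom, back[[who]]$pos), ]
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$pos, b$pos)
    expect_equal(a$depth, b$depth)
    expect_equal(a$alt_reads, b$alt_reads)
    expect_equal(a$consequence, b$consequence)
    expect_equal(a$bidirectional, b$bidirectional)
    expect_equal(a$af_exac, b$af_exac)
  }
})

test_that("phenotype simulator hits its target correlation", {
  # near-zero target
  t0 <- simulate_phenotypes(phenotype_sim_spec(n = 1000, target_r = 0, seed = 1))$table
  r0 <- oracle_pearson(t0$aggregation_pct, t0$expression_ratio)$r
  expect_lt(abs(r0), 0.1)
  # strong negative target: envelope over seeds
  rs <- vapply(1:30, function(s) {
    tt <- simulate_phenotypes(phenotype_sim_spec(n = 1000, target_r = -0.9,
                                                 seed = s))$table
    oracle_pearson(tt$aggregation_pct, tt$expression_ratio)$r
  }, numeric(1))
  expect_true(all(rs > -0.95 & rs < -0.82))
  # degenerate: perfect anticorrelation without noise is exactly collinear
  tc <- simulate_phenotypes(phenotype_sim_spec(n = 50, target_r = -1,
                                               noise_sd = 0, seed = 2))$table
  expect_equal(oracle_pearson(tc$aggregation_pct, tc$expression_ratio)$r, -1,
               tolerance = 1e-12)
  expect_error(phenotype_sim_spec(n = 100, target_r = -1.2), "target_r")
  expect_error(phenotype_sim_spec(n = 2, target_r = 0), "n >= 3")
})

test_that("correlation calibration: mean realized r tracks the target to 0.02", {
  for (target in c(-0.9, -0.5, 0, 0.5)) {
    rs <- vapply(1:200, function(s) {
      tt <- simulate_phenotypes(phenotype_sim_spec(n = 1000, target_r = target,
                                                   seed = s))$table
      cor(tt$aggregation_pct, tt$expression_ratio)
    }, numeric(1))
    expect_lt(abs(mean(rs) - target), 0.02)
  }
})

test_that("toy structures encode their geometry and round-trip through PDB text", {
  s <- toy_structure(1:3, cbind(c(0, 5, 10), 0, 0))
  expect_equal(min_distance(s, 1, 2), 5)
  expect_equal(min_distance(s, 1, 3), 10)
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(s, f)
  m <- parse_structure(f)
  expect_equal(as.matrix(m$atoms[m$atoms$type == "ATOM", c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # a strand with the site at one end has monotone distances
  strand <- toy_structure(1:20, cbind(3.8 * (0:19), 0, 0))
  d <- vapply(2:20, function(p) min_distance(strand, p, 1L), numeric(1))
  expect_true(all(diff(d) >= 0))
  expect_error(toy_structure(integer(0), matrix(numeric(0), 0, 3)), "non-empty")
  expect_error(toy_structure(c(1, 1), cbind(c(0, 1), 0, 0)), "duplicate")
})
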