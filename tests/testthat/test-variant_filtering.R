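clean_variant <- function(depth = 100, alt_reads = 50, consequence = "missense",
                          bidirectional = TRUE, is_indel = FALSE,
                          in_simple_repeat = FALSE, af = 0) {
  data.frame(chrom = "9", pos = 1000L, ref = "C", alt = "T", gene = "FBP1",
             depth = depth, alt_reads = alt_reads, consequence = consequence,
             bidirectional = bidirectional, is_indel = is_indel,
             in_simple_repeat = in_simple_repeat, af_exac = af,
             stringsAsFactors = FALSE)
}

test_that("vaf is alt_reads/depth and rejects zero depth", {
  expect_equal(vaf(15, 30), 0.5)
  expect_equal(vaf(30, 30), 1.0)
  expect_equal(vaf(4, 8), 0.5)  # both adoption thresholds exactly met
  expect_error(vaf(0, 0), "zero depth")
  expect_error(vaf(5, 4), "alt_reads")
})

test_that("germline filter applies every adoption and exclusion rule with reason codes", {
  cfg <- filter_config()
  # depth boundary: 7 fails, 8 passes (hom VAF keeps the VAF rule satisfied)
  g <- germline_filter(clean_variant(depth = 7, alt_reads = 7), cfg)
  expect_false(g$pass); expect_equal(g$reasons, "depth")
  expect_true(germline_filter(clean_variant(depth = 8, alt_reads = 4), cfg)$pass)
  # clean missense passes with empty reasons
  g <- germline_filter(clean_variant(), cfg)
  expect_true(g$pass); expect_equal(g$reasons, "")
  # each exclusion fires alone
  expect_equal(germline_filter(clean_variant(consequence = "synonymous"), cfg)$reasons,
               "synonymous")
  expect_equal(germline_filter(clean_variant(bidirectional = FALSE), cfg)$reasons,
               "unidirectional")
  expect_equal(germline_filter(clean_variant(is_indel = TRUE, in_simple_repeat = TRUE),
                               cfg)$reasons, "indel_in_repeat")
  expect_equal(germline_filter(clean_variant(af = 0.002), cfg)$reasons,
               "known_variant")
  # frequency exactly at the threshold is kept ("> 0.001" excludes)
  expect_true(germline_filter(clean_variant(af = 0.001), cfg)$pass)
  # VAF outside het window and below hom level
  expect_equal(germline_filter(clean_variant(depth = 100, alt_reads = 30), cfg)$reasons,
               "vaf")
  # all failing rules are reported, not just the first
  g <- germline_filter(clean_variant(depth = 6, alt_reads = 2,
                                     consequence = "synonymous"), cfg)
  expect_equal(g$reasons, "depth;alt_reads;vaf;synonymous")
})

test_that("filter is monotone in depth and alt reads at fixed VAF", {
  cfg <- filter_config()
  # depth sweep at VAF 0.5: once passing, deeper never fails the depth rule
  passed <- FALSE
  for (d in seq(2, 60, by = 2)) {
    g <- germline_filter(clean_variant(depth = d, alt_reads = d / 2), cfg)
    fails_counts <- grepl("depth|alt_reads", g$reasons)
    if (passed) expect_false(fails_counts)
    if (!fails_counts) passed <- TRUE
  }
  expect_true(passed)
})

test_that("trio fixture reproduces the published compound heterozygote", {
  vcf <- system.file("extdata", "fbp1_trio.vcf", package = "fbppheno")
  ped <- system.file("extdata", "fbp1_trio.ped", package = "fbppheno")
  trio <- read_trio_vcf(vcf, ped)
  cfg <- filter_config()
  filt <- lapply(trio, function(t) { g <- germline_filter(t, cfg); g[g$pass, ] })
  # the fodder variants are filtered out of the proband
  expect_equal(nrow(filt$proband), 2L)
  calls <- detect_compound_het(filt$proband, filt$father, filt$mother, cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene, "FBP1")
  expect_equal(calls$paternal_hgvs, "c.491G>A")
  expect_equal(calls$maternal_hgvs, "c.581T>C")
})

test_that("cis configuration (both variants from one parent) yields no call", {
  p <- rbind(clean_variant(), transform(clean_variant(), pos = 2000L))
  f <- p                               # father carries both
  m <- p[0, ]                          # mother carries neither
  p$alt_reads <- p$depth * 0.5; f$alt_reads <- f$depth * 0.5
  expect_equal(nrow(detect_compound_het(p, f, m)), 0L)
})

test_that("missing parental sample is an explicit pedigree error", {
  p <- clean_variant()
  expect_error(detect_compound_het(p, NULL, p), "incomplete pedigree")
  expect_error(detect_compound_het(p, p, NULL), "incomplete pedigree")
})

test_that("compound-het detection is order-invariant and matches the brute-force oracle", {
  for (s in 1:25) {
    set.seed(s)
    p <- random_variant_table(40); f <- random_variant_table(40); m <- random_variant_table(40)
    calls <- detect_compound_het(p, f, m)
    shuffled <- detect_compound_het(p[sample(nrow(p)), ],
                                    f[sample(nrow(f)), ],
                                    m[sample(nrow(m)), ])
    expect_equal(calls, shuffled, ignore_attr = TRUE)
    oracle <- oracle_comphet(p, f, m)
    expect_equal(nrow(calls), nrow(oracle))
    if (nrow(calls)) {
      expect_equal(calls$gene, oracle$gene)
      expect_equal(sort(paste(calls$paternal_variant, calls$maternal_variant)),
                   sort(paste(oracle$paternal, oracle$maternal)))
    }
  }
})

test_that("genes with a homozygous proband call are excluded and unassigned genes warn", {
  cfg <- filter_config()
  a <- clean_variant(); a$alt_reads <- a$depth          # hom in proband
  b <- transform(clean_variant(), pos = 2000L)
  c <- transform(clean_variant(), pos = 3000L)
  p <- rbind(a, b, c)
  f <- b; m <- c
  expect_equal(nrow(detect_compound_het(p, f, m, cfg)), 0L)
  p2 <- rbind(b, c); p2$gene <- NA_character_
  expect_warning(res <- detect_compound_het(p2, f, m, cfg), "gene")
  expect_equal(nrow(res), 0L)
})
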