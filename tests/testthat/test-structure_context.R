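test_that("PDB parsing preserves coordinates, ligands, and rejects malformed records", {
  s <- toy_structure(1:5, cbind(c(0, 3, 6, 9, 12), 1, -2),
                     ligand = list(resname = "AMP", coords = cbind(c(0, 3), 4, -2)))
  f <- tempfile(fileext = ".pdb")
  write_toy_pdb(s, f)
  m <- parse_structure(f)
  expect_equal(m$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(m$atoms$resno, s$atoms$resno)
  expect_true(any(m$atoms$type == "HETATM" & m$atoms$resid == "AMP"))
  # truncated ATOM record errors with the line number
  lines <- readLines(f)
  lines[2] <- substr(lines[2], 1, 40)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  expect_error(parse_structure(f2), "line 2")
})

test_that("min_distance: 3-4-5 geometry, self-inclusion, ligand targets, missing query", {
  s <- toy_structure(1:2, rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(min_distance(s, 1, 2), 5.0)
  expect_equal(min_distance(s, 2, 1), 5.0)              # symmetric
  expect_equal(min_distance(s, 1, c(1L, 2L)), 0.0)      # self-inclusion
  expect_error(min_distance(s, 99, 1), "not present")
  lig <- toy_structure(1:2, rbind(c(0, 0, 0), c(10, 0, 0)),
                       ligand = list(resname = "F6P", coords = cbind(6, 8, 0)))
  expect_equal(min_distance(lig, 1, "F6P"), 10)
})

test_that("min_distance matches the exhaustive all-pairs oracle on random models", {
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(10:80, 1)
    s <- toy_structure(seq_len(n), matrix(runif(3 * n, -30, 30), ncol = 3))
    q <- sample(n, 1)
    target <- sample(setdiff(seq_len(n), q), sample(1:5, 1))
    expect_equal(min_distance(s, q, target), oracle_min_dist(s, q, target),
                 tolerance = 1e-12)
  }
})

test_that("distances are invariant to atom order and minimized over chains", {
  set.seed(31)
  n <- 30
  s <- toy_structure(seq_len(n), matrix(runif(3 * n, 0, 20), ncol = 3),
                     chain = rep(c("A", "B"), length.out = n))
  perm <- sample(nrow(s$atoms))
  s2 <- s; s2$atoms <- s$atoms[perm, ]
  expect_equal(min_distance(s, 3, c(10L, 20L)), min_distance(s2, 3, c(10L, 20L)))
  # all-chain minimum is never larger than the per-chain minimum
  q <- 2L; t <- 4L  # even residues both land on chain B
  d_all <- min_distance(s, q, t, chains = "all")
  expect_lte(d_all, min_distance(s, q, t, chains = "per_chain"))
})

test_that("context from a model: distances, pocket flag and pivotal annotation", {
  sites <- site_annotation(list(metal = c(2L), substrate = c(5L)))
  s <- toy_structure(1:6, cbind(3.8 * (0:5), 0, 0))
  ctx <- build_context(5, sites, model = s, radius = 12)
  expect_equal(ctx$min_dist_substrate, 0)   # substrate residue itself
  expect_true(ctx$pocket_proximal)
  expect_true(ctx$is_pivotal)
  expect_equal(ctx$pivotal_site, "substrate")
  ctx1 <- build_context(1, sites, model = s, radius = 5)
  expect_equal(ctx1$min_dist_metal, 3.8)
  expect_equal(ctx1$min_dist_substrate, 4 * 3.8)
  expect_false(ctx1$pocket_proximal)
  expect_false(ctx1$is_pivotal)
})

test_that("context from the packaged table reproduces the panel annotations", {
  sites <- fbp1_sites()
  tab <- fbp1_context_table()
  ctx119 <- build_context(119, sites, context_table = tab)
  expect_true(ctx119$is_pivotal)
  expect_equal(ctx119$pivotal_site, "metal")
  expect_equal(ctx119$min_dist_metal, 0)
  expect_true(build_context(164, sites, context_table = tab)$pocket_proximal)
  expect_false(build_context(325, sites, context_table = tab)$pocket_proximal)
  expect_equal(build_context(281, sites, context_table = tab)$secondary_structure,
               "turn")
  expect_error(build_context(999, sites, context_table = tab),
               "context unavailable")
})

test_that("pocket separation: every misfolding-prone position is nearer than every distant one", {
  panel <- fbp1_panel()
  tab <- fbp1_context_table()
  d <- setNames(tab$min_dist_substrate, tab$position)
  pos_of <- function(type) unique(vapply(panel$mutation[panel$type == type],
    function(m) parse_hgvs(paste0("p.", m))$position, integer(1)))
  type2 <- pos_of(2); type3 <- pos_of(3)
  expect_true(max(d[as.character(type2)]) < min(d[as.character(type3)]))
  # and the default radius (12 A) separates them
  expect_true(all(d[as.character(type2)] <= 12))
  expect_true(all(d[as.character(type3)] > 12))
})
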