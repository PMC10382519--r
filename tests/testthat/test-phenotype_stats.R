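test_that("pearson_cor recovers exact collinearity and rejects degenerate input", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1))$r, -1.0)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
  expect_error(pearson_cor(1:4, 1:3), "equal length")
})

test_that("pearson_cor matches the two-pass textbook formula to 1e-12", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    x <- rnorm(n); y <- 0.3 * x + rnorm(n)
    got <- pearson_cor(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
    expect_equal(got$r_squared, want$r^2, tolerance = 1e-12)
  }
})

test_that("pearson_cor is invariant to affine rescaling of either vector", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(10 * x + 3, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -2 * y + 7)$r, -base, tolerance = 1e-12)
})

test_that("panel aggregation-expression correlation matches the pre-computed value", {
  panel <- fbp1_panel()
  res <- pearson_cor(panel$aggregation_pct, panel$expression_ratio)
  # values frozen from an independent product-moment computation on the
  # 15 printed (aggregation %, expression ratio) pairs
  expect_equal(res$r, -0.9432240853724354, tolerance = 1e-9)
  expect_equal(res$r_squared, 0.8896716752266673, tolerance = 1e-9)
  expect_equal(res$p_value, 1.3675615242506348e-07, tolerance = 1e-9)
  expect_lt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("chaperone-binding correlations with aggregation are positive and significant", {
  res <- hsp_correlations(fbp1_panel())
  expect_equal(res$hsp70$r, 0.542897379293846, tolerance = 1e-9)
  expect_equal(res$hsp90$r, 0.5394162128701453, tolerance = 1e-9)
  expect_equal(res$hsp70$p_value, 0.03650518112132762, tolerance = 1e-9)
  expect_equal(res$hsp90$p_value, 0.03796605727444167, tolerance = 1e-9)
  expect_true(res$hsp70$r > 0 && res$hsp90$r > 0)
  # degenerate chaperone column errors
  panel <- fbp1_panel(); panel$hsp70_ratio <- 1
  expect_error(hsp_correlations(panel), "zero variance")
})

test_that("simulated chaperone correlations land near their target", {
  sim <- simulate_phenotypes(phenotype_sim_spec(n = 1000, target_r = -0.5,
                                                hsp_target_r = 0.8, seed = 8))
  res <- hsp_correlations(sim$table)
  expect_lt(abs(res$hsp70$r - 0.8), 0.05)
  expect_lt(abs(res$hsp90$r - 0.8), 0.05)
})

test_that("FBPase activity conversion follows Beer-Lambert dimensional analysis", {
  t <- 0:5
  # slope exactly 0.0622 A/min with the default assay constants
  res <- fbpase_activity(t, 0.05 + 0.0622 * t)
  expect_equal(res$slope, 0.0622, tolerance = 1e-12)
  expect_equal(res$activity, 7.5e-5, tolerance = 1e-9)  # mmol/min/mg, hand-derived
  expect_false(res$clipped)
  # flat series gives zero activity
  expect_equal(fbpase_activity(t, rep(0.3, 6))$activity, 0)
  # linear in slope, inversely linear in protein mass
  res2 <- fbpase_activity(t, 0.05 + 2 * 0.0622 * t)
  expect_equal(res2$activity, 2 * res$activity, tolerance = 1e-12)
  res_half <- fbpase_activity(t, 0.05 + 0.0622 * t, protein_mg = 0.080)
  expect_equal(res_half$activity, res$activity / 2, tolerance = 1e-12)
  # negative slope clips to zero with a warning
  expect_warning(resn <- fbpase_activity(t, 0.5 - 0.01 * t), "negative")
  expect_equal(resn$activity, 0)
  expect_true(resn$clipped)
  expect_error(fbpase_activity(c(0, 0, 1), c(1, 2, 3)), "diff")
})
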