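# Differential-expression primitives and the gated per-gene driver.

test_that("Anderson-Darling matches the raw-formula oracle and flags unassessable input", {
  expect_error(anderson_darling(rep(3, 20)), class = "dosig_normality_fallback")
  expect_error(anderson_darling(rnorm(5)), class = "dosig_normality_fallback")

  q <- qnorm(ppoints(50))
  got <- anderson_darling(q)
  ref <- ad_formula(q)
  expect_equal(got$A2star, ref$A2star, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  expect_gt(got$p, 0.5)

  set.seed(11)
  mix <- c(rnorm(45, 0, 0.1), rnorm(5, 5, 0.1))
  expect_lt(anderson_darling(mix)$p, 0.01)

  for (s in 1:5) {
    set.seed(s)
    x <- rlnorm(30)
    got <- anderson_darling(x)
    ref <- ad_formula(x)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U: worked example, symmetry, and reference agreement", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)

  a <- c(1.5, 2.5, 9)
  r2 <- mann_whitney_u(a, a)
  expect_equal(r2$U, length(a)^2 / 2)
  expect_equal(r2$p, 1)

  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")

  # large samples against the reference rank-test implementation
  set.seed(3)
  a <- rnorm(40); b <- rnorm(45, 0.7)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  got <- mann_whitney_u(a, b)
  expect_equal(got$p, ref$p.value, tolerance = 1e-8)
})

test_that("two-sample z-test: identity, antisymmetry, and closed-form value", {
  a <- c(1, 2, 3, 4)
  expect_equal(two_sample_z(a, a)$z, 0)
  expect_equal(two_sample_z(a, a)$p, 1)

  r <- two_sample_z(c(9, 11), c(8.5, 9.5))  # means 10, 9; vars 2, 0.5; se2 = 1.25
  expect_equal(r$z, 1 / sqrt(1.25))
  fwd <- two_sample_z(c(1, 5, 3), c(2, 2.5, 9))
  rev <- two_sample_z(c(2, 2.5, 9), c(1, 5, 3))
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)
  expect_equal(two_sample_z(c(0, 1, 2, 3), c(-1, 0, 1, 2))$p,
               2 * pnorm(-1 / sqrt(5 / 3 / 4 + 5 / 3 / 4)), tolerance = 1e-12)
  expect_error(two_sample_z(c(1, 1), c(1, 1)), "variance")
})

test_that("log2 fold change respects scale and pseudo-count", {
  expect_equal(log2_fold_change(c(8, 8), c(2, 2), "linear", 0), 2)
  expect_equal(log2_fold_change(c(3, 3), c(3, 3), "linear", 0), 0)
  expect_equal(log2_fold_change(c(0, 0), c(3, 3), "linear", 0.25),
               log2(0.25 / 3.25))
  expect_equal(log2_fold_change(c(7, 9), c(5, 5), "log2"), 3)
})

test_that("BH adjustment: worked example, bounds, rank monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  # monotone in the ranks: a smaller raw p never gets a larger adjusted p
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("the DE driver recovers planted genes, truncates, and orders stably", {
  recovered <- vapply(1:5, function(s) {
    b <- generate_fixture(fixture_spec(n_genes = 100, n_tumor = 20,
                                       n_normal = 20, n_planted_deg = 10,
                                       shift_log2 = 2, seed = s))
    deg <- run_differential_expression(b$dataset)
    c(hits = sum(b$truth$planted_degs %in% deg$gene_id),
      fp = sum(!deg$gene_id %in% b$truth$planted_degs))
  }, numeric(2))
  expect_true(all(recovered["hits", ] == 10))
  expect_true(all(recovered["fp", ] <= 1))

  b <- generate_fixture(fixture_spec(n_genes = 100, n_tumor = 20, n_normal = 20,
                                     n_planted_deg = 10, shift_log2 = 2, seed = 1))
  expect_identical(nrow(run_differential_expression(b$dataset, n = 5)), 5L)

  # invariance to sample and gene order
  deg <- run_differential_expression(b$dataset)
  perm_s <- sample(ncol(b$dataset$values))
  perm_g <- sample(nrow(b$dataset$values))
  ds_p <- expression_dataset(b$dataset$values[perm_g, perm_s],
                             b$dataset$labels[perm_s], b$dataset$scale)
  deg_p <- run_differential_expression(ds_p)
  expect_equal(as.data.frame(deg), as.data.frame(deg_p))

  # no qualifying genes -> empty table
  null_b <- generate_fixture(fixture_spec(n_genes = 50, n_tumor = 10,
                                          n_normal = 10, n_planted_deg = 0,
                                          seed = 2))
  expect_identical(nrow(run_differential_expression(null_b$dataset)), 0L)

  small <- expression_dataset(matrix(1:8, 2, 4,
                                     dimnames = list(c("G1", "G2"), paste0("S", 1:4))),
                              c("tumor", "tumor", "normal", "normal"), "log2")
  expect_error(run_differential_expression(small), "3 samples")
})

test_that("the normality gate routes normal large classes to z and others to U", {
  b <- generate_fixture(fixture_spec(n_genes = 150, n_tumor = 20, n_normal = 20,
                                     n_planted_deg = 0, scale = "log2", seed = 5))
  tab <- run_differential_expression(b$dataset, p_cut = 2, fc_cut = 0)
  expect_gt(mean(tab$test_used == "z_test"), 0.7)

  small <- generate_fixture(fixture_spec(n_genes = 50, n_tumor = 6, n_normal = 6,
                                         n_planted_deg = 0, scale = "log2", seed = 6))
  tab2 <- run_differential_expression(small$dataset, p_cut = 2, fc_cut = 0)
  expect_true(all(tab2$test_used == "mann_whitney"))
})
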