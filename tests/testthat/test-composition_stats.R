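test_that("composition percentages count known residues only", {
  cv <- composition_vector(protein_record("a", "GGSS"))
  expect_equal(cv$percents[["G"]], 50)
  expect_equal(cv$percents[["S"]], 50)
  expect_equal(sum(cv$percents), 100)

  cv2 <- composition_vector(protein_record("b", "GSCK"))
  expect_equal(unname(cv2$percents[c("G", "S", "C", "K")]), rep(25, 4))

  # X excluded from the denominator
  cv3 <- composition_vector(protein_record("c", "GGGSX"),
                            max_unknown_fraction = 0.25)
  expect_equal(cv3$percents[["G"]], 75)
  expect_equal(cv3$n_unknown, 1L)
})

test_that("records above the unknown-fraction threshold are rejected", {
  rec <- protein_record("d", paste0(strrep("G", 17), strrep("X", 3)))  # 15% X
  expect_error(composition_vector(rec), "0.150.*0.100")
  expect_silent(composition_vector(rec, max_unknown_fraction = 0.15))
})

test_that("composition sums to 100 for generator records", {
  for (s in 1:5) {
    g <- generate_loricrin_protein(generator_params(n_loops = 10, seed = s))
    cv <- composition_vector(g$record)
    expect_equal(sum(cv$percents), 100, tolerance = 1e-9)
  }
})

test_that("residue_anova agrees with the sum-of-squares oracle", {
  groups <- list(a = c(10, 12, 14), b = c(20, 22, 24))
  got <- residue_anova(groups)
  want <- oracle_anova_F(groups)
  expect_equal(got$statistic, want$F)
  expect_equal(got$p_value, want$p)
  expect_equal(unname(got$df), c(1, 4))
  expect_equal(unname(got$group_means), c(12, 22))

  g3 <- list(x = c(1, 4, 7, 2), y = c(5, 5, 6), z = c(9, 8, 12, 11, 10))
  expect_equal(residue_anova(g3)$statistic, oracle_anova_F(g3)$F)

  # identical groups: no between-group variance
  same <- residue_anova(list(a = c(3, 4, 5), b = c(3, 4, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(residue_anova(list(a = 1:3)), ">= 2 groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      a <- rnorm(sample(3:10, 1), mean = runif(1, 0, 10))
      b <- rnorm(sample(3:10, 1), mean = runif(1, 0, 10))
      F <- residue_anova(list(a, b))$statistic
      t <- stats::t.test(a, b, var.equal = TRUE)$statistic
      expect_equal(F, unname(t)^2, tolerance = 1e-10)
    }
  })
})

test_that("welch_t_test matches the closed form and its symmetries", {
  got <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  want <- oracle_welch(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, want$t)
  expect_equal(unname(got$df), want$df)
  expect_equal(got$p_value, want$p)

  # identical samples
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # zero-variance pair with equal means
  flat <- welch_t_test(c(2, 2), c(2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # swapping negates t, preserves p
  ab <- welch_t_test(c(1, 5, 3), c(9, 2, 4))
  ba <- welch_t_test(c(9, 2, 4), c(1, 5, 3))
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("ANOVA detects the planted serine offset between gene families", {
  # LOR1-like vs LOR3-like loop alphabets chosen so realized mean serine
  # differs by about 15 percentage points; n = 15 per group (scaled-down
  # replicate count here; the full 200-replicate run is in the acceptance
  # suite)
  hits <- vapply(1:20, function(r) {
    s1 <- vapply(1:15, function(i) {
      g <- generate_loricrin_protein(generator_params(
        n_loops = 20, index_style = "LOR1_like",
        loop_alphabet_weights = c(G = 0.72, S = 0.08, C = 0.15, K = 0.05),
        seed = 10000 + 100 * r + i))
      composition_vector(g$record)$percents[["S"]]
    }, numeric(1))
    s3 <- vapply(1:15, function(i) {
      g <- generate_loricrin_protein(generator_params(
        n_loops = 20, index_style = "LOR3_like",
        loop_alphabet_weights = c(G = 0.46, S = 0.32, C = 0.15, K = 0.05),
        seed = 20000 + 100 * r + i))
      composition_vector(g$record)$percents[["S"]]
    }, numeric(1))
    residue_anova(list(LOR1 = s1, LOR3 = s3))$p_value < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pca_svd matches the covariance eigendecomposition", {
  m <- matrix(c(4, 2, 0.6,
                4.2, 2.1, 0.59,
                3.9, 2.0, 0.58,
                4.3, 2.1, 0.62,
                4.1, 2.2, 0.63), ncol = 3, byrow = TRUE)
  got <- pca_svd(m)
  expect_equal(got$variance_proportions, oracle_pca_proportions(m),
               tolerance = 1e-10, ignore_attr = TRUE)
  # scores of a centred PCA have zero column means
  expect_equal(unname(colMeans(got$scores)), rep(0, 3), tolerance = 1e-12)
  # full-rank reconstruction reproduces the centred matrix
  centred <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(got$scores %*% t(got$loadings), centred,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pca_svd handles rank-1, permutation invariance and errors", {
  m1 <- outer(c(1, 2, 3, 4), c(2, 1, 0.5))
  expect_equal(pca_svd(m1)$variance_proportions[1], 1, tolerance = 1e-12)

  withr::with_seed(8, {
    m <- matrix(rnorm(60), nrow = 10)
    p1 <- pca_svd(m)$variance_proportions
    p2 <- pca_svd(m[sample(10), ])$variance_proportions
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_true(all(diff(p1) <= 1e-12))
  })
  expect_error(pca_svd(matrix(1, 4, 3)), "constant")
})
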