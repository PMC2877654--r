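test_that("Box-Cox selects a near-zero exponent for log-normal data", {
  set.seed(1)
  x <- exp(rnorm(500))
  bc <- boxcox_transform(x)
  expect_lte(abs(bc$lambda), 0.2)
  expect_identical(bc$offset, 0)
})

test_that("Box-Cox closed forms, offsets, and errors behave", {
  x <- c(1, 3, 7, 20, 2, 5)
  # lambda = 1 is the affine shift x - 1 (rank preserving)
  bc1 <- boxcox_transform(x, lambda_grid = 1)
  expect_equal(bc1$transformed, x - 1)
  # a zero triggers the half-minimum offset and stays finite
  bc0 <- boxcox_transform(c(0, x), lambda_grid = seq(-2, 2, 0.1))
  expect_equal(bc0$offset, 0.5)
  expect_true(all(is.finite(bc0$transformed)))
  expect_error(boxcox_transform(rep(2, 5)), "constant")
  expect_error(boxcox_transform(c(-1, 2, 3)), "non-negative")
})

test_that("skew screening transforms only skewed variables and reports them", {
  set.seed(2)
  hb <- data.frame(sym = rnorm(100), skew = exp(rnorm(100, sd = 1.5)))
  prep <- prepare_habitat(hb)
  expect_identical(prep$transformed, "skew")
  expect_identical(prep$values$sym, hb$sym)
  expect_lt(abs(tadfd:::sample_skewness(prep$values$skew)),
            abs(tadfd:::sample_skewness(hb$skew)))
})

test_that("correlation-matrix PCA has the exact closed-form spectrum", {
  # two correlated variables: eigenvalues 1 + r and 1 - r
  set.seed(3)
  z <- rnorm(2000)
  X <- data.frame(a = z + rnorm(2000, sd = 0.8), b = z + rnorm(2000, sd = 0.8))
  r <- stats::cor(X$a, X$b)
  p <- run_pca(X)
  expect_equal(p$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-9)

  # trace conservation and spectral reconstruction on a 14-variable table
  tm <- generate_trait_matrix(seed = 4)
  cm <- generate_communities(tm, assembly_scenario("neutral", seed = 5))
  hb <- generate_habitat(cm, 0.8, seed = 6)
  pca <- run_pca(hb)
  expect_equal(sum(pca$eigenvalues), 14, tolerance = 1e-9)
  R <- pca$loadings %*% diag(pca$eigenvalues) %*% t(pca$loadings)
  expect_equal(R, stats::cor(as.matrix(as.data.frame(hb))), tolerance = 1e-9)
  # scores of distinct non-degenerate components are uncorrelated (the
  # microhabitat simplex forces one exactly-zero eigenvalue, whose scores
  # are numerical noise)
  keep <- pca$eigenvalues > 1e-8
  cc <- stats::cor(pca$scores[, keep])
  expect_equal(cc, diag(sum(keep)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(run_pca(cbind(as.data.frame(hb), flat = 1)), "flat")
})

test_that("eigenvalue proportions flatten to 1/p for independent noise", {
  set.seed(7)
  X <- as.data.frame(matrix(rnorm(20000 * 14), ncol = 14))
  p <- run_pca(X)
  expect_true(all(abs(p$proportion - 1 / 14) < 0.01))
})

test_that("broken-stick retention and its override", {
  ev <- c(7, 3.2, 1.8, 0.5, 0.4, 0.4, 0.35, 0.35)
  ev <- ev / sum(ev) * 14
  expect_gte(select_n_components(ev), 2)
  # hand-check against the closed form sum_{j >= k} 1/j
  p <- length(ev)
  bs <- sapply(1:p, function(k) sum(1 / (k:p)) / p)
  expect_identical(select_n_components(ev),
                   as.integer(sum(cumsum(ev / sum(ev) <= bs) == 0)))
  expect_identical(select_n_components(rep(1, 14)), 0L)
  expect_identical(select_n_components(rep(1, 14), override = 3), 3L)
})

test_that("broken-stick expectations match the reference implementation", {
  skip_if_not_installed("vegan")
  ev <- run_pca(as.data.frame(matrix(rnorm(50 * 8), 50, 8)))$eigenvalues
  ref <- vegan::bstick(length(ev), tot.var = sum(ev))
  expect_equal(tadfd:::broken_stick(length(ev)) * sum(ev), ref,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("profile-likelihood lambda agrees with the reference Box-Cox profile", {
  skip_if_not_installed("MASS")
  set.seed(15)
  x <- exp(rnorm(200, sd = 0.8))
  grid <- seq(-2, 2, 0.1)
  bc <- boxcox_transform(x, lambda_grid = grid)
  ref <- MASS::boxcox(x ~ 1, lambda = grid, plotit = FALSE)
  expect_equal(bc$lambda, ref$x[which.max(ref$y)], tolerance = 1e-9)
})

test_that("bootstrapped-eigenvector flags recover block structure and symmetry", {
  set.seed(8)
  n <- 60
  b1 <- rnorm(n); b2 <- rnorm(n)
  X <- cbind(sapply(1:5, function(i) b1 + rnorm(n, sd = 0.3)),
             sapply(1:5, function(i) b2 + rnorm(n, sd = 0.3)),
             matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("v", 1:14)
  bt <- bootstrap_eigenvector_test(as.data.frame(X), n_boot = 999,
                                   alpha = 0.05, seed = 9)
  # both blocks load significantly on the two leading components
  expect_true(all(bt$flags[1:5, 1] | bt$flags[1:5, 2]))
  expect_true(all(bt$flags[6:10, 1] | bt$flags[6:10, 2]))
  # determinism under a fixed seed
  bt2 <- bootstrap_eigenvector_test(as.data.frame(X), n_boot = 999,
                                    alpha = 0.05, seed = 9)
  expect_identical(bt$flags, bt2$flags)
  expect_error(bootstrap_eigenvector_test(as.data.frame(X), n_boot = 99),
               "at least 199")
})

test_that("duplicated variables receive identical flags", {
  set.seed(10)
  n <- 50
  base <- matrix(rnorm(n * 5), n, 5)
  X <- cbind(base, dup = base[, 3])
  colnames(X) <- c(paste0("v", 1:5), "dup")
  bt <- bootstrap_eigenvector_test(as.data.frame(X), n_boot = 299, seed = 11)
  expect_identical(unname(bt$flags["v3", ]), unname(bt$flags["dup", ]))
})

test_that("SR regression eliminates uninformative components and keeps exact fits", {
  set.seed(12)
  scores <- matrix(rnorm(29 * 3), 29, 3,
                   dimnames = list(NULL, paste0("PC", 1:3)))
  SR <- 3 * scores[, 1] + 10
  fit <- suppressWarnings(regress_sr_on_pcs(scores, SR))  # exact fit
  expect_identical(fit$retained, "PC1")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_setequal(fit$trace$dropped, c("PC2", "PC3"))

  # pure-noise response: every component is dropped, intercept-only model
  fit0 <- regress_sr_on_pcs(scores, rnorm(29), threshold = 1e-6)
  expect_length(fit0$retained, 0L)
  expect_identical(nrow(fit0$coefficients), 1L)
})

test_that("the habitat gradient is recovered as a significant SR predictor", {
  tm <- generate_trait_matrix(seed = 13)
  hits <- sapply(1:60, function(r) {
    cm <- generate_communities(tm, assembly_scenario("neutral", seed = 200 + r))
    hb <- generate_habitat(cm, 0.9, seed = 900 + r)
    pca <- run_pca(prepare_habitat(hb)$values)
    sr <- regress_sr_on_pcs(pca$scores[, 1:3], species_richness(cm))
    cf <- sr$coefficients
    "PC1" %in% rownames(cf) && cf["PC1", "Pr(>|t|)"] < 0.001 &&
      sign(cf["PC1", "Estimate"]) == sign(pca$loadings["width", 1])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("regression fit statistics are invariant to component sign flips", {
  set.seed(14)
  scores <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("PC1", "PC2")))
  SR <- 2 * scores[, 1] - scores[, 2] + rnorm(40)
  f1 <- regress_sr_on_pcs(scores, SR, threshold = 1)
  f2 <- regress_sr_on_pcs(scores %*% diag(c(-1, 1)) , SR, threshold = 1)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(unname(f1$coefficients["PC1", "Estimate"]),
               -unname(f2$coefficients["PC1", "Estimate"]), tolerance = 1e-12)
})
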