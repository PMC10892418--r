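test_that("district summary computes CV from the n-1 standard deviation", {
  s <- toy_samples()[1:2, ]
  s$As <- c(2, 4)
  summ <- district_summary(s)
  as_row <- summ[summ$metal == "As", ]
  expect_equal(as_row$mean, 3)
  expect_equal(as_row$cv, 100 * sqrt(2) / 3, tolerance = 1e-10)   # 47.14%
  expect_equal(as_row$min, 2)
  expect_equal(as_row$max, 4)

  s$Hg <- c(0.05, 0.05)
  expect_equal(district_summary(s)$cv[summ$metal == "Hg"], 0)
  expect_error(district_summary(toy_samples()[1, ]), "fewer than 2")
  full <- district_summary(toy_samples())
  expect_true(all(full$min <= full$mean & full$mean <= full$max))
})

test_that("standardization yields unit z-scores and is idempotent", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "As"))
  expect_equal(as.vector(standardize_metals(m)), c(-1, 0, 1))

  s <- random_samples(30, seed = 2)
  z <- standardize_metals(s)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 7))
  expect_equal(unname(standardize_metals(z)), unname(z), tolerance = 1e-10)

  s$Cd <- 0.2
  expect_error(standardize_metals(s), "Cd")
})

test_that("correlation matrix matches cor.test and annotates significance", {
  s <- random_samples(110, seed = 21)
  corr <- metal_correlation(s)
  expect_equal(diag(corr$r), setNames(rep(1, 7), metals()))
  expect_equal(corr$r, t(corr$r))
  expect_true(all(abs(corr$r) <= 1))
  expect_true(all(is.na(diag(corr$p))))

  m <- as.matrix(s[, metals()])
  for (pair in list(c(1, 3), c(2, 5), c(4, 7))) {
    ct <- cor.test(m[, pair[1]], m[, pair[2]])
    expect_equal(corr$r[pair[1], pair[2]], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(corr$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-10)
  }
  expect_true(all(corr$stars[!is.na(corr$p) & corr$p < 0.01] == "**"))
  expect_true(all(corr$stars[!is.na(corr$p) & corr$p >= 0.05] == ""))

  # an r of 0.498 on 110 samples is far past the 1% threshold
  tstat <- 0.498 * sqrt(108 / (1 - 0.498^2))
  expect_lt(2 * pt(-tstat, 108), 0.01)

  # exact linear dependence
  two <- cbind(a = s$As, b = 3 * s$As + 1, c = -2 * s$As)
  r2 <- suppressWarnings(stats::cor(two))
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)
  expect_error(metal_correlation(s[1:2, ]), "at least 3")
})

test_that("correlation is invariant to affine unit rescaling", {
  s <- random_samples(60, seed = 31)
  base <- metal_correlation(s)$r
  s$Pb <- s$Pb * 1000 + 5   # mg/kg -> ug/kg with an offset
  expect_equal(metal_correlation(s)$r, base, tolerance = 1e-12)
})

test_that("PCA bookkeeping: trace, Kaiser retention, loadings and reconstruction", {
  # rank-1 toy: two perfectly correlated variables
  withr::local_seed(7)
  a <- rnorm(30)
  toy <- cbind(v1 = a, v2 = 2 * a)
  p1 <- metal_pca(toy)
  expect_equal(p1$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p1$n_retained, 1)
  expect_equal(p1$contribution, c(100, 0), tolerance = 1e-12)

  s <- random_samples(110, seed = 13)
  p <- metal_pca(s)
  expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-8)
  expect_equal(sum(p$contribution), 100, tolerance = 1e-8)
  expect_equal(p$cumulative[7], 100, tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(p$n_retained, sum(p$eigenvalues >= 1))
  expect_identical(colnames(p$loadings), paste0("PC", seq_len(p$n_retained)))

  # independent eigen-solver: singular values of the z matrix
  z <- standardize_metals(s)
  sv <- svd(z)$d^2 / (nrow(z) - 1)
  expect_equal(p$eigenvalues, sv, tolerance = 1e-8)

  # communalities and full reconstruction of the correlation matrix
  L <- p$loadings_full
  expect_equal(unname(rowSums(L^2)), rep(1, 7), tolerance = 1e-8)
  expect_lt(max(abs(L %*% t(L) - cor(z))), 1e-8)
  expect_true(all(rowSums(p$loadings^2) <= 1 + 1e-8))

  # deterministic sign: the dominant loading of each component is positive
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)

  expect_error(metal_pca(random_samples(6, seed = 1)), "more samples")
})

test_that("district-wise PCA runs on each district's own z-scores", {
  s <- rbind(random_samples(20, "A", seed = 1), random_samples(25, "B", seed = 2))
  out <- pca_by_district(s)
  expect_named(out, c("A", "B"))
  expect_equal(out$A$n, 20)
  expect_equal(sum(out$B$eigenvalues), 7, tolerance = 1e-8)
})
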