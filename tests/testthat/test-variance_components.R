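test_that("the GRM is symmetric, unit-diagonal on average, and scale-invariant", {
  X <- random_genotypes(150, 200, seed = 41)
  grm <- build_grm(X)
  K <- grm$K
  expect_lt(max(abs(K - t(K))), 1e-10)
  expect_equal(mean(diag(K)), 1, tolerance = 0.1)
  # duplicating the marker set leaves the GRM unchanged
  K2 <- build_grm(cbind(X, X))$K
  expect_equal(K2, K, tolerance = 1e-12)
  # independent markers: off-diagonals shrink as 1/sqrt(m)
  off <- K[upper.tri(K)]
  expect_lt(unname(quantile(abs(off), 0.99)), 3 / sqrt(200))
  expect_lt(max(abs(off)), 6 / sqrt(200))
  # single balanced marker: entries are +/-1 up to standardization
  x1 <- matrix(rep(c(-1, 1), each = 10), ncol = 1,
               dimnames = list(paste0("s", 1:20), "chrI:10_A/C"))
  K1 <- build_grm(x1)$K
  expect_true(all(abs(abs(K1) - max(abs(K1))) < 1e-10))
  expect_warning(build_grm(cbind(X, const = rep(1, 150))), "constant")
})

test_that("REML heritability hits the boundaries for pure-noise and noiseless traits", {
  X <- random_genotypes(300, 250, seed = 42)
  grm <- build_grm(X)
  set.seed(43)
  null_h2 <- vapply(1:10, function(i) reml_h2(rnorm(300), grm)$h2, numeric(1L))
  expect_lt(median(null_h2), 0.05)
  b <- rnorm(250, 0, 1 / sqrt(250))
  g <- as.numeric(X %*% b)
  expect_gt(reml_h2(g, grm)$h2, 0.98)
})

test_that("REML h2 is invariant to affine rescaling of the trait", {
  X <- random_genotypes(200, 150, seed = 44)
  grm <- build_grm(X)
  set.seed(45)
  y <- as.numeric(X %*% rnorm(150, 0, 0.05)) + rnorm(200)
  h <- reml_h2(y, grm)$h2
  expect_equal(reml_h2(5 * y - 3, grm)$h2, h, tolerance = 1e-6)
})

test_that("REML handles missing values and matrix traits consistently", {
  X <- random_genotypes(200, 150, seed = 46)
  grm <- build_grm(X)
  set.seed(47)
  y <- as.numeric(X %*% rnorm(150, 0, 0.08)) + rnorm(200)
  y_na <- y; y_na[1:20] <- NA
  single <- reml_h2(y_na, grm)$h2
  Y <- cbind(t1 = y, t2 = y_na)
  rownames(Y) <- rownames(X)
  multi <- reml_h2(Y, grm)
  expect_equal(multi$h2[multi$trait == "t2"], single, tolerance = 1e-10)
  expect_equal(multi$n, c(200L, 180L))
  # bootstrap SE is returned and positive
  b <- reml_h2(y, grm, n_boot = 20, seed = 3L)
  expect_gt(b$se, 0)
})

test_that("hotspot marker sets capture hotspot-driven variance", {
  p <- small_panel()
  G <- unclass(p$growth)
  hot <- p$hotspots$peak_marker
  suite <- marker_set_variance_suite(p$growth, p$genotypes, hot,
                                     n_random = 20, seed = 6L)
  est <- suite$estimates
  # conditions driven by hotspots: hotspot-set h2 close to all-marker h2
  byc <- merge(est[est$set == "all_markers", c("condition", "h2")],
               est[est$set == "hotspots", c("condition", "h2")],
               by = "condition", suffixes = c("_all", "_hot"))
  strong <- byc[byc$h2_all > 0.2, ]
  expect_gt(nrow(strong), 0)
  expect_gt(median(strong$h2_hot / strong$h2_all), 0.7)
  expect_true(all(suite$p_hotspot >= 0 & suite$p_hotspot <= 1, na.rm = TRUE))
})

test_that("growth driven only by private loci leaves hotspot sets uninformative", {
  set.seed(51)
  X <- random_genotypes(250, 120, seed = 51)
  g <- genotype_matrix(X)
  hot <- colnames(X)[1:15]
  private <- colnames(X)[101:104]
  y <- as.numeric(X[, private] %*% rep(0.5, 4)) + rnorm(250)
  Y <- matrix(y, dimnames = list(rownames(X), "cond"))
  suite <- marker_set_variance_suite(Y, g, hot, n_random = 30, seed = 8L)
  est <- suite$estimates
  h_all <- est$h2[est$set == "all_markers"]
  h_hot <- est$h2[est$set == "hotspots"]
  expect_gt(h_all, 0.3)
  expect_lt(h_hot, 0.5 * h_all)
  expect_gt(suite$p_hotspot[["cond"]], 0.05)
})

test_that("incremental hotspot curves saturate when one hotspot dominates", {
  set.seed(52)
  X <- random_genotypes(250, 60, seed = 52)
  g <- genotype_matrix(X)
  hs <- data.frame(hotspot = paste0("hs", 1:6),
                   peak_marker = colnames(X)[c(5, 15, 25, 35, 45, 55)],
                   n_target_genes = c(600, 50, 40, 30, 20, 10))
  y <- 0.9 * X[, 5] + rnorm(250, 0, 0.8)   # hs1 (most targets) is causal
  names(y) <- rownames(X)
  inc <- incremental_hotspot_variance(y, g, hs)
  expect_equal(inc$curve$k, 2:6)
  # curve is non-decreasing up to REML noise and saturates at the first set
  expect_true(all(diff(inc$curve$h2) > -0.02))
  expect_gt(inc$curve$h2[1], 0.8 * inc$curve$h2[5])
  expect_equal(inc$k_half, 2L)
  expect_true(all(inc$contributions$frac >= 0))
})

test_that("equal-effect hotspots accumulate variance roughly linearly", {
  set.seed(53)
  X <- random_genotypes(300, 40, seed = 53)
  g <- genotype_matrix(X)
  idx <- c(3, 11, 19, 27, 35)
  hs <- data.frame(hotspot = paste0("hs", 1:5), peak_marker = colnames(X)[idx],
                   n_target_genes = 5:1)
  y <- as.numeric(X[, idx] %*% rep(0.4, 5)) + rnorm(300, 0, 0.8)
  names(y) <- rownames(X)
  inc <- incremental_hotspot_variance(y, g, hs)
  expect_gt(cor(inc$curve$k, inc$curve$h2), 0.9)
})
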