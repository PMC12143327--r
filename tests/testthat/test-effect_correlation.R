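test_that("marker effects report r with a Fisher-z CI", {
  x <- rep(c(-1, 1), 20)
  eff <- marker_effect(x, x)
  expect_equal(eff$r, 1)
  expect_gt(eff$ci_hi, 0.9999)
  expect_error(marker_effect(rnorm(20), rep(1, 20)), "constant")
  expect_error(marker_effect(c(1, 2, NA, NA, NA), c(-1, 1, 1, -1, 1)), "fewer")
})

test_that("the Fisher-z CI covers zero ~95% of the time under independence", {
  set.seed(21)
  n <- 200
  covered <- vapply(seq_len(1000), function(i) {
    eff <- marker_effect(rnorm(n), sample(c(-1, 1), n, replace = TRUE))
    eff$ci_lo <= 0 && eff$ci_hi >= 0
  }, logical(1L))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("weighted Pearson reduces to the unweighted coefficient", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(weighted_pearson(x, y, rep(1, 10))$r_w, cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, rep(0.37, 10))$r_w, cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, x, runif(10) + 0.1)$r_w, 1, tolerance = 1e-12)
  expect_error(weighted_pearson(x, y, c(rep(1, 9), -1)), "positive")
  expect_error(weighted_pearson(1:2, 1:2, 1:2), "length >= 3")
})

test_that("weighted Pearson matches a brute-force moment evaluation", {
  brute <- function(x, y, w) {
    w <- w / sum(w)
    mx <- 0; my <- 0
    for (i in seq_along(x)) { mx <- mx + w[i] * x[i]; my <- my + w[i] * y[i] }
    cxy <- 0; vx <- 0; vy <- 0
    for (i in seq_along(x)) {
      cxy <- cxy + w[i] * (x[i] - mx) * (y[i] - my)
      vx <- vx + w[i] * (x[i] - mx)^2
      vy <- vy + w[i] * (y[i] - my)^2
    }
    cxy / sqrt(vx * vy)
  }
  expect_equal(weighted_pearson(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 1, 1, 10))$r_w,
               brute(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 1, 1, 10)),
               tolerance = 1e-12)
})

test_that("stepwise effects recover a single noiseless cause exactly", {
  X <- orthogonal_markers(5)
  eff <- stepwise_effects(X[, 3], X)
  expect_equal(as.numeric(eff), c(0, 0, 1, 0, 0))
  expect_identical(attr(eff, "selected"), "m3")
  expect_error(stepwise_effects(rep(1, nrow(X)), X), "constant")
})

test_that("stepwise effects equal marginal correlations for orthogonal markers", {
  X <- orthogonal_markers(6)
  b <- c(0.7, 0.55, 0.4, 0.3, 0.2, 0)
  y <- as.numeric(X %*% b)
  eff <- stepwise_effects(y, X)
  marginal <- as.numeric(cor(y, X))
  expect_equal(unname(eff)[1:5], marginal[1:5], tolerance = 1e-6)
  expect_equal(unname(eff)[6], 0)
})

test_that("stepwise effects are invariant to marker column order", {
  set.seed(14)
  X <- random_genotypes(150, 10)
  y <- X[, 2] * 0.5 - X[, 7] * 0.4 + rnorm(150)
  eff <- stepwise_effects(y, X)
  perm <- sample(10)
  eff_p <- stepwise_effects(y, X[, perm])
  expect_equal(eff_p[colnames(X)], eff, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a pure-noise trait selects few hotspot markers", {
  n_sel <- vapply(1:5, function(s) {
    X <- random_genotypes(300, 102, seed = s)
    set.seed(s + 500)
    length(attr(stepwise_effects(rnorm(300), X), "selected"))
  }, numeric(1L))
  expect_lt(median(n_sel), 15)
})

test_that("QTL effect correlations flag constructed proportional architectures", {
  set.seed(31)
  n <- 400
  X <- random_genotypes(n, 40)
  g <- genotype_matrix(X)
  loci <- colnames(X)[seq(1, 36, by = 6)]   # 6 well-separated eQTLs
  b <- c(0.6, -0.5, 0.4, -0.35, 0.3, 0.25)
  expr <- as.numeric(X[, loci] %*% b) + rnorm(n, 0, 0.5)
  growth <- as.numeric(X[, loci] %*% (1.6 * b)) + rnorm(n, 0, 0.5)
  E <- cbind(geneA = expr, geneB = rnorm(n))
  G <- cbind(condZ = growth)
  rownames(E) <- rownames(G) <- rownames(X)
  mk <- parse_marker_id(loci)
  eqtl <- data.frame(trait = "geneA", chrom = mk$chrom, peak_pos = mk$pos,
                     ci_lo = mk$pos - 10, ci_hi = mk$pos + 10, lod = 20)
  # geneB has only 2 eQTLs -> excluded by the min_loci gate
  eqtl2 <- rbind(eqtl, data.frame(trait = "geneB", chrom = mk$chrom[1:2],
                                  peak_pos = mk$pos[1:2], ci_lo = mk$pos[1:2] - 10,
                                  ci_hi = mk$pos[1:2] + 10, lod = 15))
  res <- qtl_effect_correlations(eqtl2, E, G, g, min_loci = 3, fdr = 0.20)
  expect_identical(unique(res$gene), "geneA")
  expect_gt(res$r_w, 0.8)
  expect_true(res$significant)
  expect_equal(res$n_loci, 6)
})

test_that("hotspot effect correlation is 1 for an identical single cause", {
  X <- orthogonal_markers(5)
  E <- cbind(gene = X[, 2] * 1.0)
  G <- cbind(cond = X[, 2] * 2.0)
  rownames(E) <- rownames(G) <- rownames(X)
  res <- hotspot_effect_correlations(E, G, X)
  expect_equal(res$r, 1, tolerance = 1e-10)
})

test_that("random marker sets are reproducible and uniform", {
  ids <- paste0("chrI:", 1:200, "_A/C")
  s1 <- random_marker_sets(ids, k = 20, n_sets = 300, seed = 7L)
  s2 <- random_marker_sets(ids, k = 20, n_sets = 300, seed = 7L)
  expect_identical(s1, s2)
  expect_true(all(lengths(s1) == 20))
  expect_true(all(!vapply(s1, anyDuplicated, integer(1L))))
  # k = n -> every set is the full list
  full <- random_marker_sets(ids[1:5], k = 5, n_sets = 3, seed = 1L)
  expect_true(all(vapply(full, setequal, logical(1L), ids[1:5])))
  # membership frequency ~ k/m within 4 sigma
  freq <- table(factor(unlist(s1), levels = ids)) / 300
  p0 <- 20 / 200
  expect_true(all(abs(freq - p0) < 4 * sqrt(p0 * (1 - p0) / 300)))
  expect_error(random_marker_sets(ids, k = 300), "exceeds")
})

test_that("split-half hotspot effect correlations agree in sign when strong", {
  p <- arch_panel()
  E <- unclass(correct_expression(p$expression, p$covariates$batch,
                                  p$covariates$od))
  G <- unclass(p$growth)
  H <- p$genotypes$geno[, p$hotspots$peak_marker]
  full <- hotspot_effect_correlations(E, G, H)
  set.seed(99)
  idx <- sample(nrow(H))
  h1 <- idx[seq_len(floor(length(idx) / 2))]
  h2 <- setdiff(idx, h1)
  r1 <- hotspot_effect_correlations(E[h1, ], G[h1, ], H[h1, ])
  r2 <- hotspot_effect_correlations(E[h2, ], G[h2, ], H[h2, ])
  m <- merge(merge(r1, r2, by = c("gene", "condition")), full,
             by = c("gene", "condition"))
  strong <- m[abs(m$r) > 0.5, ]
  expect_gt(nrow(strong), 10)
  expect_gt(mean(sign(strong$r.x) == sign(strong$r.y)), 0.9)
})
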