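# Pleiotropy versus linkage: one shared QTL or two distinct QTLs?
#
# For a pair of traits mapping to overlapping intervals, the scan compares a
# bivariate model in which both traits are driven by a single marker against
# one in which each trait has its own marker. Likelihoods are Gaussian with
# an unstructured 2x2 residual covariance estimated from the residual
# cross-products; all log-likelihoods are in log10 units so the test
# statistic is a LOD-like quantity. Significance comes from a parametric
# bootstrap under the fitted single-QTL model: a LARGE statistic rejects
# pleiotropy in favour of two distinct QTLs, so p > 0.05 supports a shared,
# pleiotropic QTL.

#' Thin markers to a target adjacent correlation
#'
#' Greedy left-to-right pass within each chromosome: a marker is kept iff
#' its genotype correlation with the last kept marker is below `r_max`; the
#' first marker of each chromosome is always kept.
#'
#' @param genotypes A [genotype_matrix()].
#' @param r_max Correlation threshold.
#' @return Character vector of retained marker IDs.
#' @export
thin_markers <- function(genotypes, r_max = 0.95) {
  X <- genotypes$geno
  mk <- genotypes$markers
  keep <- logical(nrow(mk))
  for (cc in unique(mk$chrom)) {
    idx <- which(mk$chrom == cc)
    last <- idx[1L]
    keep[last] <- TRUE
    for (i in idx[-1L]) {
      r <- suppressWarnings(cor(X[, i], X[, last]))
      if (is.na(r) || abs(r) < r_max) {
        keep[i] <- TRUE
        last <- i
      }
    }
  }
  mk$id[keep]
}

#' Candidate (gQTL, local eQTL) pairs for pleiotropy testing
#'
#' All pairs whose confidence intervals, extended by `pad` bp on each side,
#' overlap on the same chromosome and whose LOD scores are both at least
#' `lod_min`. The scan region is the smallest interval containing both
#' padded CIs.
#'
#' @param gqtl Growth-QTL table.
#' @param local_eqtl Local-eQTL table.
#' @param lod_min Minimum LOD for both members.
#' @param pad CI extension in bp.
#' @return data.frame with `condition`, `gene`, `chrom`, region bounds and
#'   the two LODs.
#' @export
candidate_pairs <- function(gqtl, local_eqtl, lod_min = 10, pad = 5000) {
  g <- gqtl[gqtl$lod >= lod_min, , drop = FALSE]
  e <- local_eqtl[local_eqtl$lod >= lod_min, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(g))) {
    j <- which(e$chrom == g$chrom[i] &
                 .int_overlaps(g$ci_lo[i] - pad, g$ci_hi[i] + pad,
                               e$ci_lo - pad, e$ci_hi + pad))
    if (!length(j)) next
    rows[[length(rows) + 1L]] <- data.frame(
      condition = g$trait[i], gene = e$trait[j], chrom = g$chrom[i],
      lo = pmax(1, pmin(g$ci_lo[i], e$ci_lo[j]) - pad),
      hi = pmax(g$ci_hi[i], e$ci_hi[j]) + pad,
      lod_gqtl = g$lod[i], lod_eqtl = e$lod[j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition = character(0), gene = character(0),
                      chrom = character(0), lo = numeric(0), hi = numeric(0),
                      lod_gqtl = numeric(0), lod_eqtl = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# residuals of y (vector) on [1, x] for every column of Xc (centered);
# returns n x k matrix
.marker_residuals <- function(y, Xc, ssx) {
  yc <- y - mean(y)
  b <- as.numeric(crossprod(Xc, yc)) / ssx
  yc - sweep(Xc, 2L, b, `*`)
}

# log10-likelihood surface of the two-QTL model (and its diagonal = one-QTL)
.ll_surface <- function(y1, y2, Xc, ssx, n) {
  R1 <- .marker_residuals(y1, Xc, ssx)
  R2 <- .marker_residuals(y2, Xc, ssx)
  rss1 <- colSums(R1^2); rss2 <- colSums(R2^2)
  C <- crossprod(R1, R2)
  dets <- outer(rss1, rss2) - C^2
  if (any(dets <= 0)) {
    # singular residual covariance: ridge the cross-product matrix
    rss1 <- rss1 + 1e-8; rss2 <- rss2 + 1e-8
    dets <- outer(rss1, rss2) - C^2
    attr(dets, "ridged") <- TRUE
  }
  -(n / 2) * log10(dets / n^2)
}

#' Single-pleiotropic-QTL versus two-distinct-QTLs test
#'
#' Scans all markers of the region for the best single shared QTL (both
#' traits regressed on the same marker) and all ordered marker pairs for the
#' best two-QTL fit (each trait on its own marker), with an unstructured
#' 2x2 residual covariance. The test statistic is
#' `lrt = max log10 L(two-QTL) - max log10 L(one-QTL)` (non-negative: the
#' two-QTL surface contains the one-QTL fit on its diagonal). Significance
#' is assessed by parametric bootstrap from the fitted one-QTL model, with
#' `p = (1 + #(lrt* >= lrt)) / (1 + n_boot)`. Profile LOD curves report, for
#' each trait, the two-QTL log10-likelihood as its QTL position varies with
#' the other trait's QTL fixed at the joint optimum, minus the one-QTL
#' maximum.
#'
#' @param y1,y2 Trait vectors (aligned with the genotype rows).
#' @param region_genotypes Genotypes at the (thinned) region markers,
#'   segregants x markers; needs >= 3 markers for a valid test.
#' @param n_boot Parametric-bootstrap replicates.
#' @param seed Integer seed.
#' @return list of class `pleiotropy_result`: `lrt`, `p`, `n_boot`,
#'   `best_single`, `best_pair`, `profile` (data.frame marker/lod1/lod2),
#'   `verdict` (`"pleiotropic"`, `"distinct"`, or `"untestable"`), `n`.
#' @export
pleiotropy_test <- function(y1, y2, region_genotypes, n_boot = 1000, seed = 1L) {
  X <- as.matrix(region_genotypes)
  k <- ncol(X)
  if (k < 3L) {
    return(structure(list(lrt = NA_real_, p = NA_real_, n_boot = n_boot,
                          best_single = NA_character_, best_pair = c(NA, NA),
                          profile = NULL, verdict = "untestable", n = NA_integer_),
                     class = "pleiotropy_result"))
  }
  ok <- !is.na(y1) & !is.na(y2)
  y1 <- y1[ok]; y2 <- y2[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y1)
  if (n < 10L) stop("fewer than 10 jointly observed segregants")
  if (sd(y1) == 0 || sd(y2) == 0) stop("constant trait in the scan region")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  ssx <- pmax(colSums(Xc^2), 1e-12)
  ll <- .ll_surface(y1, y2, Xc, ssx, n)
  ll1 <- diag(ll)
  L1 <- max(ll1)
  m_star <- which.max(ll1)
  pair <- arrayInd(which.max(ll), dim(ll))
  lrt <- max(ll) - L1
  lrt <- max(lrt, 0)
  prof1 <- ll[, pair[2L]] - L1
  prof2 <- ll[pair[1L], ] - L1
  # parametric bootstrap under the fitted one-QTL model at m_star
  xb <- X[, m_star]
  Z <- cbind(1, xb)
  fit1 <- lm.fit(Z, y1); fit2 <- lm.fit(Z, y2)
  Rb <- cbind(fit1$residuals, fit2$residuals)
  V <- crossprod(Rb) / n
  if (det(V) <= 0) V <- V + diag(1e-8, 2L)
  cholV <- chol(V)
  mu1 <- fit1$fitted.values; mu2 <- fit2$fitted.values
  set.seed(seed)
  lrt_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    Eb <- matrix(rnorm(2L * n), n, 2L) %*% cholV
    llb <- .ll_surface(mu1 + Eb[, 1L], mu2 + Eb[, 2L], Xc, ssx, n)
    lrt_boot[b] <- max(max(llb) - max(diag(llb)), 0)
  }
  p <- (1 + sum(lrt_boot >= lrt)) / (1 + n_boot)
  mknames <- colnames(X)
  if (is.null(mknames)) mknames <- paste0("m", seq_len(k))
  structure(list(
    lrt = lrt, p = p, n_boot = n_boot,
    best_single = mknames[m_star],
    best_pair = c(mknames[pair[1L]], mknames[pair[2L]]),
    profile = data.frame(marker = mknames, lod1 = prof1, lod2 = prof2,
                         stringsAsFactors = FALSE),
    verdict = if (p > 0.05) "pleiotropic" else "distinct",
    n = n), class = "pleiotropy_result")
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  if (x$verdict == "untestable") {
    cat("pleiotropy test: untestable (< 3 markers in region)\n")
  } else {
    cat(sprintf("pleiotropy test: lrt = %.3f, p = %.4g (%d bootstraps) -> %s\n",
                x$lrt, x$p, x$n_boot, x$verdict))
  }
  invisible(x)
}

#' Markers of a scan region
#'
#' @param genotypes A [genotype_matrix()].
#' @param chrom Chromosome name.
#' @param lo,hi Region bounds (bp, inclusive).
#' @param thinned Optional character vector of retained marker IDs (e.g. from
#'   [thin_markers()]); region markers are intersected with it.
#' @return Genotype submatrix (segregants x region markers).
#' @export
region_genotypes <- function(genotypes, chrom, lo, hi, thinned = NULL) {
  mk <- genotypes$markers
  sel <- mk$chrom == chrom & mk$pos >= lo & mk$pos <= hi
  if (!is.null(thinned)) sel <- sel & mk$id %in% thinned
  genotypes$geno[, mk$id[sel], drop = FALSE]
}
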