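# Per-locus effect estimation and effect-effect correlations.
#
# A QTL effect is measured on the correlation scale: the Pearson coefficient
# between a trait and the +/-1 genotype at a peak marker, with a 95% CI from
# the Fisher z-transform. Effects of a gene's eQTLs on its expression are
# then correlated with the same loci's effects on growth (weighted by the
# inverse product of the CI widths), and hotspot effect vectors built by a
# forward-stepwise scan are correlated between expression and growth.

#' Trait-genotype effect at one marker
#'
#' Pearson correlation with a 95% CI from the Fisher z-transform
#' (`z +- 1.96/sqrt(n - 3)`, back-transformed).
#'
#' @param trait Numeric trait vector (NA allowed).
#' @param genotype Numeric +/-1 genotype vector.
#' @return data.frame with `r`, `ci_lo`, `ci_hi`, `n`.
#' @export
marker_effect <- function(trait, genotype) {
  ok <- !is.na(trait) & !is.na(genotype)
  if (sum(ok) < 4L) stop("fewer than 4 jointly observed segregants")
  x <- genotype[ok]; y <- trait[ok]
  if (sd(x) == 0) stop("constant genotype column")
  r <- cor(y, x)
  n <- length(x)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- qnorm(0.975) / sqrt(n - 3)
  data.frame(r = r, ci_lo = tanh(z - hw), ci_hi = tanh(z + hw), n = n)
}

# Vectorized effects of one trait at many markers; returns r, CI width, n.
.effects_at <- function(trait, X) {
  ok <- !is.na(trait)
  n <- sum(ok)
  r <- as.numeric(suppressWarnings(cor(trait[ok], X[ok, , drop = FALSE])))
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  hw <- qnorm(0.975) / sqrt(n - 3)
  width <- tanh(z + hw) - tanh(z - hw)
  list(r = r, width = width, n = n)
}

#' Weighted Pearson correlation
#'
#' Weighted-moment estimator: weights are normalized to sum to 1 and the
#' coefficient is the weighted covariance over the product of weighted SDs.
#' The p-value uses `t = r * sqrt((n - 2)/(1 - r^2))` with `n` the unweighted
#' number of observations (two-sided).
#'
#' @param x,y Numeric vectors (length >= 3).
#' @param w Positive weights.
#' @return data.frame with `r_w`, `n`, `p`.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (n < 3L || length(y) != n || length(w) != n) stop("need aligned vectors of length >= 3")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  r <- cxy / sqrt(vx * vy)
  r <- min(max(r, -1), 1)
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  data.frame(r_w = r, n = n, p = 2 * pt(-abs(tt), df = n - 2))
}

#' QTL effect correlations between expression and growth
#'
#' For every gene with at least `min_loci` eQTLs, computes the effects of the
#' gene's eQTL peak markers on its (corrected) expression and on growth in
#' each condition, and correlates the two effect vectors with weights
#' `1 / (CI width on expression x CI width on growth)` (widths floored at
#' 1e-6). FDR by Benjamini-Hochberg within each condition.
#'
#' @param eqtl eQTL table (`trait` = gene, `chrom`, `peak_pos`, ...).
#' @param expression Corrected expression matrix.
#' @param growth Growth matrix.
#' @param genotypes A [genotype_matrix()].
#' @param min_loci Minimum eQTLs per gene (genes below are excluded).
#' @param fdr FDR level for the `significant` flag (the screen is run at a
#'   lenient 20% by default).
#' @return data.frame with `gene`, `condition`, `r_w`, `n_loci`, `p`, `q`,
#'   `significant`.
#' @export
qtl_effect_correlations <- function(eqtl, expression, growth, genotypes,
                                    min_loci = 3, fdr = 0.20) {
  E <- .trait_values(expression); G <- .trait_values(growth)
  common <- intersect(rownames(E), rownames(G))
  common <- intersect(common, rownames(genotypes$geno))
  E <- E[common, , drop = FALSE]; G <- G[common, , drop = FALSE]
  X <- genotypes$geno[common, , drop = FALSE]
  eqtl$marker <- .peak_marker_ids(eqtl, genotypes)
  genes <- intersect(unique(eqtl$trait), colnames(E))
  loci <- split(eqtl$marker, eqtl$trait)
  loci <- lapply(loci[genes], unique)
  loci <- loci[lengths(loci) >= min_loci]
  if (!length(loci)) stop("no gene has >= min_loci eQTL peak markers")
  # expression effects per gene at its own loci
  expr_eff <- lapply(names(loci), function(g) .effects_at(E[, g], X[, loci[[g]], drop = FALSE]))
  names(expr_eff) <- names(loci)
  all_markers <- unique(unlist(loci))
  out <- vector("list", ncol(G))
  for (ci in seq_len(ncol(G))) {
    gvec <- G[, ci]
    ok <- !is.na(gvec)
    if (sum(ok) < 4L) next
    ge <- .effects_at(gvec, X[, all_markers, drop = FALSE])
    gr <- setNames(ge$r, all_markers)
    gw <- setNames(ge$width, all_markers)
    rows <- lapply(names(loci), function(g) {
      mk <- loci[[g]]
      ee <- expr_eff[[g]]
      wexp <- pmax(ee$width, 1e-6)
      wgro <- pmax(gw[mk], 1e-6)
      if (anyNA(gr[mk]) || length(mk) < min_loci) return(NULL)
      wp <- weighted_pearson(ee$r, gr[mk], 1 / (wexp * wgro))
      data.frame(gene = g, condition = colnames(G)[ci], r_w = wp$r_w,
                 n_loci = length(mk), p = wp$p, stringsAsFactors = FALSE)
    })
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no testable gene-condition pair")
  res$q <- NA_real_
  for (cc in unique(res$condition)) {
    i <- res$condition == cc
    res$q[i] <- p.adjust(res$p[i], method = "BH")
  }
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res
}

#' Forward-stepwise hotspot effects on one trait
#'
#' Iteratively correlates the (residualized) trait with every unselected
#' hotspot marker; if the strongest |r| is significant at `p_enter`, the
#' marker's effect is recorded and its contribution regressed out of the
#' trait, until no marker reaches `p_enter`. Unselected markers get effect 0.
#' Ties in |r| resolve to the lowest marker index.
#'
#' Recorded effects are expressed on the scale of the original trait
#' (`cov(residual trait, x) / (sd(original trait) * sd(x))`) so that
#' estimates from successive steps are directly comparable; for mutually
#' orthogonal markers this equals the marginal correlation. Selection and
#' the stopping rule use the ordinary correlation test on the residualized
#' trait.
#'
#' @param trait Numeric trait vector (NA allowed; complete cases used).
#' @param hotspot_genotypes Matrix of +/-1 genotypes at the hotspot peak
#'   markers (segregants x hotspots).
#' @param p_enter Entry/stop p-value threshold.
#' @return Named numeric effect vector (length = number of hotspots) with
#'   attribute `selected` (marker names in selection order).
#' @export
stepwise_effects <- function(trait, hotspot_genotypes, p_enter = 0.05) {
  X <- as.matrix(hotspot_genotypes)
  k <- ncol(X)
  ok <- !is.na(trait)
  y <- trait[ok]; Xo <- X[ok, , drop = FALSE]
  if (sd(y) == 0) stop("constant trait")
  n <- length(y)
  sd0 <- sd(y)
  eff <- setNames(numeric(k), colnames(X))
  unsel <- rep(TRUE, k)
  selected <- character(0)
  iter <- 0L
  while (any(unsel)) {
    iter <- iter + 1L
    stopifnot(iter <= k)          # loop cannot exceed the number of markers
    s_cur <- sd(y)
    if (s_cur == 0) break         # trait fully explained
    r <- as.numeric(suppressWarnings(cor(y, Xo[, unsel, drop = FALSE])))
    r[is.na(r)] <- 0
    best <- which.max(abs(r))     # ties -> lowest index among unselected
    rb <- r[best]
    tt <- abs(rb) * sqrt((n - 2) / max(1 - rb^2, 1e-300))
    p <- 2 * pt(-tt, df = n - 2)
    if (!is.finite(p) || p >= p_enter) break
    j <- which(unsel)[best]
    eff[j] <- rb * s_cur / sd0
    xb <- Xo[, j]
    y <- y - xb * (sum((xb - mean(xb)) * y) / sum((xb - mean(xb))^2))
    y <- y - mean(y)
    unsel[j] <- FALSE
    selected <- c(selected, colnames(X)[j])
  }
  attr(eff, "selected") <- selected
  eff
}

#' Hotspot effect correlations between expression and growth
#'
#' Computes [stepwise_effects()] for every gene and every condition over the
#' same hotspot peak markers, then correlates each gene's effect vector with
#' each condition's (unweighted Pearson over the hotspot entries). Pairs in
#' which either vector is all zero are skipped. FDR by Benjamini-Hochberg
#' within each condition.
#'
#' @param expression Corrected expression matrix.
#' @param growth Growth matrix.
#' @param hotspot_genotypes Genotypes at the hotspot peak markers
#'   (segregants x hotspots), or a [genotype_matrix()] plus `markers` IDs.
#' @param fdr FDR level.
#' @param p_enter Stepwise entry threshold.
#' @return data.frame with `gene`, `condition`, `r`, `n_loci`, `p`, `q`,
#'   `significant`, plus attributes `gene_effects` and `growth_effects`
#'   (effect matrices for audit).
#' @export
hotspot_effect_correlations <- function(expression, growth, hotspot_genotypes,
                                        fdr = 0.05, p_enter = 0.05) {
  E <- .trait_values(expression); G <- .trait_values(growth)
  H <- as.matrix(hotspot_genotypes)
  common <- intersect(rownames(E), rownames(G))
  common <- intersect(common, rownames(H))
  E <- E[common, , drop = FALSE]; G <- G[common, , drop = FALSE]
  H <- H[common, , drop = FALSE]
  k <- ncol(H)
  gene_eff <- t(vapply(seq_len(ncol(E)),
                       function(j) stepwise_effects(E[, j], H, p_enter),
                       numeric(k)))
  rownames(gene_eff) <- colnames(E)
  gro_eff <- t(vapply(seq_len(ncol(G)),
                      function(j) stepwise_effects(G[, j], H, p_enter),
                      numeric(k)))
  rownames(gro_eff) <- colnames(G)
  rows <- vector("list", ncol(G))
  for (ci in seq_len(ncol(G))) {
    gv <- gro_eff[ci, ]
    if (all(gv == 0)) next
    keep <- apply(gene_eff, 1L, function(v) any(v != 0))
    if (!any(keep)) next
    sub <- gene_eff[keep, , drop = FALSE]
    r <- as.numeric(cor(t(sub), gv))
    tt <- r * sqrt((k - 2) / pmax(1 - r^2, 1e-300))
    rows[[ci]] <- data.frame(gene = rownames(sub), condition = colnames(G)[ci],
                             r = r, n_loci = k, p = 2 * pt(-abs(tt), df = k - 2),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable gene-condition pair (all-zero effect vectors)")
  res <- res[!is.na(res$r), , drop = FALSE]
  res$q <- NA_real_
  for (cc in unique(res$condition)) {
    i <- res$condition == cc
    res$q[i] <- p.adjust(res$p[i], method = "BH")
  }
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  attr(res, "gene_effects") <- gene_eff
  attr(res, "growth_effects") <- gro_eff
  res
}

#' Random marker sets
#'
#' Draws `n_sets` sets of `k` markers uniformly without replacement (within
#' each set), reproducibly from `seed`. Used as null controls for
#' hotspot-based analyses.
#'
#' @param marker_ids Character vector of marker IDs (or a
#'   [genotype_matrix()]).
#' @param k Set size.
#' @param n_sets Number of sets.
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
random_marker_sets <- function(marker_ids, k = 102, n_sets = 1000, seed = 1L) {
  if (inherits(marker_ids, "genotype_matrix")) marker_ids <- marker_ids$markers$id
  if (k > length(marker_ids)) stop("k exceeds the number of markers")
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) sample(marker_ids, k))
}
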