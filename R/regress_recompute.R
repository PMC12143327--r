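# eQTL sources of genetic correlations: remove a marker set's effects from
# both expression and growth and recompute the correlations on residuals.

#' Regress a marker set out of a trait
#'
#' Joint multiple-regression residuals of the trait on all markers of the set
#' simultaneously (plus intercept). Collinear columns are handled by the
#' pivoted QR decomposition (aliased columns dropped). Missing trait values
#' are preserved in place. An empty set returns the centered trait.
#'
#' @param trait Numeric trait vector (NA allowed).
#' @param genotype_set Matrix of genotype columns (segregants x markers), or
#'   NULL/zero columns for the empty set.
#' @return Residual vector, same length and NA pattern as `trait`.
#' @export
regress_out <- function(trait, genotype_set = NULL) {
  out <- rep(NA_real_, length(trait))
  ok <- !is.na(trait)
  y <- trait[ok]
  if (is.null(genotype_set) || NCOL(genotype_set) == 0L) {
    out[ok] <- y - mean(y)
    return(out)
  }
  X <- as.matrix(genotype_set)[ok, , drop = FALSE]
  if (ncol(X) >= length(y) - 1L) stop("more markers than observations - 2")
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  out[ok] <- fit$residuals
  out
}

#' Recompute genetic correlations after removing marker sets
#'
#' For each gene (and each condition), removes the effects of the gene's
#' marker set from BOTH its expression and the growth trait, recomputes the
#' Pearson correlation on the residuals, and pairs it with the uncorrected
#' coefficient.
#'
#' @param expression Corrected expression matrix.
#' @param growth Growth matrix.
#' @param genotypes A [genotype_matrix()].
#' @param sets Either a character vector of marker IDs applied to every gene
#'   (e.g. all hotspot peaks), or a named list (by gene) of per-gene marker
#'   IDs (e.g. each gene's local or trans eQTL peaks); genes without an
#'   entry are skipped.
#' @param label Label stored in the `set` column.
#' @param before Optional result of [genetic_correlations()] used to supply
#'   `r_before` and to restrict to its rows; computed when NULL.
#' @param restrict_significant If TRUE, only pairs significant in `before`
#'   are reported.
#' @return data.frame with `gene`, `condition`, `set`, `n_markers`,
#'   `r_before`, `r_after`.
#' @export
recompute_correlations <- function(expression, growth, genotypes, sets,
                                   label = "set", before = NULL,
                                   restrict_significant = TRUE) {
  E <- .trait_values(expression); G <- .trait_values(growth)
  common <- intersect(intersect(rownames(E), rownames(G)),
                      rownames(genotypes$geno))
  E <- E[common, , drop = FALSE]; G <- G[common, , drop = FALSE]
  X <- genotypes$geno[common, , drop = FALSE]
  if (is.null(before)) {
    before <- suppressMessages(genetic_correlations(E, G))
  }
  keep <- if (restrict_significant) before[before$significant, , drop = FALSE] else before
  per_gene <- is.list(sets) && !is.data.frame(sets)
  if (per_gene) keep <- keep[keep$gene %in% names(sets), , drop = FALSE]
  genes <- unique(keep$gene)
  genes <- intersect(genes, colnames(E))
  rows <- vector("list", length(genes))
  # growth residuals are gene-set specific; cache by marker-set signature
  gro_cache <- new.env(parent = emptyenv())
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ids <- if (per_gene) sets[[g]] else sets
    ids <- intersect(ids, colnames(X))
    Xs <- X[, ids, drop = FALSE]
    e_res <- regress_out(E[, g], Xs)
    conds <- keep$condition[keep$gene == g]
    key <- paste(ids, collapse = ";")
    rr <- vapply(conds, function(cc) {
      ck <- paste(key, cc)
      if (is.null(gro_cache[[ck]])) gro_cache[[ck]] <- regress_out(G[, cc], Xs)
      suppressWarnings(cor(e_res, gro_cache[[ck]], use = "pairwise.complete.obs"))
    }, numeric(1L))
    rows[[gi]] <- data.frame(gene = g, condition = conds, set = label,
                             n_markers = length(ids),
                             r_before = keep$r[keep$gene == g],
                             r_after = rr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize before/after correlation magnitudes
#'
#' Median relative drop in |r| (`(|r_before| - |r_after|) / |r_before|`,
#' pairs with `|r_before| < 1e-6` excluded from the median and counted
#' separately) and a paired two-sided Wilcoxon signed-rank test on the |r|
#' distributions.
#'
#' @param report Output of [recompute_correlations()] (one set label, or
#'   several - summarized per label).
#' @return data.frame with `set`, `n_pairs`, `n_excluded`,
#'   `median_rel_drop`, `wilcoxon_p`.
#' @export
compare_correlations <- function(report) {
  out <- lapply(split(report, report$set), function(d) {
    usable <- abs(d$r_before) >= 1e-6
    dd <- d[usable, , drop = FALSE]
    if (!nrow(dd)) {
      return(data.frame(set = d$set[1L], n_pairs = 0L,
                        n_excluded = sum(!usable),
                        median_rel_drop = NA_real_, wilcoxon_p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    drop <- (abs(dd$r_before) - abs(dd$r_after)) / abs(dd$r_before)
    wp <- if (all(abs(dd$r_before) == abs(dd$r_after))) 1 else
      suppressWarnings(wilcox.test(abs(dd$r_before), abs(dd$r_after),
                                   paired = TRUE))$p.value
    data.frame(set = d$set[1L], n_pairs = nrow(dd),
               n_excluded = sum(!usable),
               median_rel_drop = median(drop, na.rm = TRUE),
               wilcoxon_p = wp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
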