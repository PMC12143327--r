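# Signed gene-set enrichment of correlation hit lists and trait clustering.

#' Signed gene-set enrichment of significant correlations
#'
#' Per condition, the significantly correlated genes are split by correlation
#' sign ('positive': r > 0, 'negative': r < 0) and each gene set is tested
#' for enrichment in each direction with a one-sided Fisher's exact
#' (hypergeometric upper tail) test against the background. The fold is
#' observed/expected with expected = |list| * |term in background| /
#' |background|. Terms are retained at `p < p_keep`; when a term passes in
#' both directions only the direction with the larger |log2 fold| is kept.
#'
#' @param correlations Result of [genetic_correlations()] (needs `gene`,
#'   `condition`, `r`, `significant`).
#' @param term_sets Named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param background Character vector of all tested gene IDs (must contain
#'   every listed gene).
#' @param p_keep Retention threshold.
#' @return data.frame with `condition`, `term`, `direction`, `fold`,
#'   `log2_fold`, `p`, `n_observed`, `n_expected`.
#' @export
signed_enrichment <- function(correlations, term_sets, background,
                              p_keep = 0.001) {
  background <- unique(background)
  N <- length(background)
  term_sets <- lapply(term_sets, function(s) intersect(s, background))
  empty <- lengths(term_sets) == 0L
  if (any(empty)) {
    message(sum(empty), " term(s) with zero background overlap skipped")
    term_sets <- term_sets[!empty]
  }
  rows <- list()
  for (cc in unique(correlations$condition)) {
    d <- correlations[correlations$condition == cc & correlations$significant, ,
                      drop = FALSE]
    for (dir in c("positive", "negative")) {
      hits <- if (dir == "positive") d$gene[d$r > 0] else d$gene[d$r < 0]
      hits <- intersect(hits, background)
      k <- length(hits)
      if (!k) next
      for (tn in names(term_sets)) {
        term <- term_sets[[tn]]
        K <- length(term)
        obs <- length(intersect(hits, term))
        expd <- k * K / N
        p <- phyper(obs - 1L, K, N - K, k, lower.tail = FALSE)
        if (p < p_keep) {
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cc, term = tn, direction = dir,
            fold = obs / expd, log2_fold = log2(pmax(obs, 0.5) / expd),
            p = p, n_observed = obs, n_expected = expd,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(condition = character(0), term = character(0),
                      direction = character(0), fold = numeric(0),
                      log2_fold = numeric(0), p = numeric(0),
                      n_observed = integer(0), n_expected = numeric(0)))
  }
  # both-directions rule: keep the direction with the larger |log2 fold|
  key <- paste(res$condition, res$term)
  keep <- unlist(lapply(split(seq_len(nrow(res)), key), function(i) {
    if (length(i) == 1L) return(i)
    i[which.max(abs(res$log2_fold[i]))]
  }))
  res <- res[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster traits on signed enrichment profiles
#'
#' Builds a conditions x terms matrix of signed log2 fold enrichments
#' (negative-direction terms enter with a negative sign; absent terms are 0)
#' and partitions the conditions by k-means with multiple restarts.
#'
#' @param enrichment Result of [signed_enrichment()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Named integer vector of cluster labels with attribute `profile`
#'   (the matrix clustered).
#' @export
cluster_traits <- function(enrichment, k = 3, seed = 1L, nstart = 50) {
  conds <- unique(enrichment$condition)
  if (k > length(conds)) stop("k exceeds the number of conditions")
  terms <- unique(enrichment$term)
  M <- matrix(0, length(conds), length(terms), dimnames = list(conds, terms))
  signed <- ifelse(enrichment$direction == "negative",
                   -abs(enrichment$log2_fold), abs(enrichment$log2_fold))
  M[cbind(match(enrichment$condition, conds), match(enrichment$term, terms))] <- signed
  set.seed(seed)
  U <- unique(M)
  if (k >= nrow(U)) {
    # at most one distinct profile per cluster: exact optimum (WSS = 0)
    lab_u <- seq_len(nrow(U))
  } else {
    lab_u <- kmeans(U, centers = k, nstart = nstart)$cluster
  }
  key <- apply(M, 1L, paste, collapse = "\r")
  key_u <- apply(U, 1L, paste, collapse = "\r")
  out <- setNames(lab_u[match(key, key_u)], conds)
  attr(out, "profile") <- M
  out
}

#' Mean genetic correlation of gene signatures
#'
#' Arithmetic mean of the correlation coefficients over the members of each
#' gene group present in the table, per condition.
#'
#' @param correlations Result of [genetic_correlations()].
#' @param groups Named list of gene-ID vectors.
#' @return data.frame with `condition`, `group`, `mean_r`, `n_genes`.
#' @export
signature_means <- function(correlations, groups) {
  rows <- list()
  for (cc in unique(correlations$condition)) {
    d <- correlations[correlations$condition == cc, , drop = FALSE]
    for (gn in names(groups)) {
      members <- intersect(groups[[gn]], d$gene)
      if (!length(members)) {
        warning("group '", gn, "' has no genes in the correlation table")
        mr <- NA_real_
      } else {
        mr <- mean(d$r[match(members, d$gene)])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cc, group = gn, mean_r = mr, n_genes = length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
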