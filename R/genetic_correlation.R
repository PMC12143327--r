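# Expression-growth genetic correlations.
#
# The central quantity is the Pearson correlation, across segregants, between
# a transcript's (covariate-corrected) abundance measured in a baseline
# culture and colony growth measured in an independent experiment. Because
# the two measurements share nothing but the segregants' genotypes, the
# correlation is attributable to shared genetic effects.

#' Remove batch and culture-density effects from expression
#'
#' Per gene, returns the residuals of the least-squares fit of expression on
#' batch indicator contrasts plus a linear OD600 term
#' (`E = alpha * B + beta * OD + R`). Residuals are orthogonal to every batch
#' indicator and to OD. Segregants with a missing covariate are dropped for
#' all genes.
#'
#' @param expression Expression [trait_matrix()] (or numeric matrix),
#'   segregants x genes.
#' @param batch Factor (or coercible) of batch labels, aligned with rows.
#' @param od Numeric OD600 covariate, aligned with rows.
#' @return Residual expression matrix (class `trait_matrix`), possibly with
#'   fewer rows if covariates were missing.
#' @export
correct_expression <- function(expression, batch, od) {
  E <- .trait_values(expression)
  if (length(batch) != nrow(E) || length(od) != nrow(E)) {
    stop("covariates must be aligned with the expression rows")
  }
  keep <- !is.na(batch) & !is.na(od)
  if (!all(keep)) {
    message(sum(!keep), " segregant(s) dropped for missing covariates")
    E <- E[keep, , drop = FALSE]; batch <- batch[keep]; od <- od[keep]
  }
  batch <- droplevels(as.factor(batch))
  small <- table(batch) < 2L
  if (any(small)) {
    warning("batch level(s) with < 2 segregants retained: ",
            paste(names(small)[small], collapse = ", "))
  }
  X <- stats::model.matrix(~ batch + od)
  if (anyNA(E)) {
    R <- E
    for (j in seq_len(ncol(E))) {
      ok <- !is.na(E[, j])
      fit <- lm.fit(X[ok, , drop = FALSE], E[ok, j])
      R[ok, j] <- fit$residuals
    }
  } else {
    R <- lm.fit(X, E)$residuals
    dimnames(R) <- dimnames(E)
  }
  trait_matrix(R, "expression")
}

#' Standardize trait columns to mean 0, SD 1
#'
#' Missing values are ignored in the moments and preserved in the output.
#'
#' @param x A [trait_matrix()] or numeric matrix.
#' @return Standardized matrix of the same class/kind.
#' @export
standardize_traits <- function(x) {
  kind <- attr(x, "kind")
  m <- .trait_values(x)
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2L, sd, na.rm = TRUE)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) stop("constant or empty column(s): ",
                     paste(colnames(m)[bad], collapse = ", "))
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
  if (!is.null(kind)) out <- trait_matrix(out, kind)
  out
}

# ---- Storey q-values --------------------------------------------------------

#' Storey q-values with smoother pi0 estimate
#'
#' Estimates the null proportion pi0 by the natural-cubic-spline smoother
#' over the lambda grid 0.05..0.95 and converts p-values to q-values
#' (`q_i = pi0 * min_{p_j >= p_i} p_j * m / rank_j`). With fewer than 100
#' p-values, or when the smoother fails or returns a non-positive value, it
#' falls back to Benjamini-Hochberg (pi0 = 1).
#'
#' @param p Numeric vector of p-values (NA allowed, propagated).
#' @param lambda Grid of lambda values for the pi0 smoother.
#' @return Vector of q-values with attribute `pi0`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  pi0 <- 1
  if (m >= 100L) {
    pi0_lambda <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1L))
    pi0_try <- tryCatch({
      fit <- smooth.spline(lambda, pi0_lambda, df = 3)
      predict(fit, x = max(lambda))$y
    }, error = function(e) NA_real_)
    if (is.finite(pi0_try) && pi0_try > 0) pi0 <- min(pi0_try, 1)
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  qv <- pi0 * pmin(1, cummin(pv[o] * m / rank(pv, ties.method = "max")[o]))[ro]
  q[ok] <- pmin(qv, 1)
  attr(q, "pi0") <- pi0
  q
}

# ---- genetic correlations ---------------------------------------------------

#' Expression-growth genetic correlations with within-trait FDR
#'
#' Pairwise-complete Pearson correlation between every gene and every growth
#' condition, with two-sided p-values from the t distribution (n - 2 df) and
#' Storey q-values computed over genes within each condition. Pairs with
#' fewer than 3 overlapping segregants are dropped (with a message).
#'
#' @param expression Corrected expression matrix, segregants x genes.
#' @param growth Growth matrix, segregants x conditions (NA allowed).
#' @param fdr FDR level for the `significant` flag.
#' @return data.frame with columns `gene`, `condition`, `r`, `n`, `p`, `q`,
#'   `significant`.
#' @export
genetic_correlations <- function(expression, growth, fdr = 0.05) {
  E <- .trait_values(expression)
  G <- .trait_values(growth)
  common <- intersect(rownames(E), rownames(G))
  if (length(common) < 3L) stop("fewer than 3 shared segregants")
  E <- E[common, , drop = FALSE]; G <- G[common, , drop = FALSE]
  R <- suppressWarnings(cor(E, G, use = "pairwise.complete.obs"))
  N <- crossprod(!is.na(E) + 0, !is.na(G) + 0)
  res <- data.frame(
    gene = rep(colnames(E), times = ncol(G)),
    condition = rep(colnames(G), each = ncol(E)),
    r = as.vector(R),
    n = as.vector(N),
    stringsAsFactors = FALSE)
  drop <- res$n < 3L | is.na(res$r)
  if (any(drop)) {
    message(sum(drop), " gene-condition pair(s) skipped (< 3 overlapping segregants)")
    res <- res[!drop, , drop = FALSE]
  }
  tt <- res$r * sqrt((res$n - 2) / pmax(1 - res$r^2, 1e-300))
  res$p <- 2 * pt(-abs(tt), df = res$n - 2)
  res$q <- NA_real_
  for (cc in unique(res$condition)) {
    i <- res$condition == cc
    res$q[i] <- storey_qvalue(res$p[i])
  }
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res
}

#' Remove the base-medium component from a growth condition
#'
#' Residuals of the simple regression of growth in a condition on growth in
#' its base medium (`G_i = alpha * G_b + R`), on jointly non-missing
#' segregants; other entries stay NA.
#'
#' @param condition Numeric growth vector for the condition.
#' @param base Numeric growth vector for the base medium (YNB or YPD),
#'   aligned with `condition`.
#' @return Residual vector of the same length.
#' @export
correct_base_medium <- function(condition, base) {
  if (length(condition) != length(base)) stop("vectors must be aligned")
  out <- rep(NA_real_, length(condition))
  ok <- !is.na(condition) & !is.na(base)
  if (sum(ok) < 3L) stop("fewer than 3 jointly measured segregants")
  fit <- lm.fit(cbind(1, base[ok]), condition[ok])
  out[ok] <- fit$residuals
  out
}

#' Base-medium correction across a growth matrix
#'
#' Applies [correct_base_medium()] per condition, using `base_map` (named
#' character vector mapping each condition to its base-medium column).
#' Conditions mapped to themselves (the base media are themselves among the
#' conditions) are skipped with a message and excluded from the output.
#'
#' @param growth Growth matrix, segregants x conditions.
#' @param base_map Named character vector, `base_map[condition] = base column`.
#' @return Residual growth matrix for the corrected conditions.
#' @export
correct_base_media <- function(growth, base_map) {
  G <- .trait_values(growth)
  conds <- colnames(G)
  miss <- setdiff(conds, names(base_map))
  if (length(miss)) stop("no base-medium assignment for: ",
                         paste(miss, collapse = ", "))
  keep <- conds[base_map[conds] != conds]
  skipped <- setdiff(conds, keep)
  if (length(skipped)) message("self-correction skipped for: ",
                               paste(skipped, collapse = ", "))
  out <- sapply(keep, function(cc) correct_base_medium(G[, cc], G[, base_map[[cc]]]))
  rownames(out) <- rownames(G)
  out
}

#' Principal-component spectrum of the growth traits
#'
#' Drops traits measured in fewer than `min_measured_frac` of segregants,
#' then drops segregants with any missing value among the retained traits,
#' standardizes the columns, and returns the eigen-spectrum as percent
#' variance per component.
#'
#' @param growth Growth matrix, segregants x conditions.
#' @param min_measured_frac Minimum fraction of segregants measured.
#' @return data.frame with `component`, `var_pct`, `cum_pct`; attributes
#'   `n_traits`, `n_segregants`, `dropped_traits`.
#' @export
growth_trait_pca <- function(growth, min_measured_frac = 0.20) {
  G <- .trait_values(growth)
  cover <- colMeans(!is.na(G))
  keep <- cover >= min_measured_frac
  if (sum(keep) < 2L) stop("fewer than 2 traits pass the coverage filter")
  G <- G[, keep, drop = FALSE]
  cc <- complete.cases(G)
  if (sum(cc) < 3L) stop("fewer than 3 segregants with complete measurements")
  Z <- standardize_traits(G[cc, , drop = FALSE])
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  v <- pc$sdev^2
  pct <- 100 * v / sum(v)
  out <- data.frame(component = seq_along(pct), var_pct = pct,
                    cum_pct = cumsum(pct))
  attr(out, "n_traits") <- ncol(Z)
  attr(out, "n_segregants") <- sum(cc)
  attr(out, "dropped_traits") <- colnames(.trait_values(growth))[!keep]
  out
}

#' Genetic correlations in downsampled segregant panels
#'
#' Samples subsets of segregants without replacement and records, per subset
#' size and condition, the median over replicates of the number of
#' significant correlations (at `fdr`) and of the median |r| among them.
#'
#' @param expression Corrected expression matrix.
#' @param growth Growth matrix.
#' @param sizes Subset sizes.
#' @param reps Replicates per size.
#' @param fdr FDR level.
#' @param seed Integer seed.
#' @return data.frame with `size`, `condition`, `n_significant`,
#'   `median_abs_r` (medians over replicates).
#' @export
downsample_correlations <- function(expression, growth,
                                    sizes = c(250, 500, 750), reps = 5,
                                    fdr = 0.05, seed = 1L) {
  E <- .trait_values(expression); G <- .trait_values(growth)
  common <- intersect(rownames(E), rownames(G))
  if (any(sizes > length(common))) stop("subset size exceeds panel size")
  set.seed(seed)
  rows <- list()
  for (s in sizes) {
    per_rep <- vector("list", reps)
    for (r in seq_len(reps)) {
      idx <- sample(common, s)
      gc <- suppressMessages(
        genetic_correlations(E[idx, , drop = FALSE], G[idx, , drop = FALSE], fdr))
      agg <- lapply(split(gc, gc$condition), function(d) {
        sig <- d[d$significant, , drop = FALSE]
        data.frame(condition = d$condition[1L], n_significant = nrow(sig),
                   median_abs_r = if (nrow(sig)) median(abs(sig$r)) else NA_real_,
                   stringsAsFactors = FALSE)
      })
      per_rep[[r]] <- do.call(rbind, agg)
    }
    all <- do.call(rbind, per_rep)
    med <- lapply(split(all, all$condition), function(d) {
      data.frame(size = s, condition = d$condition[1L],
                 n_significant = median(d$n_significant),
                 median_abs_r = median(d$median_abs_r, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    rows[[as.character(s)]] <- do.call(rbind, med)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
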