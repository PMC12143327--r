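# Mediation of a hotspot's growth effect through a transcript.
#
# Two least-squares equations:
#   mediator = alpha * genotype + e1
#   outcome  = beta * genotype + gamma * mediator + e2
# The total genotype effect decomposes as beta + alpha*gamma, and the
# proportion mediated is alpha*gamma / (beta + alpha*gamma). Inference on
# the indirect effect alpha*gamma uses a nonparametric bootstrap over
# segregants.

# closed-form fits of the two mediation equations on complete data
.mediation_coefs <- function(x, m, y) {
  xc <- x - mean(x); mc <- m - mean(m); yc <- y - mean(y)
  sxx <- sum(xc^2)
  alpha <- sum(xc * mc) / sxx
  # y ~ x + m via 2x2 normal equations on centered data
  sxm <- sum(xc * mc); smm <- sum(mc^2)
  sxy <- sum(xc * yc); smy <- sum(mc * yc)
  det <- sxx * smm - sxm^2
  if (abs(det) < 1e-12) return(c(alpha = alpha, beta = NA_real_, gamma = NA_real_))
  beta <- (smm * sxy - sxm * smy) / det
  gamma <- (sxx * smy - sxm * sxy) / det
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Mediation of a genotype effect through one mediator
#'
#' Fits the two linear models, computes the indirect effect `alpha * gamma`,
#' the direct effect `beta` and the proportion mediated
#' `alpha*gamma / (beta + alpha*gamma)`, and derives a two-sided bootstrap
#' p-value for the indirect effect as
#' `min(1, 2 * (1 + min(#{<=0}, #{>=0})) / (1 + n_boot))` over `n_boot`
#' nonparametric resamples of segregants.
#'
#' @param genotype Numeric +/-1 genotype vector at the hotspot peak marker.
#' @param mediator Numeric mediator vector (corrected expression).
#' @param outcome Numeric outcome vector (growth).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param min_n Minimum jointly observed segregants.
#' @return data.frame with `alpha`, `beta`, `gamma`, `indirect`,
#'   `prop_mediated` (NA and flagged when the total effect is ~0), `p`, `n`,
#'   `undefined_total`.
#' @export
mediate <- function(genotype, mediator, outcome, n_boot = 1000, seed = 1L,
                    min_n = 30L) {
  ok <- !is.na(genotype) & !is.na(mediator) & !is.na(outcome)
  if (sum(ok) < min_n) stop("fewer than ", min_n, " jointly observed segregants")
  x <- genotype[ok]; m <- mediator[ok]; y <- outcome[ok]
  if (sd(x) == 0) stop("constant genotype")
  n <- length(x)
  cf <- .mediation_coefs(x, m, y)
  indirect <- cf[["alpha"]] * cf[["gamma"]]
  total <- cf[["beta"]] + indirect
  undefined <- !is.finite(total) || abs(total) < 1e-12
  prop <- if (undefined) NA_real_ else indirect / total
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  Xb <- matrix(x[idx], n); Mb <- matrix(m[idx], n); Yb <- matrix(y[idx], n)
  # vectorized cross-moments per bootstrap column
  cx <- sweep(Xb, 2L, colMeans(Xb)); cm <- sweep(Mb, 2L, colMeans(Mb))
  cy <- sweep(Yb, 2L, colMeans(Yb))
  sxx <- colSums(cx^2); sxm <- colSums(cx * cm); smm <- colSums(cm^2)
  sxy <- colSums(cx * cy); smy <- colSums(cm * cy)
  alpha_b <- sxm / sxx
  det <- sxx * smm - sxm^2
  gamma_b <- (sxx * smy - sxm * sxy) / det
  ind_b <- alpha_b * gamma_b
  ind_b <- ind_b[is.finite(ind_b)]
  nb <- length(ind_b)
  p <- min(1, 2 * (1 + min(sum(ind_b <= 0), sum(ind_b >= 0))) / (1 + nb))
  data.frame(alpha = cf[["alpha"]], beta = cf[["beta"]], gamma = cf[["gamma"]],
             indirect = indirect, prop_mediated = prop, p = p, n = n,
             undefined_total = undefined)
}

#' Mediation screen across a hotspot's target genes
#'
#' Runs [mediate()] for every gene of the list against the same hotspot
#' genotype and growth outcome, and applies Benjamini-Hochberg FDR across
#' the screened genes. The mediation sign (positive or negative) is the sign
#' of the indirect effect.
#'
#' @param genotype Genotype vector at the hotspot peak marker.
#' @param expression Corrected expression matrix (segregants x genes).
#' @param genes Character vector of gene IDs to screen.
#' @param outcome Growth vector.
#' @param n_boot Bootstrap replicates per gene.
#' @param fdr FDR level for the `significant` flag.
#' @param seed Integer seed.
#' @return data.frame with one row per gene: mediation coefficients,
#'   `prop_mediated`, `p`, `q`, `sign`, `significant`.
#' @export
mediation_screen <- function(genotype, expression, genes, outcome,
                             n_boot = 1000, fdr = 0.05, seed = 1L) {
  E <- .trait_values(expression)
  missing <- setdiff(genes, colnames(E))
  if (length(missing)) stop("gene(s) not in expression matrix: ",
                            paste(head(missing, 3L), collapse = ", "))
  rows <- lapply(seq_along(genes), function(i) {
    r <- mediate(genotype, E[, genes[i]], outcome, n_boot = n_boot,
                 seed = seed + i)
    cbind(data.frame(gene = genes[i], stringsAsFactors = FALSE), r)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res$sign <- ifelse(res$indirect >= 0, "positive", "negative")
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res
}
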