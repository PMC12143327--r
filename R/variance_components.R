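# Marker-set heritability by single-component REML.
#
# The model is y = mu + g + e with g ~ N(0, sigma2_g * K) for a genetic
# relatedness matrix K built from a marker set, and e ~ N(0, sigma2_e * I).
# After eigen-rotation of K the restricted likelihood profiles down to a
# one-dimensional optimization over h2 = sigma2_g / (sigma2_g + sigma2_e),
# which is exact for a single variance component and numerically robust.

#' Genetic relatedness matrix from a marker set
#'
#' GCTA-style construction: marker columns are standardized to mean 0, SD 1
#' and `K = X X' / m` with `m` the number of markers. Constant markers are
#' dropped with a warning.
#'
#' @param genotypes A [genotype_matrix()] or bare +/-1 matrix.
#' @param marker_ids Optional character vector selecting markers.
#' @return list of class `grm`: `K` (symmetric PSD, segregant dimnames),
#'   `markers`, `m`.
#' @export
build_grm <- function(genotypes, marker_ids = NULL) {
  X <- .geno_values(genotypes)
  if (!is.null(marker_ids)) {
    missing <- setdiff(marker_ids, colnames(X))
    if (length(missing)) stop("marker(s) not in genotype matrix: ",
                              paste(head(missing, 3L), collapse = ", "))
    X <- X[, marker_ids, drop = FALSE]
  }
  s <- apply(X, 2L, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant marker(s) dropped from GRM")
    X <- X[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  if (ncol(X) < 1L) stop("no usable markers for the GRM")
  Z <- sweep(sweep(X, 2L, colMeans(X), "-"), 2L, s, "/")
  K <- tcrossprod(Z) / ncol(X)
  structure(list(K = K, markers = colnames(X), m = ncol(X)), class = "grm")
}

.grm_K <- function(grm) if (inherits(grm, "grm")) grm$K else as.matrix(grm)

# profiled restricted log-likelihood at a given h2 (intercept-only fixed part)
.reml_ll <- function(h2, d, ytil, xtil) {
  lam <- h2 * d + (1 - h2)
  w <- 1 / lam
  xtw <- sum(xtil^2 * w)
  beta <- sum(xtil * ytil * w) / xtw
  r <- ytil - xtil * beta
  rss <- sum(r^2 * w)
  nm1 <- length(ytil) - 1
  -0.5 * (nm1 * log(rss / nm1) + sum(log(lam)) + log(xtw))
}

.reml_fit_rotated <- function(ytil, xtil, d) {
  opt <- optimize(function(h) .reml_ll(h, d, ytil, xtil),
                  interval = c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-6)
  h2 <- opt$maximum
  # optimize() never returns the exact interval ends; snap near-boundary fits
  at0 <- .reml_ll(0, d, ytil, xtil)
  if (at0 >= opt$objective) h2 <- 0
  lam <- h2 * d + (1 - h2)
  w <- 1 / lam
  beta <- sum(xtil * ytil * w) / sum(xtil^2 * w)
  sigma2p <- sum((ytil - xtil * beta)^2 * w) / (length(ytil) - 1)
  list(h2 = h2, beta = beta, sigma2p = sigma2p, lam = lam)
}

.reml_fit_eig <- function(y, eig) {
  ytil <- as.numeric(crossprod(eig$vectors, y))
  xtil <- as.numeric(crossprod(eig$vectors, rep(1, length(y))))
  .reml_fit_rotated(ytil, xtil, eig$values)$h2
}

# parametric bootstrap in the rotated basis: simulate from the fitted model
# (case resampling is unusable here: a duplicated segregant has an identical
# phenotype and a unit genetic correlation, which drives every resampled fit
# to the h2 = 1 boundary)
.reml_boot_se <- function(ytil, xtil, d, fit, n_boot) {
  s <- sqrt(fit$sigma2p * fit$lam)
  hb <- vapply(seq_len(n_boot), function(b) {
    yb <- fit$beta * xtil + rnorm(length(ytil)) * s
    .reml_fit_rotated(yb, xtil, d)$h2
  }, numeric(1L))
  sd(hb)
}

.grm_eigen <- function(K, tol = 1e-6) {
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -tol * max(abs(eig$values), 1)) {
    stop("GRM is not positive semi-definite")
  }
  eig$values <- pmax(eig$values, 0)
  eig
}

#' REML heritability for a marker-set GRM
#'
#' Fits `y = mu + g + e`, `g ~ N(0, sigma2_g K)`, by REML via
#' eigendecomposition of the GRM restricted to observed segregants and 1-D
#' optimization of the profiled restricted likelihood over `h2` in [0, 1].
#' The optional bootstrap SE refits `n_boot` replicates simulated from the
#' fitted model (a parametric bootstrap, run in the eigen-rotated basis;
#' case resampling is not usable with a relatedness kernel because a
#' duplicated segregant carries an identical phenotype with a unit genetic
#' correlation, which drives every resampled fit to the h2 = 1 boundary).
#' The full study-scale setting is 5,000 bootstrap iterations; the default
#' here is 0 (no SE).
#'
#' @param traits Numeric vector, or a segregants x traits matrix (columns
#'   fitted separately, eigendecompositions shared across columns with the
#'   same missingness pattern).
#' @param grm A [build_grm()] result (or bare symmetric matrix) whose
#'   rows/columns align with `traits`.
#' @param n_boot Bootstrap replicates for the SE (0 = none).
#' @param seed Integer seed for the bootstrap.
#' @param min_n Minimum non-missing segregants per trait.
#' @return data.frame with `trait`, `h2`, `se`, `n`, `n_boot`.
#' @export
reml_h2 <- function(traits, grm, n_boot = 0, seed = 1L, min_n = 30L) {
  K <- .grm_K(grm)
  Y <- if (is.matrix(traits)) .trait_values(traits) else
    matrix(traits, ncol = 1L, dimnames = list(names(traits), "trait"))
  if (nrow(Y) != nrow(K)) stop("traits and GRM must cover the same segregants")
  pat <- apply(!is.na(Y), 2L, function(z) paste(which(z), collapse = ","))
  out <- data.frame(trait = colnames(Y), h2 = NA_real_, se = NA_real_,
                    n = colSums(!is.na(Y)), n_boot = n_boot,
                    stringsAsFactors = FALSE)
  if (n_boot > 0) set.seed(seed)
  for (pp in unique(pat)) {
    cols <- which(pat == pp)
    ok <- !is.na(Y[, cols[1L]])
    n <- sum(ok)
    if (n < min_n) next
    eig <- .grm_eigen(K[ok, ok])
    xtil <- as.numeric(crossprod(eig$vectors, rep(1, n)))
    for (j in cols) {
      y <- Y[ok, j]
      ytil <- as.numeric(crossprod(eig$vectors, y))
      fit <- .reml_fit_rotated(ytil, xtil, eig$values)
      out$h2[j] <- fit$h2
      if (n_boot > 0) {
        out$se[j] <- .reml_boot_se(ytil, xtil, eig$values, fit, n_boot)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Marker-set variance suite across conditions
#'
#' Per condition, the fraction of growth variance explained by (a) all
#' markers, (b) the hotspot peak markers, (c) optionally that condition's
#' gQTL peak markers, and (d) random marker sets matched in size to the
#' hotspot set. The hotspot empirical p-value per condition is the fraction
#' of random sets whose h2 matches or exceeds the hotspot h2.
#'
#' @param growth Growth matrix, segregants x conditions.
#' @param genotypes A [genotype_matrix()].
#' @param hotspot_markers Character vector of hotspot peak marker IDs.
#' @param gqtl_sets Optional named list (by condition) of gQTL marker IDs.
#' @param n_random Number of random marker sets.
#' @param seed Integer seed.
#' @param n_boot Bootstrap replicates for SEs of the named sets.
#' @return list: `estimates` (data.frame condition/set/h2/se/n),
#'   `random_h2` (conditions x n_random matrix), `p_hotspot` (named vector).
#' @export
marker_set_variance_suite <- function(growth, genotypes, hotspot_markers,
                                      gqtl_sets = NULL, n_random = 1000,
                                      seed = 1L, n_boot = 0) {
  G <- .trait_values(growth)
  X <- genotypes$geno[rownames(G), , drop = FALSE]
  fit_set <- function(ids, label) {
    est <- reml_h2(G, build_grm(X, ids), n_boot = n_boot, seed = seed)
    data.frame(condition = est$trait, set = label, h2 = est$h2, se = est$se,
               n = est$n, stringsAsFactors = FALSE)
  }
  rows <- list(fit_set(NULL, "all_markers"),
               fit_set(hotspot_markers, "hotspots"))
  if (!is.null(gqtl_sets)) {
    gq <- lapply(intersect(colnames(G), names(gqtl_sets)), function(cc) {
      ids <- intersect(gqtl_sets[[cc]], colnames(X))
      if (!length(ids)) return(NULL)
      est <- reml_h2(G[, cc, drop = FALSE], build_grm(X, ids),
                     n_boot = n_boot, seed = seed)
      data.frame(condition = cc, set = "gqtl", h2 = est$h2, se = est$se,
                 n = est$n, stringsAsFactors = FALSE)
    })
    rows <- c(rows, gq)
  }
  estimates <- do.call(rbind, rows)
  sets <- random_marker_sets(genotypes, k = length(hotspot_markers),
                             n_sets = n_random, seed = seed)
  random_h2 <- vapply(sets, function(ids) {
    reml_h2(G, build_grm(X, ids))$h2
  }, numeric(ncol(G)))
  random_h2 <- matrix(random_h2, nrow = ncol(G),
                      dimnames = list(colnames(G), NULL))
  hs <- estimates[estimates$set == "hotspots", ]
  p_hotspot <- vapply(colnames(G), function(cc) {
    h <- hs$h2[hs$condition == cc]
    if (!length(h) || is.na(h)) return(NA_real_)
    mean(random_h2[cc, ] >= h, na.rm = TRUE)
  }, numeric(1L))
  list(estimates = estimates, random_h2 = random_h2, p_hotspot = p_hotspot)
}

#' Incremental hotspot variance curve
#'
#' Orders hotspots by the number of genes they affect (descending), fits
#' nested marker sets of size 2 up to all hotspots, and reports the
#' cumulative h2 curve, each hotspot's fractional contribution
#' (`h2(first k) - h2(first k-1)`, floored at 0), and the smallest set sizes
#' reaching 50% and 80% of the full-set h2. Single-marker sets are not
#' estimable under this scheme, so the curve starts at 2.
#'
#' @param trait Numeric growth vector.
#' @param genotypes A [genotype_matrix()].
#' @param hotspots Hotspot table (`peak_marker`, `n_target_genes`).
#' @return list: `curve` (data.frame k/h2), `contributions`
#'   (data.frame hotspot/frac), `k_half`, `k_80`.
#' @export
incremental_hotspot_variance <- function(trait, genotypes, hotspots) {
  ord <- order(hotspots$n_target_genes, decreasing = TRUE)
  hs <- hotspots[ord, , drop = FALSE]
  ids <- hs$peak_marker
  if (length(ids) < 2L) stop("need at least 2 hotspots")
  X <- genotypes$geno
  if (!is.null(names(trait))) X <- X[names(trait), , drop = FALSE]
  h2 <- vapply(2:length(ids), function(k) {
    reml_h2(trait, build_grm(X, ids[seq_len(k)]))$h2
  }, numeric(1L))
  curve <- data.frame(k = 2:length(ids), h2 = h2)
  contrib <- pmax(diff(c(0, h2)), 0)
  # first two hotspots enter together; their shared increment is h2 at k=2
  contributions <- data.frame(hotspot = hs$hotspot[-1L], frac = contrib,
                              stringsAsFactors = FALSE)
  total <- h2[length(h2)]
  k_half <- if (total > 0) curve$k[which(h2 >= 0.5 * total)[1L]] else NA_integer_
  k_80 <- if (total > 0) curve$k[which(h2 >= 0.8 * total)[1L]] else NA_integer_
  list(curve = curve, contributions = contributions,
       k_half = k_half, k_80 = k_80)
}
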