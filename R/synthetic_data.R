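# Synthetic segregant panel with known ground truth.
#
# The generator emulates the statistical structure of a large haploid yeast
# cross: linked biallelic markers along 16 chromosomes at ~0.5 allele
# frequency, trans-eQTL hotspots that each perturb many transcripts, sparse
# strong local eQTLs, growth traits driven by a subset of hotspots plus
# private loci, batch and culture-density (OD600) nuisance structure, and
# Gaussian residual noise.

#' Configuration for the synthetic segregant panel
#'
#' Defaults reproduce the scale of the cross the pipeline targets: 1,000
#' segregants genotyped at 11,520 markers (16 chromosomes, ~1 kb spacing,
#' recombination probability 0.004 per interval so adjacent markers correlate
#' at ~0.99), 5,720 expressed genes, 46 growth conditions, 102 trans-eQTL
#' hotspots, about half of genes with a local eQTL, 11 culture batches and 5%
#' missing growth measurements. Any field can be overridden for smaller
#' panels.
#'
#' @param n_segregants Number of haploid segregants.
#' @param n_chromosomes Number of chromosomes.
#' @param chr_length Chromosome length in bp (recycled across chromosomes).
#' @param markers_per_chrom Markers per chromosome, evenly spaced.
#' @param recomb_prob Probability that adjacent markers are separated by a
#'   crossover (per-interval Bernoulli flip; Haldane-like, no interference).
#'   Adjacent-marker genotype correlation is `1 - 2 * recomb_prob`.
#' @param n_genes Number of expressed genes.
#' @param n_conditions Number of growth conditions.
#' @param n_hotspots Number of trans-eQTL hotspots.
#' @param hotspot_target_frac Fraction of genes affected by each hotspot.
#' @param local_frac Fraction of genes with a local eQTL.
#' @param local_sd,hotspot_gene_sd,hotspot_growth_sd,private_sd SDs of the
#'   effect-size distributions (local eQTL on expression, hotspot on
#'   expression, hotspot on growth, private gQTL on growth), in residual-SD
#'   units.
#' @param growth_hotspot_frac Fraction of hotspots affecting each condition.
#' @param n_private Private (non-hotspot) gQTLs per condition.
#' @param n_batches Number of culture batches (assigned round-robin).
#' @param batch_sd SD of per-gene batch effects.
#' @param od_sd SD of per-gene OD600 coefficients (OD drawn lognormal).
#' @param expr_noise_sd,growth_noise_sd Residual SDs.
#' @param missing_growth_frac Fraction of growth values set missing at random.
#' @param ci_halfwidth Half-width (bp) of the confidence intervals written to
#'   the emitted QTL tables.
#' @param mediation Optional list(`condition`, `hotspot`, `n_mediators`,
#'   `gamma_sd`) routing part of one hotspot's effect on one condition
#'   through realized transcript levels, to give mediation analyses a ground
#'   truth. Off (`NULL`) by default.
#' @param seed Integer seed; the same config regenerates bit-identical data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_segregants = 1000,
                       n_chromosomes = 16,
                       chr_length = 750000,
                       markers_per_chrom = 720,
                       recomb_prob = 0.004,
                       n_genes = 5720,
                       n_conditions = 46,
                       n_hotspots = 102,
                       hotspot_target_frac = 0.1,
                       local_frac = 0.5,
                       local_sd = 0.8,
                       hotspot_gene_sd = 0.35,
                       hotspot_growth_sd = 0.3,
                       private_sd = 0.3,
                       growth_hotspot_frac = 0.3,
                       n_private = 2,
                       n_batches = 11,
                       batch_sd = 0.3,
                       od_sd = 0.3,
                       expr_noise_sd = 1,
                       growth_noise_sd = 1,
                       missing_growth_frac = 0.05,
                       ci_halfwidth = 10000,
                       mediation = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$recomb_prob, cfg$hotspot_target_frac, cfg$local_frac,
             cfg$growth_hotspot_frac, cfg$missing_growth_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sds <- c(cfg$local_sd, cfg$hotspot_gene_sd, cfg$hotspot_growth_sd,
           cfg$private_sd, cfg$batch_sd, cfg$od_sd, cfg$expr_noise_sd,
           cfg$growth_noise_sd)
  if (any(sds < 0)) stop("effect and noise SDs must be >= 0")
  n_markers <- cfg$n_chromosomes * cfg$markers_per_chrom
  if (cfg$n_hotspots > n_markers) stop("more hotspots than markers")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate linked segregant genotypes
#'
#' Per segregant and chromosome, the first marker allele is Bernoulli(0.5)
#' mapped to -1/+1 and each subsequent marker flips with probability
#' `recomb_prob` (a Markov chain, giving monotone LD decay with distance and
#' adjacent-marker correlation `1 - 2 * recomb_prob`).
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with roman-numeral chromosome names and
#'   marker IDs of the form `"chrI:1042_A/G"`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_segregants
  m <- cfg$markers_per_chrom
  chroms <- paste0("chr", as.character(utils::as.roman(seq_len(cfg$n_chromosomes))))
  spacing <- floor(cfg$chr_length / (m + 1))
  pos <- spacing * seq_len(m)
  bases <- c("A", "C", "G", "T")
  blocks <- vector("list", cfg$n_chromosomes)
  ids <- character(0)
  for (c_i in seq_len(cfg$n_chromosomes)) {
    first <- matrix(sample(c(-1, 1), n, replace = TRUE), nrow = n, ncol = 1)
    if (m > 1L) {
      flips <- matrix(rbinom(n * (m - 1L), 1L, cfg$recomb_prob), nrow = n)
      steps <- 1 - 2 * flips                      # +1 keep, -1 switch
      g <- first[, 1L] * cbind(1, t(apply(steps, 1L, cumprod)))
    } else {
      g <- first
    }
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1L))
    ids_c <- paste0(chroms[c_i], ":", pos, "_", a1, "/", a2)
    colnames(g) <- ids_c
    blocks[[c_i]] <- g
    ids <- c(ids, ids_c)
  }
  geno <- do.call(cbind, blocks)
  rownames(geno) <- sprintf("seg%04d", seq_len(n))
  layout <- genome_layout(chroms, rep(cfg$chr_length, cfg$n_chromosomes))
  genotype_matrix(geno, layout = layout)
}

#' Simulate a full segregant panel with ground truth
#'
#' Generates genotypes, expression (local + hotspot genetic effects, batch
#' and OD600 nuisance, Gaussian noise), growth (hotspot + private genetic
#' effects, optional mediation through transcripts, missing values), the
#' matching eQTL/gQTL tables (true causal markers as peaks, CIs spanning a
#' configurable window, LODs computed from realized marginal r^2 as
#' `-n * log10(1 - r^2) / 2`), the hotspot table, gene annotation, and a
#' complete truth record.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genotypes`, `expression`, `growth`,
#'   `covariates` (data.frame with `batch`, `od`), `eqtl`, `gqtl`,
#'   `hotspots`, `genes`, `truth`, `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genotypes <- simulate_genotypes(cfg)   # consumes cfg$seed stream first
  X <- genotypes$geno
  n <- nrow(X); n_mark <- ncol(X)
  mk <- genotypes$markers
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  cond_ids <- sprintf("cond%02d", seq_len(cfg$n_conditions))

  # -- causal marker assignment
  hot_idx <- sort(sample.int(n_mark, cfg$n_hotspots))
  free <- setdiff(seq_len(n_mark), hot_idx)
  if (cfg$n_private > length(free)) {
    stop("not enough non-hotspot markers for the requested private loci")
  }

  # genes placed uniformly; the local eQTL is the nearest marker
  gene_chrom_i <- sample.int(cfg$n_chromosomes, cfg$n_genes, replace = TRUE)
  gene_chrom <- genotypes$layout$chrom[gene_chrom_i]
  gene_start <- sample.int(max(cfg$chr_length - 2000L, 1L), cfg$n_genes, replace = TRUE)
  gene_end <- pmin(gene_start + 1499L, cfg$chr_length)
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(gene = gene_ids, chrom = gene_chrom,
                      cds_start = gene_start, cds_end = gene_end,
                      strand = gene_strand, stringsAsFactors = FALSE)
  local_gene <- sort(sample.int(cfg$n_genes, round(cfg$local_frac * cfg$n_genes)))
  local_marker <- rep(NA_integer_, cfg$n_genes)
  for (j in local_gene) {
    on_chr <- which(mk$chrom == gene_chrom[j])
    local_marker[j] <- on_chr[which.min(abs(mk$pos[on_chr] - gene_start[j]))]
  }
  b_local <- numeric(cfg$n_genes)
  b_local[local_gene] <- rnorm(length(local_gene), 0, cfg$local_sd)

  # hotspot -> gene effects
  B_hot <- matrix(0, cfg$n_genes, cfg$n_hotspots,
                  dimnames = list(gene_ids, mk$id[hot_idx]))
  n_targets <- pmax(1L, round(cfg$hotspot_target_frac * cfg$n_genes))
  for (h in seq_len(cfg$n_hotspots)) {
    tg <- sample.int(cfg$n_genes, n_targets)
    B_hot[tg, h] <- rnorm(n_targets, 0, cfg$hotspot_gene_sd)
  }

  # hotspot -> growth and private gQTL effects
  C_hot <- matrix(0, cfg$n_conditions, cfg$n_hotspots,
                  dimnames = list(cond_ids, mk$id[hot_idx]))
  n_gh <- pmax(0L, round(cfg$growth_hotspot_frac * cfg$n_hotspots))
  priv_idx <- matrix(0L, cfg$n_conditions, cfg$n_private)
  D_priv <- matrix(0, cfg$n_conditions, max(cfg$n_private, 1L))
  for (cc in seq_len(cfg$n_conditions)) {
    if (n_gh > 0L) {
      hh <- sample.int(cfg$n_hotspots, n_gh)
      C_hot[cc, hh] <- rnorm(n_gh, 0, cfg$hotspot_growth_sd)
    }
    if (cfg$n_private > 0L) {
      priv_idx[cc, ] <- sample(free, cfg$n_private)
      D_priv[cc, seq_len(cfg$n_private)] <- rnorm(cfg$n_private, 0, cfg$private_sd)
    }
  }

  # -- nuisance covariates
  batch <- factor(rep_len(seq_len(cfg$n_batches), n))
  od <- rlnorm(n, meanlog = log(0.4), sdlog = 0.2)
  batch_coef <- matrix(rnorm(cfg$n_batches * cfg$n_genes, 0, cfg$batch_sd),
                       cfg$n_batches, cfg$n_genes)
  od_coef <- rnorm(cfg$n_genes, 0, cfg$od_sd)

  # -- expression
  Xhot <- X[, hot_idx, drop = FALSE]
  E_gen <- Xhot %*% t(B_hot)                     # n x genes
  has_local <- which(b_local != 0)
  for (j in has_local) E_gen[, j] <- E_gen[, j] + X[, local_marker[j]] * b_local[j]
  E_nuis <- batch_coef[as.integer(batch), , drop = FALSE] +
    outer(od - mean(od), od_coef)
  E <- E_gen + E_nuis +
    matrix(rnorm(n * cfg$n_genes, 0, cfg$expr_noise_sd), n)
  dimnames(E) <- list(rownames(X), gene_ids)

  # -- growth
  G_gen <- Xhot %*% t(C_hot)                     # n x conditions
  for (cc in seq_len(cfg$n_conditions)) {
    if (cfg$n_private > 0L) {
      G_gen[, cc] <- G_gen[, cc] +
        X[, priv_idx[cc, ], drop = FALSE] %*% D_priv[cc, seq_len(cfg$n_private)]
    }
  }
  med <- cfg$mediation
  gamma_med <- NULL
  if (!is.null(med)) {
    stopifnot(med$condition %in% seq_len(cfg$n_conditions) || med$condition %in% cond_ids,
              med$hotspot %in% seq_len(cfg$n_hotspots))
    cc <- if (is.character(med$condition)) match(med$condition, cond_ids) else med$condition
    # mediators are drawn from the hotspot's more strongly affected targets
    # and carry effects bounded away from zero, so the ground truth labels
    # genes whose indirect effects are real rather than vanishing
    targets <- which(abs(B_hot[, med$hotspot]) >= 0.5 * cfg$hotspot_gene_sd)
    if (!length(targets)) targets <- which(B_hot[, med$hotspot] != 0)
    n_med <- min(med$n_mediators, length(targets))
    mediators <- sort(targets[sample.int(length(targets), n_med)])
    gamma <- sample(c(-1, 1), n_med, replace = TRUE) *
      runif(n_med, 0.5, 1.5) * med$gamma_sd
    gamma_med <- data.frame(gene = gene_ids[mediators], gamma = gamma,
                            condition = cond_ids[cc], stringsAsFactors = FALSE)
    # growth flows through realized expression, so alpha*gamma is a true
    # indirect effect for these genes
    G_gen[, cc] <- G_gen[, cc] + E[, mediators, drop = FALSE] %*% gamma
  }
  G <- G_gen + matrix(rnorm(n * cfg$n_conditions, 0, cfg$growth_noise_sd), n)
  dimnames(G) <- list(rownames(X), cond_ids)
  if (cfg$missing_growth_frac > 0) {
    drop <- matrix(runif(n * cfg$n_conditions) < cfg$missing_growth_frac, n)
    G[drop] <- NA
  }

  h2_true <- apply(G_gen, 2L, var) /
    (apply(G_gen, 2L, var) + cfg$growth_noise_sd^2)

  # -- emitted QTL tables (true causal markers as peaks)
  lod_from_r <- function(r, n_obs) -n_obs * log10(pmax(1 - r^2, 1e-12)) / 2
  mk_qtl <- function(trait, marker_i, trait_vals) {
    r <- as.numeric(cor(trait_vals, X[, marker_i]))
    data.frame(trait = trait, chrom = mk$chrom[marker_i],
               peak_pos = mk$pos[marker_i],
               ci_lo = pmax(1, mk$pos[marker_i] - cfg$ci_halfwidth),
               ci_hi = pmin(cfg$chr_length, mk$pos[marker_i] + cfg$ci_halfwidth),
               lod = lod_from_r(r, sum(!is.na(trait_vals))),
               effect_r = r, stringsAsFactors = FALSE)
  }
  eqtl_rows <- vector("list", cfg$n_genes)
  for (j in seq_len(cfg$n_genes)) {
    mi <- integer(0)
    if (b_local[j] != 0) mi <- local_marker[j]
    mi <- c(mi, hot_idx[B_hot[j, ] != 0])
    if (length(mi)) {
      rr <- as.numeric(cor(E[, j], X[, mi, drop = FALSE]))
      eqtl_rows[[j]] <- data.frame(
        trait = gene_ids[j], chrom = mk$chrom[mi], peak_pos = mk$pos[mi],
        ci_lo = pmax(1, mk$pos[mi] - cfg$ci_halfwidth),
        ci_hi = pmin(cfg$chr_length, mk$pos[mi] + cfg$ci_halfwidth),
        lod = lod_from_r(rr, n), effect_r = rr, stringsAsFactors = FALSE)
    }
  }
  eqtl <- do.call(rbind, eqtl_rows[!vapply(eqtl_rows, is.null, logical(1L))])
  gqtl_rows <- vector("list", cfg$n_conditions)
  for (cc in seq_len(cfg$n_conditions)) {
    mi <- c(hot_idx[C_hot[cc, ] != 0],
            if (cfg$n_private > 0L) priv_idx[cc, ] else integer(0))
    if (length(mi)) {
      ok <- !is.na(G[, cc])
      rr <- as.numeric(cor(G[ok, cc], X[ok, mi, drop = FALSE]))
      gqtl_rows[[cc]] <- data.frame(
        trait = cond_ids[cc], chrom = mk$chrom[mi], peak_pos = mk$pos[mi],
        ci_lo = pmax(1, mk$pos[mi] - cfg$ci_halfwidth),
        ci_hi = pmin(cfg$chr_length, mk$pos[mi] + cfg$ci_halfwidth),
        lod = lod_from_r(rr, sum(ok)), effect_r = rr, stringsAsFactors = FALSE)
    }
  }
  gqtl <- do.call(rbind, gqtl_rows[!vapply(gqtl_rows, is.null, logical(1L))])

  hotspots <- data.frame(
    hotspot = sprintf("hs%03d", seq_len(cfg$n_hotspots)),
    chrom = mk$chrom[hot_idx],
    ci_lo = pmax(1, mk$pos[hot_idx] - cfg$ci_halfwidth),
    ci_hi = pmin(cfg$chr_length, mk$pos[hot_idx] + cfg$ci_halfwidth),
    peak_marker = mk$id[hot_idx],
    n_target_genes = colSums(B_hot != 0),
    stringsAsFactors = FALSE)

  truth <- list(
    local_marker = setNames(ifelse(is.na(local_marker), NA_character_,
                                   mk$id[local_marker]), gene_ids),
    local_effect = setNames(b_local, gene_ids),
    hotspot_gene_effect = B_hot,
    hotspot_growth_effect = C_hot,
    private_marker = matrix(mk$id[priv_idx], nrow = cfg$n_conditions),
    private_effect = D_priv,
    mediators = gamma_med,
    h2 = setNames(h2_true, cond_ids),
    batch_coef = batch_coef,
    od_coef = setNames(od_coef, gene_ids),
    hotspot_marker = mk$id[hot_idx])

  list(genotypes = genotypes,
       expression = trait_matrix(E, "expression"),
       growth = trait_matrix(G, "growth"),
       covariates = data.frame(segregant = rownames(X), batch = batch, od = od,
                               stringsAsFactors = FALSE),
       eqtl = eqtl, gqtl = gqtl, hotspots = hotspots, genes = genes,
       truth = truth, config = cfg)
}
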