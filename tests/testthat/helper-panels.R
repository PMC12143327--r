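# Shared synthetic fixtures, built once per test run.

# Moderate hotspot-driven panel for cross-module tests.
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_panel(sim_config(
        n_segregants = 300, n_chromosomes = 4, chr_length = 200000,
        markers_per_chrom = 50, recomb_prob = 0.02, n_genes = 80,
        n_conditions = 6, n_hotspots = 10, hotspot_target_frac = 0.25,
        local_frac = 0.5, growth_hotspot_frac = 0.4, n_private = 1,
        missing_growth_frac = 0.03, seed = 101L))
    }
    cache
  }
})

# Global-null panel: no genetic, batch or OD structure anywhere.
null_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_panel(sim_config(
        n_segregants = 250, n_chromosomes = 4, chr_length = 200000,
        markers_per_chrom = 50, recomb_prob = 0.5, n_genes = 60,
        n_conditions = 5, n_hotspots = 8, local_sd = 0, hotspot_gene_sd = 0,
        hotspot_growth_sd = 0, private_sd = 0, batch_sd = 0, od_sd = 0,
        missing_growth_frac = 0, seed = 202L))
    }
    cache
  }
})

# Strongly hotspot-driven panel: most growth genetics flows through hotspots
# with sizeable effects, so effect-based and correlation-based views of the
# architecture should agree.
arch_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_panel(sim_config(
        n_segregants = 800, n_chromosomes = 4, chr_length = 200000,
        markers_per_chrom = 40, recomb_prob = 0.03, n_genes = 60,
        n_conditions = 6, n_hotspots = 16, hotspot_target_frac = 0.4,
        hotspot_gene_sd = 0.5, hotspot_growth_sd = 0.5, local_frac = 0.3,
        growth_hotspot_frac = 0.5, n_private = 1, missing_growth_frac = 0,
        seed = 303L))
    }
    cache
  }
})

# Mutually orthogonal +/-1 design: columns of a full 2^k factorial.
orthogonal_markers <- function(k) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  colnames(g) <- paste0("m", seq_len(k))
  rownames(g) <- paste0("s", seq_len(nrow(g)))
  g
}

# independent +/-1 genotypes with marker-style names
random_genotypes <- function(n, m, seed = 1L, chrom = "chrI") {
  set.seed(seed)
  X <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
  colnames(X) <- paste0(chrom, ":", seq_len(m) * 100, "_A/C")
  rownames(X) <- sprintf("s%04d", seq_len(n))
  X
}
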