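# End-to-end orchestration over a synthetic panel: simulate, then run each
# analysis stage in dependency order, writing tab-separated outputs and a
# deterministic manifest. Identical config + seed reproduces every output
# bit-identically.

# per-stage seed derived from (global seed, stage name) so adding a stage
# does not shift the streams of the others
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

.pipeline_defaults <- list(
  seed = 1L,
  stages = c("simulate", "gencorr", "effectcorr", "hotspotcorr", "overlap",
             "varcomp", "regressout", "mediate", "coloc"),
  sim = list(),
  fdr = 0.05,
  effect_fdr = 0.20,
  min_loci = 3,
  n_random_sets = 50,
  overlap_reps = 200,
  coloc_n_boot = 200,
  coloc_lod_min = 10,
  coloc_max_pairs = 10,
  mediation_n_boot = 500,
  varcomp_n_random = 25
)

#' Run the integrated pipeline on a synthetic panel
#'
#' Simulates a segregant panel, then runs covariate correction, genetic
#' correlations, QTL and hotspot effect correlations, gQTL/hotspot interval
#' overlap with a random-placement null, marker-set heritability, marker-set
#' regress-out recomputation, mediation (when the simulated panel carries a
#' mediation architecture, or against the hotspot with most targets
#' otherwise), and pleiotropy tests on candidate pairs. Every stage writes
#' tab-separated outputs under `output_dir` and a manifest of md5 checksums;
#' outputs are a pure function of the config (including its seed).
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults; `sim` is a list of [sim_config()] overrides. `output_dir` is
#'   required.
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return Invisibly, the manifest data.frame (file, md5).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.pipeline_defaults, config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("config needs an output_dir")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  written <- character(0)
  emit <- function(x, f) {
    data.table::fwrite(x, out(f), sep = "\t", na = "NA", quote = FALSE)
    written <<- c(written, f)
  }
  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    message("stage ", name)
    tryCatch(fun(), error = function(e) {
      writeLines(paste("stage", name, "failed:", conditionMessage(e)),
                 out("FAILED"))
      stop("stage ", name, " failed: ", conditionMessage(e))
    })
  }

  # -- simulate
  sim_args <- cfg$sim
  sim_args$seed <- .stage_seed(cfg$seed, "simulate")
  panel <- NULL
  run_stage("simulate", function() {
    panel <<- simulate_panel(do.call(sim_config, sim_args))
    write_genotype_matrix(panel$genotypes, out("genotypes.tsv"))
    write_trait_matrix(panel$expression, out("expression.tsv"))
    write_trait_matrix(panel$growth, out("growth.tsv"))
    emit(panel$covariates, "covariates.tsv")
    emit(panel$eqtl, "eqtl.tsv")
    emit(panel$gqtl, "gqtl.tsv")
    emit(panel$hotspots, "hotspots.tsv")
    emit(panel$genes, "genes.tsv")
    emit(data.frame(condition = names(panel$truth$h2), h2 = panel$truth$h2),
         "truth_h2.tsv")
    written <<- c(written, "genotypes.tsv", "expression.tsv", "growth.tsv")
  })
  if (is.null(panel)) stop("the pipeline currently requires the simulate stage")
  E <- correct_expression(panel$expression, panel$covariates$batch,
                          panel$covariates$od)
  G <- .trait_values(panel$growth)
  X <- panel$genotypes$geno
  hot_ids <- panel$hotspots$peak_marker
  gencorr <- NULL
  run_stage("gencorr", function() {
    gencorr <<- suppressMessages(genetic_correlations(E, G, fdr = cfg$fdr))
    emit(gencorr, "genetic_correlations.tsv")
  })
  run_stage("effectcorr", function() {
    ec <- qtl_effect_correlations(panel$eqtl, E, G, panel$genotypes,
                                  min_loci = cfg$min_loci, fdr = cfg$effect_fdr)
    emit(ec, "qtl_effect_correlations.tsv")
  })
  run_stage("hotspotcorr", function() {
    hc <- hotspot_effect_correlations(E, G, X[, hot_ids, drop = FALSE],
                                      fdr = cfg$fdr)
    emit(hc, "hotspot_effect_correlations.tsv")
  })
  run_stage("overlap", function() {
    on <- random_interval_null(
      unique(panel$gqtl[, c("chrom", "ci_lo", "ci_hi")]),
      panel$genotypes$layout,
      panel$hotspots[, c("chrom", "ci_lo", "ci_hi")],
      n_reps = cfg$overlap_reps, seed = .stage_seed(cfg$seed, "overlap"))
    emit(data.frame(observed = on$observed, p = on$p, n_reps = on$n_reps,
                    null_mean = mean(on$null_counts)), "overlap_null.tsv")
  })
  run_stage("varcomp", function() {
    vs <- marker_set_variance_suite(
      panel$growth, panel$genotypes, hot_ids,
      n_random = cfg$varcomp_n_random,
      seed = .stage_seed(cfg$seed, "varcomp"))
    emit(vs$estimates, "variance_components.tsv")
    emit(data.frame(condition = names(vs$p_hotspot), p = vs$p_hotspot),
         "hotspot_variance_p.tsv")
  })
  run_stage("regressout", function() {
    if (is.null(gencorr)) gencorr <<- suppressMessages(
      genetic_correlations(E, G, fdr = cfg$fdr))
    local_sets <- panel$truth$local_marker
    local_sets <- as.list(local_sets[!is.na(local_sets)])
    rep_local <- recompute_correlations(E, G, panel$genotypes, local_sets,
                                        label = "local", before = gencorr)
    rep_hot <- recompute_correlations(E, G, panel$genotypes, hot_ids,
                                      label = "hotspots", before = gencorr)
    rep <- rbind(rep_local, rep_hot)
    emit(rep, "regress_out.tsv")
    emit(compare_correlations(rep), "regress_out_summary.tsv")
  })
  run_stage("mediate", function() {
    med <- panel$truth$mediators
    if (!is.null(med)) {
      hs <- panel$config$mediation$hotspot
      marker <- panel$truth$hotspot_marker[hs]
      cond <- med$condition[1L]
      genes <- rownames(panel$truth$hotspot_gene_effect)[
        panel$truth$hotspot_gene_effect[, hs] != 0]
    } else {
      hs <- which.max(panel$hotspots$n_target_genes)
      marker <- panel$hotspots$peak_marker[hs]
      cond <- colnames(G)[1L]
      genes <- rownames(panel$truth$hotspot_gene_effect)[
        panel$truth$hotspot_gene_effect[, hs] != 0]
    }
    ms <- mediation_screen(X[, marker], E, genes, G[, cond],
                           n_boot = cfg$mediation_n_boot, fdr = cfg$fdr,
                           seed = .stage_seed(cfg$seed, "mediate"))
    ms$hotspot_marker <- marker
    ms$condition <- cond
    emit(ms, "mediation.tsv")
  })
  run_stage("coloc", function() {
    eqtl <- panel$eqtl
    cls <- classify_eqtl(eqtl, panel$genes, panel$genotypes$layout)
    pairs <- candidate_pairs(panel$gqtl, eqtl[cls == "local", , drop = FALSE],
                             lod_min = cfg$coloc_lod_min)
    thin <- thin_markers(panel$genotypes)
    n_run <- min(nrow(pairs), cfg$coloc_max_pairs)
    rows <- lapply(seq_len(n_run), function(i) {
      rg <- region_genotypes(panel$genotypes, pairs$chrom[i], pairs$lo[i],
                             pairs$hi[i], thinned = thin)
      pt <- pleiotropy_test(G[, pairs$condition[i]], E[, pairs$gene[i]], rg,
                            n_boot = cfg$coloc_n_boot,
                            seed = .stage_seed(cfg$seed, paste0("coloc", i)))
      data.frame(condition = pairs$condition[i], gene = pairs$gene[i],
                 lrt = pt$lrt, p = pt$p, verdict = pt$verdict,
                 stringsAsFactors = FALSE)
    })
    emit(if (length(rows)) do.call(rbind, rows) else
      data.frame(condition = character(0), gene = character(0),
                 lrt = numeric(0), p = numeric(0), verdict = character(0)),
      "pleiotropy.tsv")
  })

  cfg_out <- cfg[setdiff(sort(names(cfg)), "output_dir")]
  yaml::write_yaml(cfg_out, out("config_used.yaml"))
  written <- c(written, "config_used.yaml")
  files <- sort(unique(written))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$output_dir, files))),
    stringsAsFactors = FALSE)
  data.table::fwrite(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE)
  invisible(manifest)
}
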