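#' Simulate a complete mutant study with planted candidate genes
#'
#' One call builds every input the candidate-gene pipeline consumes — an
#' annotated genome, a WT + two-mutant variant trio, coverage tracks and a
#' count matrix — with a planted truth that separates true candidates
#' (large-effect variant in both mutants AND concordant differential
#' expression) from single-criterion decoys (one or the other, never
#' both).
#'
#' @param seed Integer seed; everything below derives from it.
#' @param n_chrom,chrom_len,n_genes Genome layout (see
#'   [simulate_genome()]).
#' @param n_candidates Genes planted with both criteria.
#' @param n_decoy_effect Genes with large-effect variants in both mutants
#'   but no expression change.
#' @param n_decoy_de Genes with concordant differential expression but no
#'   variant.
#' @param n_shared,n_private Background variant counts (see
#'   [plant_variants()]).
#' @param fail_fraction Fraction of background records planted to fail the
#'   hard filter.
#' @param de_log2fc Magnitude of planted log2 fold changes.
#' @param dispersion NB dispersion of the count simulation.
#' @param mean_depth,depth_window Coverage-track parameters.
#' @param deletions Optional named list (per mutant) of deletion
#'   data.frames for [simulate_depth()].
#' @param mutants Mutant sample labels.
#' @return List with `genome`, `models`, `variants`, `counts`, `depth`
#'   (per-sample tracks) and `truth` (planted candidates, decoys, private
#'   variant keys, DE spec, deletions, seed).
#' @export
simulate_candidate_study <- function(seed = 1, n_chrom = 2,
                                     chrom_len = 2.5e6, n_genes = 40,
                                     n_candidates = 5, n_decoy_effect = 5,
                                     n_decoy_de = 5, n_shared = 300,
                                     n_private = c(hybs1 = 150, hybs2 = 150),
                                     fail_fraction = 0.05, de_log2fc = 3,
                                     dispersion = 0.05, mean_depth = 30,
                                     depth_window = 100e3, deletions = NULL,
                                     mutants = c("hybs1", "hybs2")) {
  stopifnot(n_candidates + n_decoy_effect + n_decoy_de <= n_genes)
  sim <- simulate_genome(n_chrom, chrom_len, n_genes, seed = seed)
  gene_ids <- vapply(sim$models, `[[`, character(1), "gene_id")
  picks <- with_seed(seed + 1L, {
    sel <- sample(gene_ids, n_candidates + n_decoy_effect + n_decoy_de)
    cats <- sample(c("frameshift", "stop_gained", "splice_donor",
                     "splice_acceptor", "start_lost", "stop_lost",
                     "missense"),
                   n_candidates + n_decoy_effect, replace = TRUE)
    signs <- sample(c(1, -1), n_candidates + n_decoy_de, replace = TRUE)
    list(candidates = sel[seq_len(n_candidates)],
         decoy_effect = sel[n_candidates + seq_len(n_decoy_effect)],
         decoy_de = sel[n_candidates + n_decoy_effect + seq_len(n_decoy_de)],
         categories = cats, signs = signs)
  })
  effect_genes <- c(picks$candidates, picks$decoy_effect)
  planted_effects <- do.call(rbind, lapply(mutants, function(s) {
    data.frame(sample = s, gene = effect_genes,
               category = picks$categories, stringsAsFactors = FALSE)
  }))
  planted <- plant_variants(sim$genome, sim$models, n_shared = n_shared,
                            n_private = n_private,
                            planted_effects = planted_effects,
                            seed = seed + 2L, fail_fraction = fail_fraction)
  de_genes <- c(picks$candidates, picks$decoy_de)
  de_spec <- do.call(rbind, lapply(seq_along(mutants), function(i) {
    data.frame(gene = de_genes, condition = mutants[i],
               log2fc = picks$signs * de_log2fc, stringsAsFactors = FALSE)
  }))
  baseline <- with_seed(seed + 3L, {
    b <- stats::setNames(stats::rlnorm(length(gene_ids), log(200), 1),
                         gene_ids)
    # planted genes are given solid expression so their status is a
    # property of the planted effect, not of sampling noise
    b[de_genes] <- stats::runif(length(de_genes), 500, 1500)
    b[picks$decoy_effect] <- stats::runif(n_decoy_effect, 500, 1500)
    b
  })
  counts <- simulate_counts(sim$models, de_spec = de_spec,
                            dispersion = dispersion,
                            conditions = c("WT", mutants),
                            baseline = baseline, seed = seed + 4L)
  depth <- list(WT = simulate_depth(sim$genome, mean_depth, depth_window,
                                    noise_cv = 0.05, seed = seed + 5L,
                                    sample = "WT"))
  for (i in seq_along(mutants)) {
    depth[[mutants[i]]] <- simulate_depth(
      sim$genome, mean_depth, depth_window,
      deletions = deletions[[mutants[i]]], noise_cv = 0.05,
      seed = seed + 5L + i, sample = mutants[i])
  }
  truth <- planted$truth
  truth$planted_candidates <- sort(picks$candidates)
  truth$planted_decoy_effect <- sort(picks$decoy_effect)
  truth$planted_decoy_de <- sort(picks$decoy_de)
  truth$planted_de_genes <- de_spec
  truth$planted_deletions <- deletions
  list(genome = sim$genome, models = sim$models,
       variants = planted$variants, counts = counts, depth = depth,
       truth = truth)
}

#' Run the candidate-gene discovery pipeline
#'
#' Executes the full analysis on a study (simulated or assembled from
#' files): hard-filter and normalize each sample's variants, subtract the
#' wild type to get each mutant's private set, annotate consequences and
#' collect large-effect genes, screen coverage tracks for large deletions,
#' test differential expression per mutant against the wild type, and
#' intersect the shared concordant DEGs with the shared large-effect genes
#' into the candidate report.
#'
#' @param study List as returned by [simulate_candidate_study()] (fields
#'   `genome`, `models`, `variants`, `counts`, optional `depth`).
#' @param alpha FDR threshold for DEG calling.
#' @param fc_min Minimum linear fold change for DEG calling.
#' @param categories Consequence categories qualifying a gene as
#'   large-effect for the integration (includes `missense` by default so
#'   amino-acid changes count, as candidate reporting requires).
#' @param wt_sample Wild-type sample label.
#' @param sv_threshold,sv_min_run Deletion-screen parameters
#'   (see [flag_sv_windows()]).
#' @return List with `candidates` (the report), `shared_deg`,
#'   `shared_effect_genes`, per-mutant `private`, `effects`,
#'   `large_effect`, `de`, `degs`, `sv_flags`, and a `manifest` of
#'   per-stage record counts.
#' @export
run_candidate_pipeline <- function(study, alpha = 0.05, fc_min = 2,
                                   categories = c(LARGE_EFFECT_DEFAULT,
                                                  "missense"),
                                   wt_sample = "WT", sv_threshold = -0.8,
                                   sv_min_run = 5L) {
  genome <- study$genome
  models <- study$models
  samples <- names(study$variants)
  mutants <- setdiff(samples, wt_sample)

  filtered <- lapply(study$variants, function(vs) {
    normalize_variants(apply_hard_filter(vs), genome)
  })
  private <- lapply(mutants, function(s) {
    private_variants(filtered[[s]], filtered[[wt_sample]])
  })
  names(private) <- mutants
  effects <- lapply(private, annotate_effects, models = models,
                    genome = genome)
  large_effect <- lapply(effects, large_effect_genes, categories = categories)
  venn <- shared_gene_venn(large_effect[[1]]$all, large_effect[[2]]$all)

  de <- lapply(mutants, function(s) {
    nb_test(study$counts, contrast = c(s, wt_sample), alpha = alpha)
  })
  names(de) <- mutants
  degs <- lapply(de, call_degs, alpha = alpha, fc_min = fc_min)
  shared <- shared_degs(degs[[1]], degs[[2]])

  evidence <- do.call(rbind, unname(effects))
  report <- candidate_genes(shared, venn$shared, effects = evidence,
                            de_tables = de, categories = categories)

  sv_flags <- NULL
  if (!is.null(study$depth)) {
    sv_flags <- lapply(mutants, function(s) {
      flag_sv_windows(depth_ratio(study$depth[[s]], study$depth[[wt_sample]]),
                      threshold = sv_threshold, min_run = sv_min_run)
    })
    names(sv_flags) <- mutants
  }

  manifest <- list(
    n_input = vapply(study$variants, nrow, integer(1)),
    n_pass_filter = vapply(filtered, nrow, integer(1)),
    n_private = vapply(private, nrow, integer(1)),
    n_private_snp = vapply(private, function(v) sum(v$vclass == "SNP"), integer(1)),
    n_private_indel = vapply(private, function(v) sum(v$vclass == "INDEL"), integer(1)),
    n_large_effect_genes = vapply(large_effect, function(x) length(x$all), integer(1)),
    n_shared_large_effect_genes = length(venn$shared),
    n_degs = vapply(degs, function(d) length(d$up) + length(d$down), integer(1)),
    n_shared_up = length(shared$shared_up),
    n_shared_down = length(shared$shared_down),
    n_candidates = nrow(report))

  list(candidates = report, shared_deg = shared,
       shared_effect_genes = venn$shared, private = private,
       effects = effects, large_effect = large_effect, de = de,
       degs = degs, sv_flags = sv_flags, manifest = manifest)
}
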