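#' Sample uniform control sites
#'
#' Draws `n` single-base positions uniformly over the assembled genome
#' length (the null model for element enrichment: "an equal number of
#' randomly selected control sites").
#'
#' @param genome Named [Biostrings::DNAStringSet] or named length vector.
#' @param n Number of sites, >= 1.
#' @param seed Optional seed.
#' @return data.frame with `chrom` and `pos`.
#' @export
sample_control_sites <- function(genome, n, seed = NULL) {
  stopifnot(n >= 1)
  lens <- if (is.numeric(genome)) genome else chrom_lengths(genome)
  with_seed(seed, {
    total <- sum(as.numeric(lens))
    draw <- ceiling(stats::runif(n) * total)
    cum <- cumsum(as.numeric(lens))
    idx <- findInterval(draw - 1, cum) + 1L
    pos <- as.integer(draw - c(0, cum)[idx])
    data.frame(chrom = names(lens)[idx], pos = pos,
               stringsAsFactors = FALSE)
  })
}

#' Observed/expected element enrichment
#'
#' Classifies the observed variant positions into element classes, then
#' repeatedly draws an equal number of uniform control sites and
#' classifies those; `expected` is the mean class count over resamples and
#' `ratio = observed / expected`. Classes with zero expected count are
#' flagged `undefined` rather than reported as infinite. Run separately
#' for SNPs and indels by subsetting the input.
#'
#' @param observed data.frame with `chrom`, `pos` (a [variant_set()]
#'   works).
#' @param models List of [transcript_model()]s.
#' @param chrom_lens Named chromosome lengths.
#' @param n_resamples Number of control draws (default 100; the mean over
#'   draws stabilizes the expected counts).
#' @param seed Seed for the control sampler.
#' @param promoter_span,terminator_span Flank widths, bp.
#' @return data.frame with `element`, `observed`, `expected`,
#'   `resample_sd`, `ratio`, `undefined`; attributes `n_resamples`, `seed`.
#' @export
observed_expected <- function(observed, models, chrom_lens,
                              n_resamples = 100, seed = 1,
                              promoter_span = 2000L, terminator_span = 2000L) {
  stopifnot(n_resamples >= 1)
  n <- nrow(observed)
  er <- element_ranges(models, chrom_lens, promoter_span, terminator_span)
  count_classes <- function(sites) {
    lab <- classify_element(sites, models, chrom_lens, promoter_span,
                            terminator_span, ranges = er)
    table(factor(lab, levels = ELEMENT_LEVELS))
  }
  obs <- count_classes(observed)
  draws <- with_seed(seed, {
    all_sites <- sample_control_sites(chrom_lens, n * n_resamples)
    split(all_sites, rep(seq_len(n_resamples), each = n))
  })
  exp_mat <- vapply(draws, count_classes, numeric(length(ELEMENT_LEVELS)))
  expected <- rowMeans(exp_mat)
  sds <- apply(exp_mat, 1L, stats::sd)
  undefined <- expected == 0
  ratio <- ifelse(undefined, NA_real_, as.numeric(obs) / expected)
  out <- data.frame(element = ELEMENT_LEVELS,
                    observed = as.integer(obs),
                    expected = expected,
                    resample_sd = sds,
                    ratio = ratio,
                    undefined = undefined,
                    row.names = NULL)
  attr(out, "n_resamples") <- n_resamples
  attr(out, "seed") <- seed
  out
}

#' Hypergeometric term over-representation
#'
#' For each term: `k` genes of the query set carry it out of `n`, against
#' `K` carriers in a universe of `N`; upper-tail hypergeometric p
#' (`P(X >= k)`), BH-adjusted q, significant at q < 0.05. The term map is
#' flat (no ontology propagation).
#'
#' @param gene_set Character vector, subset of `universe`.
#' @param universe Character vector of all genes.
#' @param term_map data.frame with `gene`, `term` (one row per
#'   annotation), or named list gene -> terms.
#' @param alpha Significance threshold on q.
#' @return data.frame with `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant`, sorted by p.
#' @export
term_overrepresentation <- function(gene_set, universe, term_map,
                                    alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) {
    stop("gene_set contains genes outside the universe", call. = FALSE)
  }
  if (is.list(term_map) && !is.data.frame(term_map)) {
    term_map <- data.frame(
      gene = rep(names(term_map), lengths(term_map)),
      term = unlist(term_map, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  term_map <- unique(term_map[, c("gene", "term")])
  N <- length(universe)
  n <- length(gene_set)
  terms <- unique(term_map$term)
  K <- table(factor(term_map$term, levels = terms))
  in_set <- term_map$gene %in% gene_set
  k <- table(factor(term_map$term[in_set], levels = terms))
  p <- stats::phyper(as.numeric(k) - 1, as.numeric(K), N - as.numeric(K),
                     n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = as.integer(k), n = n,
                    K = as.integer(K), N = N, p = p,
                    q = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}
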