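#' Simulate a negative-binomial count matrix
#'
#' Draws gene-level read counts for a wild type and mutant conditions with
#' replicates: `count ~ NB(mean = baseline * lib_size * 2^log2fc,
#' dispersion)`. Genes without a planted effect have log2 fold change 0 in
#' every condition; `dispersion = 0` reduces to Poisson sampling.
#'
#' @param models List of [transcript_model()]s (supplies gene ids and
#'   exon-union gene lengths), or a character vector of gene ids (then
#'   `gene_lengths` must be given).
#' @param de_spec `NULL` or data.frame with `gene`, `condition`, `log2fc`.
#' @param dispersion NB dispersion (1/size), >= 0.
#' @param lib_sizes Relative library-size factor per sample; either one
#'   value per condition x replicate (named by sample) or a single number.
#' @param conditions Condition labels; the first is the reference.
#' @param n_reps Replicates per condition.
#' @param baseline Optional named per-gene baseline mean; default drawn
#'   log-normally (median ~200) per gene.
#' @param seed Integer seed.
#' @return A `count_matrix`: list with integer matrix `counts` (genes x
#'   samples), data.frame `samples` (`sample`, `condition`, `replicate`)
#'   and named vector `gene_lengths` (bp).
#' @export
simulate_counts <- function(models, de_spec = NULL, dispersion = 0.05,
                            lib_sizes = 1, conditions = c("WT", "hybs1", "hybs2"),
                            n_reps = 3, baseline = NULL, seed = 1,
                            gene_lengths = NULL) {
  stopifnot(dispersion >= 0, all(lib_sizes > 0))
  if (is.character(models)) {
    genes <- models
    stopifnot(!is.null(gene_lengths))
    lens <- gene_lengths[genes]
  } else {
    genes <- vapply(models, `[[`, character(1), "gene_id")
    lens <- stats::setNames(vapply(models, function(m) iv_width(m$exons), integer(1)),
                            genes)
  }
  samples <- data.frame(
    sample = paste(rep(conditions, each = n_reps), rep(seq_len(n_reps), length(conditions)), sep = "_"),
    condition = rep(conditions, each = n_reps),
    replicate = rep(seq_len(n_reps), length(conditions)),
    stringsAsFactors = FALSE)
  if (length(lib_sizes) == 1L) lib_sizes <- rep(lib_sizes, nrow(samples))
  stopifnot(length(lib_sizes) == nrow(samples))
  with_seed(seed, {
    if (is.null(baseline)) {
      baseline <- stats::setNames(stats::rlnorm(length(genes),
                                                meanlog = log(200), sdlog = 1),
                                  genes)
    }
    lfc <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                  dimnames = list(genes, samples$sample))
    if (!is.null(de_spec) && nrow(de_spec)) {
      for (i in seq_len(nrow(de_spec))) {
        cols <- samples$condition == de_spec$condition[i]
        lfc[de_spec$gene[i], cols] <- de_spec$log2fc[i]
      }
    }
    mu <- baseline[genes] * 2^lfc
    mu <- sweep(mu, 2L, lib_sizes, `*`)
    counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                     dimnames = dimnames(mu))
    if (dispersion == 0) {
      counts[] <- as.integer(stats::rpois(length(mu), lambda = mu))
    } else {
      counts[] <- as.integer(stats::rnbinom(length(mu), size = 1 / dispersion,
                                            mu = mu))
    }
    structure(list(counts = counts, samples = samples,
                   gene_lengths = lens),
              class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The TSV has gene ids in the first column (`gene_id`), a `length` column
#' and one column per sample named `<condition>_<replicate>`.
#'
#' @param cm A `count_matrix`.
#' @param path File path.
#' @return `path` (write) or a `count_matrix` (read).
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = unname(cm$gene_lengths[rownames(cm$counts)]),
                   cm$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  parts <- strsplit(colnames(counts), "_", fixed = TRUE)
  samples <- data.frame(
    sample = colnames(counts),
    condition = vapply(parts, function(p) paste(p[-length(p)], collapse = "_"), character(1)),
    replicate = as.integer(vapply(parts, function(p) p[length(p)], character(1))),
    stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples,
                 gene_lengths = stats::setNames(df$length, df$gene_id)),
            class = "count_matrix")
}
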