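# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators never clobber user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

# Fetch genome subsequence as a plain character string (1-based closed).
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in genome", call. = FALSE)
  }
  if (start < 1L || end > length(genome[[chrom]])) {
    stop("coordinates ", start, "-", end, " beyond '", chrom, "' bounds",
         call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# Row-wise interval matrix helpers; intervals are 1-based closed, columns
# "start","end", rows sorted by genomic start.
ivmat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, "start"]), , drop = FALSE]
}

iv_width <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(0L)
  sum(m[, "end"] - m[, "start"] + 1L)
}

iv_contains <- function(m, pos) {
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  any(pos >= m[, "start"] & pos <= m[, "end"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
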