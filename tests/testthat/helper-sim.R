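# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small annotated genome used by most annotation tests.
tiny_sim <- function() {
  memo("tiny_sim", simulate_genome(2, 50e3, 10, seed = 11))
}

# A hand-built plus-strand model on a synthetic chromosome whose every
# coordinate is known, for closed-form element/consequence checks:
#   promoter 1001-3000, utr5 3001-3100, CDS 3101-3250 + 3501-3602
#   (intron 3251-3500), utr3 3603-3702.
hand_model <- function() {
  memo("hand_model", {
    set.seed(42)
    utr5 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), 82, TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")  # 252 bp, 84 codons
    stopifnot(nchar(cds) == 252)
    cds1 <- substr(cds, 1, 150)
    cds2 <- substr(cds, 151, 252)
    intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 246, TRUE),
                                 collapse = ""), "AG")
    utr3 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    left <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), 46298, TRUE), collapse = "")
    seqs <- paste0(left, utr5, cds1, intron, cds2, utr3, right)
    genome <- Biostrings::DNAStringSet(c(A01 = seqs))
    model <- transcript_model(
      gene_id = "gH", tx_id = "gH.1", chrom = "A01", strand = "+",
      exons = cbind(start = c(3001L, 3501L), end = c(3250L, 3702L)),
      cds = cbind(start = c(3101L, 3501L), end = c(3250L, 3602L)),
      utr5 = cbind(start = 3001L, end = 3100L),
      utr3 = cbind(start = 3603L, end = 3702L))
    list(genome = genome, model = model)
  })
}

# variant_set builder with passing INFO values.
vs_of <- function(chrom, pos, ref, alt, sample = "s", genome_id = "synthetic") {
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         QD = 10, FS = 1, SOR = 1, MQRankSum = 0,
                         ReadPosRankSum = 0, stringsAsFactors = FALSE),
              sample = sample, genome_id = genome_id)
}
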