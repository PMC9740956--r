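#' Simulate a small annotated genome
#'
#' Generates random chromosome sequences with non-overlapping multi-exon
#' gene models on both strands. Every CDS begins with ATG, ends with a stop
#' codon, contains no internal stop, and has length divisible by 3; introns
#' carry canonical GT..AG ends; each transcript gets 5' and 3' UTRs.
#' Chromosomes are named in the allotetraploid A/B convention
#' ("A01", "B01", "A02", ...) — a naming device only, no homoeologous
#' duplication is simulated.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome, bp (>= 50 kb).
#' @param n_genes Total number of genes, distributed round-robin over
#'   chromosomes.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param flank Minimum intergenic gap reserved on each side of a gene, bp.
#'
#' @return A list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]) and `models` (a list of
#'   [transcript_model()] objects, named by transcript id).
#' @export
#' @examples
#' sim <- simulate_genome(1, 100e3, 10, seed = 1)
#' length(sim$models)
simulate_genome <- function(n_chrom, chrom_len, n_genes, seed,
                            flank = 2500L) {
  stopifnot(n_chrom >= 1, chrom_len >= 50e3, n_genes >= 1)
  chrom_len <- as.integer(chrom_len)
  with_seed(seed, {
    chroms <- chrom_names(n_chrom)
    per_chrom <- table(factor(chroms[(seq_len(n_genes) - 1L) %% n_chrom + 1L],
                              levels = chroms))
    seqs <- list()
    models <- list()
    gidx <- 0L
    for (ci in seq_len(n_chrom)) {
      chrom <- chroms[ci]
      bases <- sample(DNA_BASES, chrom_len, replace = TRUE)
      cursor <- flank + 1L
      for (k in seq_len(per_chrom[[chrom]])) {
        gidx <- gidx + 1L
        g <- random_gene_structure()
        glen <- nchar(g$seq)
        if (cursor + glen - 1L + flank > chrom_len) {
          stop("cannot pack ", n_genes, " genes of mean size ~", glen,
               " bp plus ", flank, " bp flanks into ", n_chrom, " x ",
               chrom_len, " bp", call. = FALSE)
        }
        strand <- sample(c("+", "-"), 1L)
        gene_seq <- if (strand == "-") revcomp(g$seq) else g$seq
        gstart <- cursor
        gend <- cursor + glen - 1L
        bases[gstart:gend] <- strsplit(gene_seq, "")[[1]]
        models[[gidx]] <- place_gene(g, sprintf("gene%04d", gidx),
                                     chrom, strand, gstart, gend)
        cursor <- gend + flank + sample(200:800, 1L) + 1L
      }
      seqs[[chrom]] <- paste(bases, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(models) <- vapply(models, `[[`, character(1), "tx_id")
    list(genome = genome, models = models)
  })
}

chrom_names <- function(n) {
  sub <- rep(c("A", "B"), length.out = n)
  num <- ceiling(seq_len(n) / 2)
  sprintf("%s%02d", sub, num)
}

# Draw one gene in local sense coordinates: returns the sense-strand genomic
# sequence of the locus plus exon/CDS/UTR intervals local to it (1-based).
random_gene_structure <- function() {
  utr5_len <- sample(60:200, 1L)
  utr3_len <- sample(80:250, 1L)
  n_codons <- sample(60:240, 1L)   # incl. start, excl. stop
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
                 n_codons - 1L, replace = TRUE)
  cds_seq <- paste0("ATG", paste(body, collapse = ""),
                    sample(STOP_CODONS, 1L))
  tx_seq <- paste0(random_dna(utr5_len), cds_seq, random_dna(utr3_len))
  tx_len <- nchar(tx_seq)
  n_exons <- sample(2:4, 1L)
  # split the transcript into n_exons pieces of >= 50 bp each
  repeat {
    cuts <- sort(sample(51:(tx_len - 50L), n_exons - 1L))
    widths <- diff(c(0L, cuts, tx_len))
    if (all(widths >= 50L)) break
  }
  ex_tx_end <- cumsum(widths)
  ex_tx_start <- ex_tx_end - widths + 1L
  intron_lens <- sample(80:300, n_exons - 1L, replace = TRUE)
  introns <- vapply(intron_lens, function(L) {
    paste0("GT", random_dna(L - 4L), "AG")
  }, character(1))
  # assemble locus sequence and local exon coordinates
  pieces <- character(2L * n_exons - 1L)
  local_start <- integer(n_exons)
  pos <- 1L
  for (i in seq_len(n_exons)) {
    local_start[i] <- pos
    pieces[2L * i - 1L] <- substr(tx_seq, ex_tx_start[i], ex_tx_end[i])
    pos <- pos + widths[i]
    if (i < n_exons) {
      pieces[2L * i] <- introns[i]
      pos <- pos + intron_lens[i]
    }
  }
  local_end <- local_start + widths - 1L
  list(seq = paste(pieces, collapse = ""),
       exons_local = cbind(start = local_start, end = local_end),
       exons_tx = cbind(start = ex_tx_start, end = ex_tx_end),
       cds_tx = c(utr5_len + 1L, utr5_len + nchar(cds_seq)),
       utr5_tx = c(1L, utr5_len),
       utr3_tx = c(tx_len - utr3_len + 1L, tx_len))
}

# Map transcript-coordinate intervals through the exon structure to local
# sense coordinates, then to genomic coordinates given placement and strand.
place_gene <- function(g, gene_id, chrom, strand, gstart, gend) {
  tx2local <- function(span) {
    out <- NULL
    for (i in seq_len(nrow(g$exons_tx))) {
      s <- max(span[1], g$exons_tx[i, "start"])
      e <- min(span[2], g$exons_tx[i, "end"])
      if (s <= e) {
        off <- g$exons_local[i, "start"] - g$exons_tx[i, "start"]
        out <- rbind(out, c(s + off, e + off))
      }
    }
    out
  }
  local2genomic <- function(m) {
    if (is.null(m)) return(NULL)
    if (strand == "+") {
      ivmat(gstart + m[, 1] - 1L, gstart + m[, 2] - 1L)
    } else {
      ivmat(gend - m[, 2] + 1L, gend - m[, 1] + 1L)
    }
  }
  transcript_model(
    gene_id = gene_id, tx_id = paste0(gene_id, ".1"),
    chrom = chrom, strand = strand,
    exons = local2genomic(g$exons_local),
    cds = local2genomic(tx2local(g$cds_tx)),
    utr5 = local2genomic(tx2local(g$utr5_tx)),
    utr3 = local2genomic(tx2local(g$utr3_tx)))
}

#' Write a genome to FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
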