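#' Transcript model
#'
#' A light container for one gene model: strand-aware exon, CDS and UTR
#' intervals on a single chromosome. Coordinates are 1-based closed (the
#' GFF3 convention); all internal arithmetic converts at this boundary.
#'
#' @param gene_id,tx_id Gene and transcript identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 Two-column integer matrices (`start`, `end`),
#'   1-based closed, sorted by genomic start. `cds` must be contained in
#'   `exons` and have total width divisible by 3.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, tx_id, chrom, strand, exons, cds,
                             utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- ivmat(exons[, 1], exons[, 2])
  cds <- ivmat(cds[, 1], cds[, 2])
  if (nrow(exons) > 1L && any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop("exons of ", tx_id, " overlap or are unsorted", call. = FALSE)
  }
  if (iv_width(cds) %% 3L != 0L) {
    stop("CDS length of ", tx_id, " (", iv_width(cds),
         ") is not divisible by 3", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds,
         utr5 = if (is.null(utr5) || nrow(utr5) == 0L) NULL else ivmat(utr5[, 1], utr5[, 2]),
         utr3 = if (is.null(utr3) || nrow(utr3) == 0L) NULL else ivmat(utr3[, 1], utr3[, 2]),
         tx_start = min(exons[, "start"]), tx_end = max(exons[, "end"])),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s), CDS %d bp\n",
              x$tx_id, x$gene_id, x$chrom, x$tx_start, x$tx_end, x$strand,
              nrow(x$exons), iv_width(x$cds)))
  invisible(x)
}

# Intron intervals (genomic order) of a model; NULL if single-exon.
model_introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L) return(NULL)
  ivmat(ex[-nrow(ex), "end"] + 1L, ex[-1L, "start"] - 1L)
}

# Genomic positions of the CDS in translation order (5' -> 3' of the
# transcript): ascending on "+", descending on "-".
cds_genomic_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq.int(model$cds[i, "start"], model$cds[i, "end"])
  }), use.names = FALSE)
  if (model$strand == "-") rev(pos) else pos
}

#' CDS sequence of a transcript model on the coding strand
#'
#' @param model A [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Character string (reverse-complemented for minus-strand models).
#' @export
cds_sequence <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    get_seq(genome, model$chrom, model$cds[i, "start"], model$cds[i, "end"])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

# Strand-aware flanking intervals, clipped to [1, chrom_len].
promoter_interval <- function(model, span = 2000L, chrom_len = NULL) {
  if (model$strand == "+") {
    s <- model$tx_start - span; e <- model$tx_start - 1L
  } else {
    s <- model$tx_end + 1L; e <- model$tx_end + span
  }
  clip_interval(s, e, chrom_len)
}

terminator_interval <- function(model, span = 2000L, chrom_len = NULL) {
  if (model$strand == "+") {
    s <- model$tx_end + 1L; e <- model$tx_end + span
  } else {
    s <- model$tx_start - span; e <- model$tx_start - 1L
  }
  clip_interval(s, e, chrom_len)
}

clip_interval <- function(s, e, chrom_len) {
  s <- max(1L, as.integer(s))
  if (!is.null(chrom_len)) e <- min(as.integer(chrom_len), as.integer(e))
  if (e < s) return(NULL)
  ivmat(s, e)
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features with
#' ID/Parent links, via [rtracklayer::export.gff3()].
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- lapply(models, function(m) {
    feat <- function(type, iv, id = NA_character_, parent = NA_character_,
                     phase = NA_integer_) {
      if (is.null(iv)) return(NULL)
      data.frame(chrom = m$chrom, start = iv[, "start"], end = iv[, "end"],
                 strand = m$strand, type = type, ID = id, Parent = parent,
                 phase = phase, stringsAsFactors = FALSE)
    }
    cds_phase <- cds_phases(m)
    rbind(
      feat("gene", ivmat(m$tx_start, m$tx_end), id = m$gene_id),
      feat("mRNA", ivmat(m$tx_start, m$tx_end), id = m$tx_id, parent = m$gene_id),
      feat("exon", m$exons, parent = m$tx_id),
      feat("CDS", m$cds, parent = m$tx_id, phase = cds_phase),
      feat("five_prime_UTR", m$utr5, parent = m$tx_id),
      feat("three_prime_UTR", m$utr3, parent = m$tx_id))
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GFF3 phase column for CDS rows (genomic order).
cds_phases <- function(m) {
  n <- nrow(m$cds)
  widths <- m$cds[, "end"] - m$cds[, "start"] + 1L
  tx_order <- if (m$strand == "-") rev(seq_len(n)) else seq_len(n)
  ph_tx <- integer(n)
  acc <- 0L
  for (k in seq_len(n)) {
    ph_tx[k] <- (3L - acc %% 3L) %% 3L
    acc <- acc + widths[tx_order[k]]
  }
  ph <- integer(n)
  ph[tx_order] <- ph_tx
  ph
}

#' Read gene models from GFF3
#'
#' Reconstructs [transcript_model()] objects from a GFF3 file with
#' gene/mRNA/exon/CDS/UTR features (as written by [write_gff3()]).
#'
#' @param path GFF3 file path.
#' @return List of `transcript_model` objects, named by transcript id.
#' @export
read_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  mrna <- gr[type == "mRNA"]
  models <- lapply(seq_along(mrna), function(i) {
    tid <- mrna$ID[i]
    sub <- gr[!is.na(parent) & parent == tid]
    stype <- as.character(sub$type)
    pick <- function(tt) {
      s <- sub[stype == tt]
      if (length(s) == 0L) return(NULL)
      ivmat(GenomicRanges::start(s), GenomicRanges::end(s))
    }
    transcript_model(
      gene_id = parent[which(gr$ID == tid & type == "mRNA")][1],
      tx_id = tid,
      chrom = as.character(GenomicRanges::seqnames(mrna[i])),
      strand = as.character(GenomicRanges::strand(mrna[i])),
      exons = pick("exon"), cds = pick("CDS"),
      utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
  })
  names(models) <- vapply(models, `[[`, character(1), "tx_id")
  models
}
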