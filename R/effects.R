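#' Consequence categories
#'
#' Severity-ordered consequence vocabulary. The default large-effect set is
#' splice-site disruption, start-codon loss, stop-codon gain/loss and
#' frameshift; `missense` can be added for candidate-gene integration,
#' where amino-acid changes count as gene-product mutations.
#'
#' @export
CONSEQUENCE_LEVELS <- c("splice_acceptor", "splice_donor", "start_lost",
                        "stop_gained", "stop_lost", "frameshift",
                        "missense", "synonymous", "none")

#' @rdname CONSEQUENCE_LEVELS
#' @export
LARGE_EFFECT_DEFAULT <- c("splice_acceptor", "splice_donor", "start_lost",
                          "stop_gained", "stop_lost", "frameshift")

ELEMENT_LEVELS <- c("exon", "utr5", "utr3", "intron", "promoter",
                    "terminator", "intergenic")

# Per-class GRanges over all models; "exon" means coding exon (CDS).
element_ranges <- function(models, chrom_lens, promoter_span = 2000L,
                           terminator_span = 2000L) {
  grab <- function(f) {
    rows <- lapply(models, function(m) {
      iv <- f(m)
      if (is.null(iv)) return(NULL)
      data.frame(chrom = m$chrom, start = iv[, "start"], end = iv[, "end"])
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  list(
    exon = grab(function(m) m$cds),
    utr5 = grab(function(m) m$utr5),
    utr3 = grab(function(m) m$utr3),
    intron = grab(model_introns),
    promoter = grab(function(m) promoter_interval(m, promoter_span,
                                                  chrom_lens[[m$chrom]])),
    terminator = grab(function(m) terminator_interval(m, terminator_span,
                                                      chrom_lens[[m$chrom]])))
}

#' Classify positions into genomic element classes
#'
#' Assigns each position the single summary label used for class-count
#' tallies, by precedence exon > 5' UTR > 3' UTR > intron > promoter >
#' terminator > intergenic ("exon" = coding exon). Promoter/terminator are
#' strand-aware 2-kb flanks by default.
#'
#' @param sites data.frame with `chrom` and `pos` columns (a
#'   [variant_set()] works).
#' @param models List of [transcript_model()]s.
#' @param chrom_lens Named integer vector of chromosome lengths (e.g.
#'   `chrom_lengths(genome)`).
#' @param promoter_span,terminator_span Flank widths in bp.
#' @param ranges Precomputed element ranges (internal; built from `models`
#'   when `NULL`). Lets callers classifying many batches against the same
#'   annotation pay the indexing cost once.
#' @return Character vector of element labels, one per row of `sites`.
#' @export
classify_element <- function(sites, models, chrom_lens,
                             promoter_span = 2000L, terminator_span = 2000L,
                             ranges = NULL) {
  if (any(!(sites$chrom %in% names(chrom_lens)))) {
    stop("position on unknown chromosome", call. = FALSE)
  }
  if (any(sites$pos > chrom_lens[sites$chrom] | sites$pos < 1L)) {
    bad <- which(sites$pos > chrom_lens[sites$chrom] | sites$pos < 1L)[1]
    stop("position ", sites$chrom[bad], ":", sites$pos[bad],
         " beyond chromosome end", call. = FALSE)
  }
  er <- ranges %||% element_ranges(models, chrom_lens, promoter_span,
                                   terminator_span)
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  labels <- rep("intergenic", nrow(sites))
  for (cls in rev(setdiff(ELEMENT_LEVELS, "intergenic"))) {
    hit <- IRanges::overlapsAny(q, er[[cls]])
    labels[hit] <- cls
  }
  labels
}

# Per-model lookup used by the consequence caller (and by plant_variants).
model_cache <- function(model, genome) {
  list(cds_pos = cds_genomic_positions(model),
       cds_seq = cds_sequence(model, genome),
       introns = model_introns(model))
}

#' Call the functional consequence of a variant on one transcript
#'
#' Deterministic rules, strand-aware:
#' * a variant in the first 2 intronic bp (transcription order) is a
#'   `splice_donor`, in the last 2 a `splice_acceptor`;
#' * a CDS SNP disrupting the initiator codon is `start_lost`; creating an
#'   in-frame stop, `stop_gained`; destroying the terminal stop,
#'   `stop_lost`; otherwise `missense` or `synonymous` by the genetic code;
#' * a CDS indel whose length change is not a multiple of 3 is a
#'   `frameshift`; an in-frame indel is `none` unless it removes the start
#'   or stop codon;
#' * anything else is `none`.
#'
#' Indels are classified by their anchored start position.
#'
#' @param variant One-row data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (normalized).
#' @param model A [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param cache Optional precomputed [model_cache] (internal speed-up).
#' @return A list with `element`, `consequence` and `is_large_effect`.
#' @export
classify_consequence <- function(variant, model, genome, cache = NULL) {
  if (iv_width(model$cds) %% 3L != 0L) {
    stop("CDS of ", model$tx_id, " violates the divisibility-by-3 invariant",
         call. = FALSE)
  }
  if (is.null(cache)) cache <- model_cache(model, genome)
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  is_indel <- nchar(ref) != nchar(alt)
  # anchored start: for a normalized indel the first base is the anchor and
  # the change begins one base to its right
  eff_pos <- if (is_indel) pos + 1L else pos
  element <- element_within_model(eff_pos, model, genome)

  consequence <- "none"
  if (element == "intron") {
    consequence <- splice_call(eff_pos, cache$introns, model$strand)
  } else if (element == "exon") {
    if (!is_indel) {
      consequence <- snp_cds_call(pos, alt, model, cache)
    } else {
      shift <- abs(nchar(alt) - nchar(ref)) %% 3L
      if (shift != 0L) {
        consequence <- "frameshift"
      } else {
        consequence <- inframe_indel_call(pos, ref, alt, model, cache)
      }
    }
  }
  list(element = element,
       consequence = consequence,
       is_large_effect = consequence %in% LARGE_EFFECT_DEFAULT)
}

# Element of a position relative to one transcript (no cross-gene
# precedence here; used per overlapping transcript).
element_within_model <- function(pos, model, genome) {
  if (iv_contains(model$cds, pos)) return("exon")
  if (iv_contains(model$utr5, pos)) return("utr5")
  if (iv_contains(model$utr3, pos)) return("utr3")
  intr <- model_introns(model)
  if (!is.null(intr) && iv_contains(intr, pos)) return("intron")
  cl <- chrom_lengths(genome)[[model$chrom]]
  if (iv_contains(promoter_interval(model, chrom_len = cl), pos)) return("promoter")
  if (iv_contains(terminator_interval(model, chrom_len = cl), pos)) return("terminator")
  "intergenic"
}

splice_call <- function(pos, introns, strand) {
  for (i in seq_len(nrow(introns))) {
    s <- introns[i, "start"]; e <- introns[i, "end"]
    if (pos < s || pos > e) next
    at_left <- pos <= s + 1L
    at_right <- pos >= e - 1L
    if (strand == "+") {
      if (at_left) return("splice_donor")
      if (at_right) return("splice_acceptor")
    } else {
      if (at_right) return("splice_donor")
      if (at_left) return("splice_acceptor")
    }
    return("none")
  }
  "none"
}

snp_cds_call <- function(pos, alt, model, cache) {
  idx <- match(pos, cache$cds_pos)
  alt_tx <- if (model$strand == "-") comp_base(alt) else alt
  codon_i <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substr(cache$cds_seq, 3L * codon_i - 2L, 3L * codon_i)
  new_codon <- codon
  substr(new_codon, within, within) <- alt_tx
  n_codons <- nchar(cache$cds_seq) %/% 3L
  if (codon_i == 1L) {
    if (new_codon == "ATG") return("synonymous")
    return("start_lost")
  }
  if (codon_i == n_codons) {
    if (new_codon %in% STOP_CODONS) return("synonymous")
    return("stop_lost")
  }
  if (new_codon %in% STOP_CODONS) return("stop_gained")
  if (translate_codon(new_codon) == translate_codon(codon)) return("synonymous")
  "missense"
}

inframe_indel_call <- function(pos, ref, alt, model, cache) {
  # deletion removing the start or stop codon
  if (nchar(ref) > nchar(alt)) {
    removed <- seq.int(pos + 1L, pos + nchar(ref) - 1L)
    n <- length(cache$cds_pos)
    start_codon <- cache$cds_pos[1:3]
    stop_codon <- cache$cds_pos[(n - 2L):n]
    if (any(start_codon %in% removed)) return("start_lost")
    if (any(stop_codon %in% removed)) return("stop_lost")
  }
  "none"
}

#' Annotate a variant set with per-transcript effect calls
#'
#' One row per variant x overlapping transcript; variants overlapping no
#' transcript get a single row with the summary element label and
#' consequence `none`.
#'
#' @param vs A normalized [variant_set()].
#' @param models List of [transcript_model()]s.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param promoter_span,terminator_span Flank widths, bp.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `vclass`,
#'   `gene_id`, `tx_id`, `element`, `consequence`, `is_large_effect`.
#' @export
annotate_effects <- function(vs, models, genome,
                             promoter_span = 2000L, terminator_span = 2000L) {
  chrom_lens <- chrom_lengths(genome)
  if (nrow(vs) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vclass = character(),
                      gene_id = character(), tx_id = character(),
                      element = character(), consequence = character(),
                      is_large_effect = logical()))
  }
  tx_gr <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(models, `[[`, integer(1), "tx_start"),
                     vapply(models, `[[`, integer(1), "tx_end")))
  q <- GenomicRanges::GRanges(vs$chrom, IRanges::IRanges(vs$pos, vs$pos))
  hits <- GenomicRanges::findOverlaps(q, tx_gr)
  summary_label <- classify_element(vs, models, chrom_lens,
                                    promoter_span, terminator_span)
  caches <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(vs))
  hit_q <- S4Vectors::queryHits(hits)
  hit_s <- S4Vectors::subjectHits(hits)
  for (i in seq_len(nrow(vs))) {
    tx_idx <- hit_s[hit_q == i]
    if (length(tx_idx) == 0L) {
      rows[[i]] <- data.frame(
        chrom = vs$chrom[i], pos = vs$pos[i], ref = vs$ref[i],
        alt = vs$alt[i], vclass = vs$vclass[i],
        gene_id = NA_character_, tx_id = NA_character_,
        element = summary_label[i], consequence = "none",
        is_large_effect = FALSE, stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- do.call(rbind, lapply(tx_idx, function(j) {
      m <- models[[j]]
      key <- m$tx_id
      if (is.null(caches[[key]])) caches[[key]] <- model_cache(m, genome)
      call <- classify_consequence(vs[i, , drop = FALSE], m, genome,
                                   cache = caches[[key]])
      data.frame(chrom = vs$chrom[i], pos = vs$pos[i], ref = vs$ref[i],
                 alt = vs$alt[i], vclass = vs$vclass[i],
                 gene_id = m$gene_id, tx_id = m$tx_id,
                 element = call$element, consequence = call$consequence,
                 is_large_effect = call$is_large_effect,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes carrying large-effect variants
#'
#' @param effects Effect table from [annotate_effects()].
#' @param categories Consequence categories that count as large-effect.
#' @return List with gene-id character vectors `snp`, `indel` (by variant
#'   class of the triggering record) and `all`.
#' @export
large_effect_genes <- function(effects, categories = LARGE_EFFECT_DEFAULT) {
  stopifnot(all(categories %in% CONSEQUENCE_LEVELS))
  hit <- effects$consequence %in% categories & !is.na(effects$gene_id)
  list(snp = sort(unique(effects$gene_id[hit & effects$vclass == "SNP"])),
       indel = sort(unique(effects$gene_id[hit & effects$vclass == "INDEL"])),
       all = sort(unique(effects$gene_id[hit])))
}

#' Two-set Venn partition of gene sets
#'
#' @param s1,s2 Character vectors of gene ids.
#' @return List with sets `only1`, `only2`, `shared` and `counts`
#'   (`c(only1, only2, shared)`).
#' @export
shared_gene_venn <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  shared <- intersect(s1, s2)
  only1 <- setdiff(s1, s2)
  only2 <- setdiff(s2, s1)
  list(only1 = sort(only1), only2 = sort(only2), shared = sort(shared),
       counts = c(only1 = length(only1), only2 = length(only2),
                  shared = length(shared)))
}

#' Element-class and consequence count summary
#'
#' @param effects Effect table from [annotate_effects()].
#' @param summary_elements Element labels per unique variant (from
#'   [classify_element()]); if `NULL` they are recomputed from the
#'   per-transcript rows by precedence.
#' @return data.frame of counts per element class and per large-effect
#'   consequence, split by SNP/indel.
#' @export
effect_count_table <- function(effects, summary_elements = NULL) {
  key <- paste(effects$chrom, effects$pos, effects$ref, effects$alt)
  firsts <- !duplicated(key)
  if (is.null(summary_elements)) {
    elem <- factor(effects$element, levels = ELEMENT_LEVELS)
    best <- tapply(as.integer(elem), key, min)
    summary_elements <- ELEMENT_LEVELS[best[unique(key)]]
  }
  vclass1 <- effects$vclass[firsts]
  elem_tab <- table(element = factor(summary_elements, levels = ELEMENT_LEVELS),
                    vclass = factor(vclass1, levels = c("SNP", "INDEL")))
  cons_hit <- effects$consequence %in% LARGE_EFFECT_DEFAULT
  cons_tab <- table(
    consequence = factor(effects$consequence[cons_hit],
                         levels = LARGE_EFFECT_DEFAULT),
    vclass = factor(effects$vclass[cons_hit], levels = c("SNP", "INDEL")))
  rbind(as.data.frame.matrix(elem_tab), as.data.frame.matrix(cons_tab))
}
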