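# Independent consequence oracle: apply the variant to the raw chromosome
# sequence, re-extract the (shifted) CDS, translate the whole thing by
# direct genetic-code lookup, and classify by comparing proteins. Shares no
# code path with classify_consequence, which reasons locally about one
# codon.

oracle_translate <- function(s) {
  n <- nchar(s)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

oracle_extract_cds <- function(chrom_seq, cds_iv, strand) {
  s <- paste(substring(chrom_seq, cds_iv[, 1], cds_iv[, 2]), collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

oracle_consequence <- function(chrom_seq, pos, ref, alt, cds_iv, strand,
                               cds0 = NULL, p0 = NULL) {
  delta <- nchar(alt) - nchar(ref)
  mut_seq <- paste0(substr(chrom_seq, 1, pos - 1L), alt,
                    substr(chrom_seq, pos + nchar(ref), nchar(chrom_seq)))
  shift <- function(x) ifelse(x > pos, x + delta, x)
  mut_iv <- cbind(shift(cds_iv[, 1]), shift(cds_iv[, 2]))
  if (is.null(cds0)) cds0 <- oracle_extract_cds(chrom_seq, cds_iv, strand)
  cds1 <- oracle_extract_cds(mut_seq, mut_iv, strand)
  if (nchar(cds1) %% 3L != 0L) return("frameshift")
  if (is.null(p0)) p0 <- oracle_translate(cds0)
  p1 <- oracle_translate(cds1)
  if (p1 == p0) return("synonymous")
  if (substr(p1, 1, 1) != "M") return("start_lost")
  internal1 <- substr(p1, 1, nchar(p1) - 1L)
  internal0 <- substr(p0, 1, nchar(p0) - 1L)
  if (grepl("[*]", internal1) && !grepl("[*]", internal0)) return("stop_gained")
  if (substr(p1, nchar(p1), nchar(p1)) != "*") return("stop_lost")
  "missense"
}

# Draw one random CDS variant (SNP or frameshifting indel) on a model.
random_cds_variant <- function(model, chrom_seq, p_indel = 0.2) {
  cds_pos <- sort(unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq.int(model$cds[i, "start"], model$cds[i, "end"])
  })))
  if (stats::runif(1) < p_indel) {
    # insertion anchored inside the CDS (anchored change stays in CDS)
    ok <- cds_pos[c(diff(cds_pos) == 1L, FALSE)]
    pos <- sample(ok, 1L)
    b <- substr(chrom_seq, pos, pos)
    L <- sample(c(1L, 2L, 4L), 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    if (substr(ins, L, L) == b) {
      substr(ins, L, L) <- setdiff(c("A", "C", "G", "T"), b)[1]
    }
    list(pos = pos, ref = b, alt = paste0(b, ins))
  } else {
    pos <- sample(cds_pos, 1L)
    b <- substr(chrom_seq, pos, pos)
    list(pos = pos, ref = b, alt = sample(setdiff(c("A", "C", "G", "T"), b), 1L))
  }
}

# Run n random CDS variants through both routes; returns fraction agreeing
# and the first few disagreements for diagnosis.
oracle_agreement <- function(sim, n, p_indel = 0.2) {
  models <- Filter(function(m) nrow(m$cds) >= 1, sim$models)
  chrom_strings <- lapply(sim$genome, as.character)
  caches <- lapply(models, mutcand:::model_cache, genome = sim$genome)
  cds0 <- lapply(models, function(m) {
    oracle_extract_cds(chrom_strings[[m$chrom]], m$cds, m$strand)
  })
  p0 <- lapply(cds0, oracle_translate)
  agree <- logical(n)
  mismatches <- list()
  model_idx <- sample(length(models), n, replace = TRUE)
  for (i in seq_len(n)) {
    j <- model_idx[i]
    m <- models[[j]]
    v <- random_cds_variant(m, chrom_strings[[m$chrom]], p_indel = p_indel)
    got <- classify_consequence(
      data.frame(chrom = m$chrom, pos = v$pos, ref = v$ref, alt = v$alt),
      m, sim$genome, cache = caches[[j]])$consequence
    want <- oracle_consequence(chrom_strings[[m$chrom]], v$pos, v$ref, v$alt,
                               m$cds, m$strand, cds0 = cds0[[j]], p0 = p0[[j]])
    agree[i] <- identical(got, want)
    if (!agree[i] && length(mismatches) < 5) {
      mismatches[[length(mismatches) + 1]] <-
        sprintf("%s:%d %s>%s got=%s want=%s (%s)", m$chrom, v$pos, v$ref,
                v$alt, got, want, m$tx_id)
    }
  }
  list(fraction = mean(agree), mismatches = mismatches)
}
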