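#' Variant sets
#'
#' A `variant_set` is a data.frame of normalized biallelic variant records —
#' one row per (chrom, pos, ref, alt) key — with the GATK INFO metrics used
#' by the hard filter (`QD`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`;
#' `NA` when absent) and a `vclass` column separating SNPs from indels.
#' Rows are sorted by (chrom, pos, ref, alt) and keys are unique. Genotype
#' fields play no role: presence of a record is presence of the variant.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param sample Sample label.
#' @param genome_id Identifier of the reference the records are called
#'   against; set subtraction refuses to mix genome ids.
#'
#' @return A `variant_set` (classed data.frame).
#' @export
variant_set <- function(df, sample = NA_character_, genome_id = NA_character_) {
  info_cols <- c("QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  for (col in info_cols) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
      if (length(bad)) {
        stop("non-numeric INFO value '", df[[col]][bad[1]], "' for ", col,
             " at ", df$chrom[bad[1]], ":", df$pos[bad[1]], call. = FALSE)
      }
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
  }
  if (nrow(df)) {
    stopifnot(all(nchar(df$ref) > 0), all(nchar(df$alt) > 0),
              all(df$pos >= 1), all(df$ref != df$alt))
  }
  df$pos <- as.integer(df$pos)
  df$vclass <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNP", "INDEL")
  if (!"filter_status" %in% names(df)) {
    df$filter_status <- rep(NA_character_, nrow(df))
  }
  df <- df[, c("chrom", "pos", "ref", "alt", "vclass", info_cols, "filter_status")]
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  keys <- variant_keys(df)
  dup <- duplicated(keys)
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample = sample, genome_id = genome_id,
            class = c("variant_set", "data.frame"))
}

#' Variant identity keys
#'
#' `chrom:pos:ref:alt` strings — the atomic identity used for all set
#' arithmetic (subtraction, intersection, truth comparison).
#'
#' @param vs A [variant_set()] (any data.frame with those columns works).
#' @return Character vector of keys, one per record.
#' @export
variant_keys <- function(vs) {
  paste(vs$chrom, vs$pos, vs$ref, vs$alt, sep = ":")
}

vs_attrs <- function(vs) {
  list(sample = attr(vs, "sample"), genome_id = attr(vs, "genome_id"))
}

restore_vs <- function(df, template) {
  variant_set(df, sample = attr(template, "sample"),
              genome_id = attr(template, "genome_id"))
}

#' Apply the GATK-style hard filter
#'
#' A record fails when any *present* metric violates its bound:
#' `QD < 2.0`, `FS > 200.0`, `SOR > 10.0`, `MQRankSum < -12.5`, or
#' `ReadPosRankSum < -8.0` (all strict). Records with a metric absent are
#' judged on the metrics they do carry; a record at exactly the bounds
#' passes.
#'
#' @param vs A [variant_set()].
#' @return The PASS subset, with `filter_status` set; the number of removed
#'   records is in `attr(, "n_filtered")`.
#' @export
apply_hard_filter <- function(vs) {
  viol <- function(x, bad) !is.na(x) & bad(x)
  fails <- viol(vs$QD, function(x) x < 2.0) |
    viol(vs$FS, function(x) x > 200.0) |
    viol(vs$SOR, function(x) x > 10.0) |
    viol(vs$MQRankSum, function(x) x < -12.5) |
    viol(vs$ReadPosRankSum, function(x) x < -8.0)
  vs$filter_status <- ifelse(fails, "FILTERED", "PASS")
  out <- restore_vs(vs[!fails, , drop = FALSE], vs)
  attr(out, "n_filtered") <- sum(fails)
  out
}

#' Normalize variant records against a genome
#'
#' Splits MNPs (equal-length ref/alt longer than 1 bp) into per-base SNPs,
#' trims shared prefix/suffix to the minimal representation with a single
#' anchor base, and left-aligns indels as far as the reference sequence
#' allows, so that any two spellings of the same allele share one key.
#' Idempotent.
#'
#' @param vs A [variant_set()].
#' @param genome Named [Biostrings::DNAStringSet]; every record's `ref`
#'   must match the genome at its coordinates (else an error naming the
#'   record).
#' @return A normalized [variant_set()].
#' @export
normalize_variants <- function(vs, genome) {
  if (nrow(vs) == 0L) return(vs)
  rows <- vector("list", nrow(vs))
  for (i in seq_len(nrow(vs))) {
    rows[[i]] <- normalize_one(vs$chrom[i], vs$pos[i], vs$ref[i], vs$alt[i],
                               genome, vs[i, , drop = FALSE])
  }
  restore_vs(do.call(rbind, rows), vs)
}

normalize_one <- function(chrom, pos, ref, alt, genome, row) {
  ref <- toupper(ref); alt <- toupper(alt)
  obs <- get_seq(genome, chrom, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop("REF mismatch at ", chrom, ":", pos, " — record has '", ref,
         "', genome has '", obs, "'", call. = FALSE)
  }
  if (ref == alt) {
    stop("degenerate record at ", chrom, ":", pos, " (ref equals alt)",
         call. = FALSE)
  }
  out_row <- function(p, r, a) {
    row$pos <- as.integer(p); row$ref <- r; row$alt <- a
    row
  }
  # MNP: decompose into component SNPs
  if (nchar(ref) == nchar(alt) && nchar(ref) > 1L) {
    rb <- strsplit(ref, "")[[1]]; ab <- strsplit(alt, "")[[1]]
    idx <- which(rb != ab)
    return(do.call(rbind, lapply(idx, function(j) {
      out_row(pos + j - 1L, rb[j], ab[j])
    })))
  }
  # vt-style trim + left-align loop
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) {  # cannot extend left past the chromosome start
          b <- get_seq(genome, chrom, pos + nchar(ref), pos + nchar(ref))
          ref <- paste0(ref, b); alt <- paste0(alt, b)
          break
        }
        b <- get_seq(genome, chrom, pos - 1L, pos - 1L)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else if (nchar(ref) >= 2L && nchar(alt) >= 2L &&
               substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substring(ref, 2L); alt <- substring(alt, 2L)
      pos <- pos + 1L
    } else {
      break
    }
  }
  if (ref == alt) {
    stop("degenerate record at ", chrom, ":", pos, " (ref equals alt after trimming)",
         call. = FALSE)
  }
  out_row(pos, ref, alt)
}

#' Mutant-private variants
#'
#' Records of `mutant` whose (chrom, pos, ref, alt) key is absent from
#' `wt` — the "induced variant" set attributed to mutagenesis. Both sets
#' must be normalized against the same genome.
#'
#' @param mutant,wt [variant_set()]s called against the same reference.
#' @return A [variant_set()] of the private records; SNP/indel subtotals in
#'   `attr(, "n_snp")` / `attr(, "n_indel")`.
#' @export
private_variants <- function(mutant, wt) {
  check_same_genome(mutant, wt)
  keep <- !(variant_keys(mutant) %in% variant_keys(wt))
  out <- restore_vs(mutant[keep, , drop = FALSE], mutant)
  attr(out, "n_snp") <- sum(out$vclass == "SNP")
  attr(out, "n_indel") <- sum(out$vclass == "INDEL")
  out
}

#' Variants shared between two sets
#'
#' Key intersection of two (private) variant sets — the variant-level
#' building block under gene-level sharing.
#'
#' @param p1,p2 [variant_set()]s.
#' @return A [variant_set()] with the intersection (records taken from `p1`).
#' @export
shared_variants <- function(p1, p2) {
  check_same_genome(p1, p2)
  keep <- variant_keys(p1) %in% variant_keys(p2)
  restore_vs(p1[keep, , drop = FALSE], p1)
}

check_same_genome <- function(a, b) {
  ga <- attr(a, "genome_id"); gb <- attr(b, "genome_id")
  if (!is.na(ga) && !is.na(gb) && ga != gb) {
    stop("variant sets come from different genomes ('", ga, "' vs '", gb,
         "')", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-sample variant count summary
#'
#' @param ... Named [variant_set()]s (e.g. `WT = wt, hybs1_private = p1`).
#' @return data.frame with one row per class (SNP, INDEL) and one column
#'   per set.
#' @export
variant_count_table <- function(...) {
  sets <- list(...)
  out <- data.frame(variant = c("SNP", "INDEL"))
  for (nm in names(sets)) {
    out[[nm]] <- c(sum(sets[[nm]]$vclass == "SNP"),
                   sum(sets[[nm]]$vclass == "INDEL"))
  }
  out
}

#' Read a VCF into a variant_set
#'
#' Reads VCFv4.2 (plain or bgzipped) via [vcfR::read.vcfR()], splits
#' multi-allelic rows into biallelic records, and extracts the hard-filter
#' INFO metrics.
#'
#' @param path VCF file path.
#' @param sample Sample label (defaults to the file stem).
#' @param genome_id Optional reference identifier.
#' @return A [variant_set()].
#' @export
read_vcf_variants <- function(path, sample = NULL,
                              genome_id = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_cols <- c("QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  info <- lapply(info_cols, function(k) {
    x <- vcfR::extract.info(v, element = k)
    bad <- which(!is.na(x) & x != "." & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad)) {
      stop("non-numeric INFO value '", x[bad[1]], "' for ", k, " at ",
           fix$CHROM[bad[1]], ":", fix$POS[bad[1]], call. = FALSE)
    }
    suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  })
  names(info) <- info_cols
  rows <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = toupper(fix$REF), alt = toupper(fix$ALT),
                     info, stringsAsFactors = FALSE)
  # split multi-allelic ALT lists into biallelic rows
  alts <- strsplit(rows$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rows <- rows[rep(seq_len(nrow(rows)), n_alt), , drop = FALSE]
  rows$alt <- unlist(alts)
  rows <- rows[rows$alt != "*", , drop = FALSE]
  variant_set(rows,
              sample = sample %||% sub("\\.vcf(\\.gz)?$", "", basename(path)),
              genome_id = genome_id)
}

#' Write a variant_set as VCFv4.2
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param genome Optional genome ([Biostrings::DNAStringSet]) used to emit
#'   contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=mutcand"),
           if (!is.null(genome)) {
             sprintf("##contig=<ID=%s,length=%d>", names(genome),
                     Biostrings::width(genome))
           },
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info <- apply(cbind(QD = fmt_num(vs$QD), FS = fmt_num(vs$FS),
                      SOR = fmt_num(vs$SOR), MQRankSum = fmt_num(vs$MQRankSum),
                      ReadPosRankSum = fmt_num(vs$ReadPosRankSum)),
                1L, function(r) {
                  r <- r[!is.na(r)]
                  if (!length(r)) "." else paste(names(r), r, sep = "=", collapse = ";")
                })
  filt <- ifelse(is.na(vs$filter_status), ".",
                 ifelse(vs$filter_status == "PASS", "PASS", "hard_filter"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  vs$chrom, vs$pos, vs$ref, vs$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}
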