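#' Simulate hard-filter INFO metrics
#'
#' Draws the five GATK metrics uniformly inside their passing ranges; a
#' `fail_fraction` of records instead gets one metric planted beyond its
#' bound, so the filter's decisions can be checked against known truth.
#'
#' @param n Number of records.
#' @param fail_fraction Fraction of records given one failing metric.
#' @param seed Optional seed.
#' @return data.frame with columns `QD`, `FS`, `SOR`, `MQRankSum`,
#'   `ReadPosRankSum` and logical `passes`.
#' @export
simulate_info_fields <- function(n, fail_fraction = 0, seed = NULL) {
  with_seed(seed, {
    out <- data.frame(
      QD = stats::runif(n, 5, 30),
      FS = stats::runif(n, 0, 50),
      SOR = stats::runif(n, 0.5, 3),
      MQRankSum = stats::runif(n, -3, 3),
      ReadPosRankSum = stats::runif(n, -3, 3),
      passes = TRUE)
    n_fail <- round(n * fail_fraction)
    if (n_fail > 0L) {
      idx <- sample.int(n, n_fail)
      which_metric <- sample.int(5L, n_fail, replace = TRUE)
      for (k in seq_len(n_fail)) {
        i <- idx[k]
        switch(which_metric[k],
               out$QD[i] <- stats::runif(1, 0, 1.9),
               out$FS[i] <- stats::runif(1, 210, 400),
               out$SOR[i] <- stats::runif(1, 10.5, 15),
               out$MQRankSum[i] <- stats::runif(1, -20, -13),
               out$ReadPosRankSum[i] <- stats::runif(1, -12, -8.5))
      }
      out$passes[idx] <- FALSE
    }
    out
  })
}

#' Plant a variant trio with known truth
#'
#' Builds per-sample variant sets for a wild type plus mutants: `n_shared`
#' background variants present in all samples, `n_private[s]` extra
#' background variants private to each mutant, and engineered large-effect
#' variants (`planted_effects`) guaranteed to produce their intended
#' consequence category. Background variants are placed outside transcript
#' spans so that the planted large-effect gene list is exhaustive. All
#' emitted records are normalized; planted effect variants always carry
#' passing INFO metrics, while `fail_fraction` of background records get a
#' failing metric.
#'
#' @param genome,models Output of [simulate_genome()].
#' @param n_shared Background variants shared by all samples.
#' @param n_private Named integer vector of private background counts per
#'   mutant (e.g. `c(hybs1 = 100, hybs2 = 120)`).
#' @param planted_effects `NULL` or data.frame with columns `sample`,
#'   `gene`, `category` (category in [CONSEQUENCE_LEVELS]).
#' @param seed Integer seed.
#' @param fail_fraction Fraction of background records with a planted
#'   hard-filter failure.
#' @param indel_fraction Fraction of background variants that are indels.
#' @param wt_sample Label of the wild-type sample.
#'
#' @return List with `variants` (named list of [variant_set()]s, wild type
#'   first) and `truth` (planted private keys per mutant, planted
#'   large-effect genes with categories, failing-record keys, seed).
#' @export
plant_variants <- function(genome, models, n_shared, n_private,
                           planted_effects = NULL, seed = 1,
                           fail_fraction = 0, indel_fraction = 0.25,
                           wt_sample = "WT") {
  stopifnot(!is.null(names(n_private)))
  if (!is.null(planted_effects) && nrow(planted_effects) > 0) {
    stopifnot(all(c("sample", "gene", "category") %in% names(planted_effects)))
    ok <- c("splice_acceptor", "splice_donor", "start_lost", "stop_gained",
            "stop_lost", "frameshift", "missense", "synonymous")
    if (!all(planted_effects$category %in% ok)) {
      stop("unsupported consequence category in planted_effects", call. = FALSE)
    }
  }
  with_seed(seed, {
    mutants <- names(n_private)
    gene_ids <- vapply(models, `[[`, character(1), "gene_id")

    # engineered effect variants first, so background sampling can avoid them
    eng <- NULL
    if (!is.null(planted_effects) && nrow(planted_effects) > 0) {
      eng <- do.call(rbind, lapply(seq_len(nrow(planted_effects)), function(i) {
        gene <- planted_effects$gene[i]
        m <- models[[match(gene, gene_ids)]]
        if (is.null(m)) stop("unknown gene '", gene, "'", call. = FALSE)
        v <- engineer_effect_variant(m, planted_effects$category[i], genome)
        data.frame(sample = planted_effects$sample[i], gene = gene,
                   category = planted_effects$category[i],
                   chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                   stringsAsFactors = FALSE)
      }))
      dup <- duplicated(eng[, c("sample", "chrom", "pos")])
      if (any(dup)) {
        stop("planted effect variants collide at ",
             eng$chrom[dup][1], ":", eng$pos[dup][1], call. = FALSE)
      }
    }

    n_bg <- n_shared + sum(n_private)
    bg <- sample_background_variants(genome, models, n_bg, indel_fraction)
    info <- simulate_info_fields(n_bg, fail_fraction)
    bg <- cbind(bg, info)

    shared <- bg[seq_len(n_shared), , drop = FALSE]
    offset <- n_shared
    priv <- list()
    for (s in mutants) {
      k <- n_private[[s]]
      priv[[s]] <- bg[offset + seq_len(k), , drop = FALSE]
      offset <- offset + k
    }

    mk_set <- function(df, sample) {
      vs <- variant_set(df[, c("chrom", "pos", "ref", "alt", "QD", "FS",
                               "SOR", "MQRankSum", "ReadPosRankSum")],
                        sample = sample, genome_id = "synthetic")
      normalize_variants(vs, genome)
    }
    pass_info <- function(n) simulate_info_fields(n, 0)

    sets <- list()
    sets[[wt_sample]] <- mk_set(shared, wt_sample)
    truth_private <- list()
    truth_genes <- list()
    truth_failing <- list()
    for (s in mutants) {
      rows <- rbind(shared[, c("chrom", "pos", "ref", "alt", "QD", "FS",
                               "SOR", "MQRankSum", "ReadPosRankSum")],
                    priv[[s]][, c("chrom", "pos", "ref", "alt", "QD", "FS",
                                  "SOR", "MQRankSum", "ReadPosRankSum")])
      eng_s <- if (!is.null(eng)) eng[eng$sample == s, , drop = FALSE] else NULL
      if (!is.null(eng_s) && nrow(eng_s)) {
        rows <- rbind(rows, cbind(eng_s[, c("chrom", "pos", "ref", "alt")],
                                  pass_info(nrow(eng_s))[, 1:5]))
      }
      sets[[s]] <- mk_set(rows, s)
      priv_pass <- priv[[s]][priv[[s]]$passes, , drop = FALSE]
      priv_keys <- c(
        variant_keys(normalize_variants(
          variant_set(priv_pass, sample = s, genome_id = "synthetic"), genome)),
        if (!is.null(eng_s) && nrow(eng_s)) {
          variant_keys(normalize_variants(
            variant_set(cbind(eng_s[, c("chrom", "pos", "ref", "alt")],
                              pass_info(nrow(eng_s))[, 1:5]),
                        sample = s, genome_id = "synthetic"), genome))
        })
      truth_private[[s]] <- sort(priv_keys)
      truth_failing[[s]] <- sort(variant_keys(normalize_variants(
        variant_set(priv[[s]][!priv[[s]]$passes, , drop = FALSE],
                    sample = s, genome_id = "synthetic"), genome)))
      if (!is.null(eng_s) && nrow(eng_s)) {
        truth_genes[[s]] <- stats::setNames(eng_s$category, eng_s$gene)
      } else {
        truth_genes[[s]] <- stats::setNames(character(0), character(0))
      }
    }

    list(variants = sets,
         truth = list(planted_private_variants = truth_private,
                      planted_large_effect_genes = truth_genes,
                      planted_failing_variants = truth_failing,
                      wt_sample = wt_sample, seed = seed))
  })
}

# Uniform background variants outside transcript spans (3 bp margin from
# ends, >= 10 bp apart so deletions never collide).
sample_background_variants <- function(genome, models, n, indel_fraction) {
  lens <- chrom_lengths(genome)
  safe <- lapply(names(lens), function(chrom) {
    spans <- do.call(rbind, lapply(models, function(m) {
      if (m$chrom != chrom) return(NULL)
      c(m$tx_start, m$tx_end)
    }))
    complement_intervals(spans, lens[[chrom]], margin = 5L)
  })
  names(safe) <- names(lens)
  all_iv <- do.call(rbind, lapply(names(safe), function(chrom) {
    iv <- safe[[chrom]]
    if (is.null(iv)) return(NULL)
    data.frame(chrom = chrom, start = iv[, 1], end = iv[, 2])
  }))
  widths <- all_iv$end - all_iv$start + 1L
  total <- sum(widths)
  if (total < n * 12L) stop("not enough intergenic space to place ", n,
                            " background variants", call. = FALSE)
  cum <- cumsum(widths)
  offsets <- c(0L, cum)
  pos <- integer(0); chrom <- character(0)
  while (length(pos) < n) {
    draw <- sort(sample.int(total, min(4L * n, total)))
    iv_idx <- findInterval(draw - 1L, cum) + 1L
    p <- all_iv$start[iv_idx] + (draw - offsets[iv_idx]) - 1L
    cand <- data.frame(chrom = all_iv$chrom[iv_idx], pos = p)
    cand <- cand[order(cand$chrom, cand$pos), ]
    keep <- c(TRUE, diff(cand$pos) >= 10L | cand$chrom[-1] != cand$chrom[-nrow(cand)])
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    take <- utils::head(cand, n)
    pos <- take$pos; chrom <- take$chrom
  }
  is_indel <- stats::runif(n) < indel_fraction
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    b <- get_seq(genome, chrom[i], pos[i], pos[i])
    if (!is_indel[i]) {
      ref[i] <- b
      alt[i] <- sample(setdiff(DNA_BASES, b), 1L)
    } else if (stats::runif(1) < 0.5) {  # insertion
      ins <- random_dna(sample(1:3, 1L))
      # left-align stability: last inserted base must differ from the anchor
      if (substr(ins, nchar(ins), nchar(ins)) == b) {
        substr(ins, nchar(ins), nchar(ins)) <- sample(setdiff(DNA_BASES, b), 1L)
      }
      ref[i] <- b
      alt[i] <- paste0(b, ins)
    } else {  # deletion of 1-3 bp
      L <- sample(1:3, 1L)
      ref[i] <- get_seq(genome, chrom[i], pos[i], pos[i] + L)
      alt[i] <- b
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

complement_intervals <- function(spans, chrom_len, margin = 5L) {
  lo <- 1L + margin
  hi <- chrom_len - margin
  if (is.null(spans)) return(ivmat(lo, hi))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  out <- NULL
  cur <- lo
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, 1] - margin; e <- spans[i, 2] + margin
    if (s > cur) out <- rbind(out, c(cur, s - 1L))
    cur <- max(cur, e + 1L)
  }
  if (cur <= hi) out <- rbind(out, c(cur, hi))
  out
}

# Engineer one variant inside `model` guaranteed to produce `category`.
engineer_effect_variant <- function(model, category, genome) {
  cache <- model_cache(model, genome)
  fail <- function(what) {
    stop("gene ", model$gene_id, " lacks the feature needed for a ",
         category, " variant (", what, ")", call. = FALSE)
  }
  gpos_snp <- function(idx, alt_tx) {
    # substitution at CDS index `idx` (translation order), alt on tx strand
    p <- cache$cds_pos[idx]
    list(chrom = model$chrom, pos = p,
         ref = get_seq(genome, model$chrom, p, p),
         alt = if (model$strand == "-") comp_base(alt_tx) else alt_tx)
  }
  snp_at <- function(chrom, p) {
    b <- get_seq(genome, chrom, p, p)
    list(chrom = chrom, pos = p, ref = b,
         alt = sample(setdiff(DNA_BASES, b), 1L))
  }
  n_codons <- nchar(cache$cds_seq) %/% 3L
  codon_at <- function(k) substr(cache$cds_seq, 3L * k - 2L, 3L * k)

  if (category %in% c("splice_donor", "splice_acceptor")) {
    intr <- cache$introns
    if (is.null(intr)) fail("no intron")
    i <- sample.int(nrow(intr), 1L)
    s <- intr[i, "start"]; e <- intr[i, "end"]
    donor_left <- model$strand == "+"
    want_left <- (category == "splice_donor") == donor_left
    p <- if (want_left) s else e
    return(snp_at(model$chrom, p))
  }
  if (category == "start_lost") {
    return(gpos_snp(1L, sample(c("C", "G", "T"), 1L)))  # A of ATG
  }
  if (category == "stop_lost") {
    stop_codon <- codon_at(n_codons)
    for (w in 1:3) for (b in setdiff(DNA_BASES, substr(stop_codon, w, w))) {
      cand <- stop_codon
      substr(cand, w, w) <- b
      if (!(cand %in% STOP_CODONS)) {
        return(gpos_snp(3L * (n_codons - 1L) + w, b))
      }
    }
    fail("no disrupting substitution")
  }
  if (category %in% c("stop_gained", "missense", "synonymous")) {
    for (k in sample(2:(n_codons - 1L))) {
      codon <- codon_at(k)
      for (w in 1:3) for (b in setdiff(DNA_BASES, substr(codon, w, w))) {
        cand <- codon
        substr(cand, w, w) <- b
        ok <- switch(category,
          stop_gained = cand %in% STOP_CODONS,
          missense = !(cand %in% STOP_CODONS) &&
            translate_codon(cand) != translate_codon(codon),
          synonymous = !(cand %in% STOP_CODONS) &&
            translate_codon(cand) == translate_codon(codon))
        if (ok) return(gpos_snp(3L * (k - 1L) + w, b))
      }
    }
    fail("no suitable codon")
  }
  if (category == "frameshift") {
    # classic single-base insertion: ref "C" -> alt "CA" where a C is
    # available in the CDS interior; insertion is left-align-stable because
    # the inserted base differs from the anchor.
    interior <- cache$cds_pos[-c(1:3, (length(cache$cds_pos) - 2L):length(cache$cds_pos))]
    interior <- sort(interior)
    # keep away from CDS segment edges so the anchored change stays in CDS
    interior <- interior[vapply(interior, function(p) {
      iv_contains(model$cds, p) && iv_contains(model$cds, p + 1L)
    }, logical(1))]
    if (!length(interior)) fail("CDS too short")
    bases <- vapply(interior, function(p) get_seq(genome, model$chrom, p, p),
                    character(1))
    cs <- interior[bases == "C"]
    if (length(cs)) {
      p <- if (length(cs) > 1L) sample(cs, 1L) else cs
      return(list(chrom = model$chrom, pos = p, ref = "C", alt = "CA"))
    }
    p <- if (length(interior) > 1L) sample(interior, 1L) else interior
    b <- get_seq(genome, model$chrom, p, p)
    ins <- setdiff(DNA_BASES, b)[1]
    return(list(chrom = model$chrom, pos = p, ref = b, alt = paste0(b, ins)))
  }
  stop("unsupported category '", category, "'", call. = FALSE)
}

#' Write planted truth to JSON
#'
#' @param truth Truth list from [plant_variants()] (optionally augmented
#'   with deletion/DE truth by the callers that plant those).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
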