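#' Shared, concordant differentially expressed genes
#'
#' `shared_up = up1 ∩ up2`, `shared_down = down1 ∩ down2`; genes up in one
#' mutant and down in the other are discordant and never shared.
#'
#' @param de1,de2 Lists with `up` and `down` gene-id vectors (from
#'   [call_degs()]).
#' @return List with `shared_up`, `shared_down`, `discordant`.
#' @export
shared_degs <- function(de1, de2) {
  list(shared_up = sort(intersect(de1$up, de2$up)),
       shared_down = sort(intersect(de1$down, de2$down)),
       discordant = sort(union(intersect(de1$up, de2$down),
                               intersect(de1$down, de2$up))))
}

#' Candidate-gene report
#'
#' Intersects the shared, concordant DEGs with the genes carrying shared
#' large-effect variants in both mutants; each candidate is reported with
#' its variant evidence (position, alleles, consequence) and, when DE
#' tables are supplied, its per-mutant log2 fold changes. Deterministic
#' ordering by (chromosome, position).
#'
#' @param shared_deg Output of [shared_degs()].
#' @param shared_effect_genes Character vector of genes in both mutants'
#'   large-effect sets.
#' @param effects Optional combined effect table ([annotate_effects()]
#'   rows for the shared variants) used to attach variant evidence; a
#'   candidate gene absent from it is dropped with a warning.
#' @param de_tables Optional named list of per-mutant [nb_test()] results
#'   for log2FC evidence columns.
#' @param categories Consequence categories that qualify a variant as
#'   evidence (for candidate integration this includes `missense` by
#'   default, so amino-acid changes count as gene-product mutations).
#' @return data.frame with `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `direction`, and `log2FC_<mutant>` columns.
#' @export
candidate_genes <- function(shared_deg, shared_effect_genes,
                            effects = NULL, de_tables = NULL,
                            categories = c(LARGE_EFFECT_DEFAULT, "missense")) {
  deg_genes <- c(shared_deg$shared_up, shared_deg$shared_down)
  cand <- intersect(deg_genes, unique(shared_effect_genes))
  direction <- ifelse(cand %in% shared_deg$shared_up, "up", "down")
  out <- data.frame(gene = cand, direction = direction,
                    stringsAsFactors = FALSE)
  if (!is.null(effects)) {
    ev <- effects[!is.na(effects$gene_id) &
                    effects$gene_id %in% cand &
                    effects$consequence %in% categories, , drop = FALSE]
    missing <- setdiff(cand, ev$gene_id)
    if (length(missing)) {
      warning("candidate gene(s) without annotated variant evidence ",
              "dropped: ", paste(missing, collapse = ", "), call. = FALSE)
      out <- out[!out$gene %in% missing, , drop = FALSE]
    }
    sev <- match(ev$consequence, CONSEQUENCE_LEVELS)
    ev <- ev[order(ev$gene_id, sev), , drop = FALSE]
    ev <- ev[!duplicated(ev$gene_id), , drop = FALSE]  # most severe per gene
    m <- match(out$gene, ev$gene_id)
    out$chrom <- ev$chrom[m]
    out$pos <- ev$pos[m]
    out$ref <- ev$ref[m]
    out$alt <- ev$alt[m]
    out$consequence <- ev$consequence[m]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  } else {
    out <- out[order(out$gene), , drop = FALSE]
  }
  if (!is.null(de_tables)) {
    for (nm in names(de_tables)) {
      tab <- de_tables[[nm]]
      out[[paste0("log2FC_", nm)]] <- tab$log2FC[match(out$gene, tab$gene)]
    }
  }
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt_s = Ct_target(s) - Ct_reference(s)`; `ddCt_s = dCt_s -
#' dCt_calibrator`; `fold = 2^-ddCt`. The calibrator sample has fold 1 by
#' construction.
#'
#' @param ct_target,ct_reference Named numeric vectors of Ct values over
#'   the same samples (reference = internal control gene, e.g. actin).
#' @param calibrator Name of the calibrator sample.
#' @return data.frame with `sample`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(ct_target, ct_reference, calibrator) {
  samples <- names(ct_target)
  if (is.null(samples) || !all(samples %in% names(ct_reference))) {
    stop("ct_target and ct_reference must be named over the same samples",
         call. = FALSE)
  }
  if (!calibrator %in% samples) {
    stop("calibrator sample '", calibrator, "' missing", call. = FALSE)
  }
  if (anyNA(ct_target[samples]) || anyNA(ct_reference[samples])) {
    stop("missing Ct value", call. = FALSE)
  }
  dct <- ct_target[samples] - ct_reference[samples]
  ddct <- dct - dct[[calibrator]]
  data.frame(sample = samples, delta_ct = unname(dct),
             delta_delta_ct = unname(ddct), fold = unname(2^(-ddct)),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank ties; the two-sided p-value is exact — by
#' enumeration of all assignments of the observed (tied) ranks — when
#' `n1 + n2 <= exact_max`, and a tie-corrected normal approximation with
#' continuity correction otherwise. Two-sided probability is
#' `P(|U* - n1*n2/2| >= |U - n1*n2/2|)`.
#'
#' @param x,y Numeric samples, each nonempty.
#' @param exact_max Largest combined size for exact enumeration.
#' @return List with `U` (for `x`), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("empty input sample", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_from_ranks <- function(rx, nx, ny) sum(rx) - nx * (nx + 1) / 2
  U <- u_from_ranks(r[seq_len(n1)], n1, n2)
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    combos <- utils::combn(N, n1)
    us <- apply(combos, 2L, function(ix) u_from_ranks(r[ix], n1, n2))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(U = U, p = p, method = "normal")
}
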