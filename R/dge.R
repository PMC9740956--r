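#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with
#' nonzero counts in every sample) of the ratio of its count to the
#' gene's geometric mean across samples — the normalization DESeq2
#' defines.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    stop("no gene has nonzero counts in all samples; size factors are ",
         "undefined", call. = FALSE)
  }
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(counts))
}

#' FPKM and expression categories
#'
#' `FPKM = count * 1e9 / (gene_length * library_size)`. Genes with
#' FPKM < 0.1 in every sample are flagged `removed`; the remaining genes
#' get a per-sample abundance category by the bounds very high (>= 50),
#' high (10 <= FPKM < 50), moderate (2 <= FPKM < 10) and low
#' (0.1 <= FPKM < 2); a per-sample FPKM below 0.1 is `not_detected` there.
#'
#' @param counts Integer matrix, genes x samples.
#' @param lengths Named gene lengths in bp.
#' @param lib_sizes Library sizes; default column sums.
#' @return List with matrix `fpkm`, character matrix `category`, logical
#'   vector `removed`, and data.frame `category_freq` (per-sample fractions
#'   over detected genes).
#' @export
fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  lens <- lengths[rownames(counts)]
  stopifnot(all(lens > 0))
  f <- counts * 1e9 / outer(as.numeric(lens), as.numeric(lib_sizes))
  dimnames(f) <- dimnames(counts)
  removed <- apply(f < 0.1, 1L, all)
  category <- matrix(cut(f, breaks = c(-Inf, 0.1, 2, 10, 50, Inf),
                         labels = c("not_detected", "low", "moderate",
                                    "high", "very_high"),
                         right = FALSE),
                     nrow = nrow(f), dimnames = dimnames(f))
  category[removed, ] <- "removed"
  detected <- category %in% c("low", "moderate", "high", "very_high")
  freq <- apply(category, 2L, function(col) {
    d <- col[col %in% c("low", "moderate", "high", "very_high")]
    prop.table(table(factor(d, levels = c("low", "moderate", "high",
                                          "very_high"))))
  })
  list(fpkm = f, category = category, removed = removed,
       category_freq = as.data.frame(freq))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted_(i) = min_{j >= i} min(1, p_(j) * m / j)` over the sorted
#' p-values; monotone in the raw p-values. `NA`s are passed through and do
#' not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  if (!length(idx)) return(out)
  pv <- p[idx]
  stopifnot(all(pv >= 0 & pv <= 1))
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[idx[o]] <- adj
  out
}

#' Negative-binomial likelihood-ratio differential expression test
#'
#' For one mutant-vs-wild-type contrast: counts are normalized by
#' median-of-ratios size factors; a gene-wise dispersion is estimated by
#' method of moments on normalized counts pooled within conditions
#' (floored at 1e-8); the full model fits one NB mean per condition and
#' the reduced model a common mean (size factors as offsets, shared
#' dispersion), and the p-value comes from the likelihood-ratio statistic
#' against chi-square with 1 df, BH-adjusted across tested genes.
#' `log2FC = log2((mean_mut + c) / (mean_wt + c))` on normalized counts
#' with pseudo-mean `c = 0.5 / median(size factor)`. All-zero genes are
#' not tested and reported `ns`.
#'
#' @param cm A `count_matrix` (see [simulate_counts()]), or an integer
#'   matrix (then `conditions` must be a vector over its columns).
#' @param contrast Length-2 character vector `c(mutant, reference)`.
#' @param conditions Condition label per column when `cm` is a bare matrix.
#' @param alpha FDR threshold used for the `direction` call.
#' @param min_fpkm_universe Optional logical vector (genes to test), e.g.
#'   the complement of `fpkm()$removed`; untested genes are reported `ns`.
#' @return data.frame with `gene`, `baseMean`, `log2FC`, `p`, `fdr`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
nb_test <- function(cm, contrast, conditions = NULL, alpha = 0.05,
                    min_fpkm_universe = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    conditions <- cm$samples$condition
  } else {
    counts <- cm
    stopifnot(!is.null(conditions))
  }
  stopifnot(length(contrast) == 2, all(contrast %in% conditions))
  sel <- conditions %in% contrast
  counts <- counts[, sel, drop = FALSE]
  cond <- conditions[sel]
  grp_mut <- cond == contrast[1]
  grp_wt <- cond == contrast[2]
  if (sum(grp_mut) < 2 || sum(grp_wt) < 2) {
    stop("need >= 2 replicates per condition", call. = FALSE)
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  base_mean <- rowMeans(norm)
  pseudo <- 0.5 / stats::median(sf)
  m_mut <- rowMeans(norm[, grp_mut, drop = FALSE])
  m_wt <- rowMeans(norm[, grp_wt, drop = FALSE])
  log2fc <- log2((m_mut + pseudo) / (m_wt + pseudo))

  testable <- rowSums(counts) > 0
  if (!is.null(min_fpkm_universe)) {
    testable <- testable & min_fpkm_universe[rownames(counts)]
  }
  disp <- mom_dispersion(norm, grp_mut, grp_wt)
  p <- rep(NA_real_, nrow(counts))
  if (any(testable)) {
    p[testable] <- nb_lrt(counts[testable, , drop = FALSE], sf,
                          grp_mut, grp_wt, disp[testable])
  }
  fdr <- bh_adjust(p)
  direction <- rep("ns", nrow(counts))
  direction[!is.na(fdr) & fdr < alpha & log2fc >= 1] <- "up"
  direction[!is.na(fdr) & fdr < alpha & log2fc <= -1] <- "down"
  data.frame(gene = rownames(counts) %||% paste0("g", seq_len(nrow(counts))),
             baseMean = base_mean,
             log2FC = log2fc, p = p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Gene-wise method-of-moments dispersion pooled within conditions.
mom_dispersion <- function(norm, grp_mut, grp_wt, floor = 1e-8) {
  v_pool <- function(grp) {
    x <- norm[, grp, drop = FALSE]
    list(m = rowMeans(x), v = apply(x, 1L, stats::var), df = sum(grp) - 1L)
  }
  a <- v_pool(grp_mut); b <- v_pool(grp_wt)
  v <- (a$v * a$df + b$v * b$df) / (a$df + b$df)
  m <- (a$m + b$m) / 2
  disp <- (v - m) / m^2
  disp[!is.finite(disp)] <- floor
  pmax(disp, floor)
}

# Vectorized NB LRT with size-factor offsets and per-gene fixed dispersion.
nb_lrt <- function(counts, sf, grp_mut, grp_wt, disp) {
  size <- 1 / disp
  fit_mu <- function(cols) {
    x <- counts[, cols, drop = FALSE]
    s <- sf[cols]
    q <- pmax(rowSums(x) / sum(s), 1e-10)  # Poisson MLE start
    for (it in 1:8) {                       # Fisher scoring on log q
      mu <- outer(q, s)
      w <- size / (size + mu)
      score <- rowSums((x - mu) * w)
      info <- rowSums(mu * w)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      q <- q * exp(step)
    }
    q
  }
  ll <- function(q_list) {
    tot <- 0
    for (g in seq_along(q_list$groups)) {
      cols <- q_list$groups[[g]]
      mu <- outer(q_list$q[[g]], sf[cols])
      tot <- tot + rowSums(stats::dnbinom(counts[, cols, drop = FALSE],
                                          size = size, mu = mu, log = TRUE))
    }
    tot
  }
  all_cols <- grp_mut | grp_wt
  q_full <- list(groups = list(which(grp_mut), which(grp_wt)),
                 q = list(fit_mu(grp_mut), fit_mu(grp_wt)))
  q_red <- list(groups = list(which(all_cols)), q = list(fit_mu(all_cols)))
  stat <- pmax(0, 2 * (ll(q_full) - ll(q_red)))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Call differentially expressed genes
#'
#' `up`: FDR < `alpha` and linear fold change >= `fc_min`; `down`:
#' FDR < `alpha` and fold change <= `1/fc_min` (both thresholds strict on
#' FDR, matching "FDR < 0.05 and |FC| >= 2").
#'
#' @param results data.frame from [nb_test()].
#' @param alpha FDR threshold.
#' @param fc_min Minimum linear fold change.
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(results, alpha = 0.05, fc_min = 2) {
  fc <- 2^results$log2FC
  sig <- !is.na(results$fdr) & results$fdr < alpha
  list(up = results$gene[sig & fc >= fc_min],
       down = results$gene[sig & fc <= 1 / fc_min])
}
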