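#' Windowed variant density
#'
#' Counts variants per fixed-width genomic window (window `w` covers
#' positions `[w*W+1, (w+1)*W]`), SNPs and indels tallied separately.
#' Totals over windows conserve the set size.
#'
#' @param vs A [variant_set()].
#' @param chrom_lens Named chromosome lengths.
#' @param window Window size in bp (default 5 Mb).
#' @return data.frame with `chrom`, `start`, `end`, `n_snp`, `n_indel`,
#'   `n_total`.
#' @export
variant_density <- function(vs, chrom_lens, window = 5e6) {
  stopifnot(window > 0)
  window <- as.integer(window)
  rows <- lapply(names(chrom_lens), function(chrom) {
    starts <- seq.int(1L, chrom_lens[[chrom]], by = window)
    ends <- pmin(starts + window - 1L, chrom_lens[[chrom]])
    sub <- vs[vs$chrom == chrom, , drop = FALSE]
    wi <- (sub$pos - 1L) %/% window + 1L
    n_snp <- tabulate(wi[sub$vclass == "SNP"], nbins = length(starts))
    n_indel <- tabulate(wi[sub$vclass == "INDEL"], nbins = length(starts))
    data.frame(chrom = chrom, start = starts, end = ends,
               n_snp = n_snp, n_indel = n_indel,
               n_total = n_snp + n_indel)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log10 depth-of-coverage ratio between mutant and wild type
#'
#' Per window, `log10((mut + eps) / (wt + eps))` on identical window
#' grids, optionally followed by a centered moving average over `smooth_k`
#' windows within each chromosome. A track divided by itself is exactly 0
#' everywhere.
#'
#' @param mut,wt `coverage_track`s on the same grid.
#' @param pseudocount Additive pseudocount `eps` keeping the log finite on
#'   zero-depth windows. Default: 0.1 x mean wild-type depth.
#' @param smooth_k Moving-average width in windows; 1 = no smoothing.
#' @return data.frame with `chrom`, `start`, `end`, `ratio`, `smoothed`.
#' @export
depth_ratio <- function(mut, wt, pseudocount = NULL, smooth_k = 1L) {
  if (nrow(mut) != nrow(wt) ||
      !all(mut$chrom == wt$chrom & mut$start == wt$start & mut$end == wt$end)) {
    stop("mutant and wild-type tracks are on different window grids",
         call. = FALSE)
  }
  eps <- pseudocount %||% (0.1 * mean(wt$depth))
  out <- data.frame(chrom = wt$chrom, start = wt$start, end = wt$end)
  out$ratio <- log10((mut$depth + eps) / (wt$depth + eps))
  out$smoothed <- stats::ave(out$ratio, out$chrom,
                             FUN = function(x) moving_average(x, smooth_k))
  out
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Flag candidate structural-variant windows
#'
#' Maximal runs of at least `min_run` consecutive windows whose smoothed
#' log10 depth ratio is beyond `threshold` (at or below a negative
#' threshold for deletions; at or above a positive one for duplications),
#' merged into intervals.
#'
#' @param ratios Output of [depth_ratio()].
#' @param threshold Ratio threshold; negative screens for deletions.
#' @param min_run Minimum run length, windows.
#' @return data.frame with `chrom`, `start`, `end`, `n_windows`,
#'   `mean_ratio` (possibly zero rows).
#' @export
flag_sv_windows <- function(ratios, threshold = -0.8, min_run = 5L) {
  hit <- if (threshold < 0) ratios$smoothed <= threshold
         else ratios$smoothed >= threshold
  out <- list()
  for (chrom in unique(ratios$chrom)) {
    sel <- ratios$chrom == chrom
    h <- hit[sel]
    if (!any(h)) next
    r <- rle(h)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_run)
    sub <- ratios[sel, , drop = FALSE]
    for (k in runs) {
      i1 <- starts_i[k]; i2 <- ends_i[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = sub$start[i1], end = sub$end[i2],
        n_windows = i2 - i1 + 1L,
        mean_ratio = mean(sub$smoothed[i1:i2]))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_ratio = numeric()))
  }
  do.call(rbind, out)
}
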