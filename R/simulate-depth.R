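#' Simulate a windowed depth-of-coverage track
#'
#' Per-window mean depths are drawn as multiplicative gamma noise around
#' `mean_depth` (coefficient of variation `noise_cv`; exact `mean_depth`
#' when `noise_cv = 0`). Windows overlapped by a planted deletion are
#' scaled toward its copy ratio in proportion to the overlap fraction, so a
#' fully covered window sits at `mean_depth * copy_ratio` exactly when
#' noise is off.
#'
#' @param genome Named [Biostrings::DNAStringSet], or a named numeric
#'   vector of chromosome lengths (only lengths are used).
#' @param mean_depth Mean depth, > 0.
#' @param window Window size, bp; must not exceed the shortest chromosome.
#' @param deletions `NULL` or data.frame with `chrom`, `start`, `end`
#'   (1-based closed) and `copy_ratio` (0 = homozygous, 0.5 = heterozygous
#'   deletion). Intervals must lie within chromosome bounds and must not
#'   overlap.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional seed.
#' @param sample Sample label.
#' @return A `coverage_track`: data.frame with `chrom`, `start`, `end`
#'   (1-based closed, last window may be short) and `depth`; window size
#'   and sample label stored as attributes.
#' @export
simulate_depth <- function(genome, mean_depth, window, deletions = NULL,
                           noise_cv = 0, seed = NULL, sample = "sample") {
  stopifnot(mean_depth > 0, window >= 1)
  lens <- if (is.numeric(genome)) genome else chrom_lengths(genome)
  if (window > min(lens)) {
    stop("window (", window, " bp) larger than the shortest chromosome (",
         min(lens), " bp)", call. = FALSE)
  }
  if (!is.null(deletions) && nrow(deletions)) {
    bad <- deletions$start < 1 | deletions$end > lens[deletions$chrom]
    if (any(bad)) stop("deletion interval outside chromosome bounds",
                       call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(names(lens), function(chrom) {
      starts <- as.integer(seq.int(1L, lens[[chrom]], by = window))
      ends <- as.integer(pmin(starts + window - 1L, lens[[chrom]]))
      data.frame(chrom = chrom, start = starts, end = ends)
    })
    track <- do.call(rbind, rows)
    n <- nrow(track)
    depth <- rep(mean_depth, n)
    if (noise_cv > 0) {
      shape <- 1 / noise_cv^2
      depth <- depth * stats::rgamma(n, shape = shape, rate = shape)
    }
    if (!is.null(deletions) && nrow(deletions)) {
      for (i in seq_len(nrow(deletions))) {
        d <- deletions[i, ]
        sel <- track$chrom == d$chrom & track$end >= d$start & track$start <= d$end
        ov <- pmin(track$end[sel], d$end) - pmax(track$start[sel], d$start) + 1L
        frac <- ov / (track$end[sel] - track$start[sel] + 1L)
        depth[sel] <- depth[sel] * (1 - frac * (1 - d$copy_ratio))
      }
    }
    track$depth <- depth
    structure(track, window = as.integer(window), sample = sample,
              class = c("coverage_track", "data.frame"))
  })
}

#' Write a coverage track as BedGraph
#'
#' @param track A `coverage_track` (from [simulate_depth()] or
#'   [read_bedgraph()]).
#' @param path Output path (BedGraph, 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start, track$end),
                               score = track$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BedGraph depth track
#'
#' @param path BedGraph file path.
#' @param sample Sample label.
#' @return A `coverage_track` data.frame (`chrom`, `start`, `end`, `depth`;
#'   1-based closed coordinates).
#' @export
read_bedgraph <- function(path, sample = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      depth = gr$score)
  w <- if (nrow(track)) as.integer(max(track$end - track$start + 1L)) else NA_integer_
  structure(track, window = w,
            sample = sample %||% sub("\\..*$", "", basename(path)),
            class = c("coverage_track", "data.frame"))
}
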