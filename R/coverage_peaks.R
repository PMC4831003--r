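# Extended-read pileups, enriched-region masks, and locally normalized
# H3K27ac peak heights.

#' Coverage track constructor
#'
#' Per-base coverage over `[start, start + length(values))` on one
#' chromosome (0-based half-open).
#'
#' @param chrom chromosome name.
#' @param start 0-based start coordinate of the first value.
#' @param values non-negative per-base coverage.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(chrom, start, values) {
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(chrom = chrom, start = as.integer(start),
                 values = as.numeric(values)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$chrom, "[", x$start, ",",
      x$start + length(x$values), ") mean", signif(mean(x$values), 4), "\n")
  invisible(x)
}

#' Extend mapped reads from their 5' ends
#'
#' ChIP-seq fragments were size-selected around 150 bp, so each mapped read
#' is extended to `length` bp from its 5' end: a plus-strand read
#' `[s, e)` becomes `[s, s + length)`, a minus-strand read becomes
#' `[e - length, e)`. Intervals are clipped to chromosome bounds when
#' lengths are supplied.
#'
#' @param reads data.frame with columns chrom, start, end, strand.
#' @param length extension length in bp (> 0).
#' @param chrom_lengths optional named vector of chromosome lengths used for
#'   clipping.
#' @return data.frame with columns chrom, start, end.
#' @export
extend_reads <- function(reads, length = 150L, chrom_lengths = NULL) {
  if (length <= 0) stop("extension length must be > 0")
  s <- ifelse(reads$strand == "+", reads$start, reads$end - length)
  e <- s + length
  s <- pmax(s, 0L)
  if (!is.null(chrom_lengths)) {
    e <- pmin(e, unname(chrom_lengths[reads$chrom]))
  }
  data.frame(chrom = reads$chrom, start = as.integer(s), end = as.integer(e),
             stringsAsFactors = FALSE)
}

#' Pile up intervals over a region
#'
#' @param intervals data.frame with columns chrom, start, end (0-based
#'   half-open), already on the region's chromosome.
#' @param region list with `chrom`, `start`, `end`.
#' @return A [coverage_track()] with `values[b]` = number of intervals
#'   covering base `b`.
#' @export
pileup <- function(intervals, region) {
  len <- region$end - region$start
  delta <- numeric(len + 1L)
  if (nrow(intervals)) {
    iv <- intervals[intervals$chrom == region$chrom, , drop = FALSE]
    s <- pmax(iv$start, region$start) - region$start
    e <- pmin(iv$end, region$end) - region$start
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    for (i in seq_along(s)) {
      delta[s[i] + 1L] <- delta[s[i] + 1L] + 1
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
    }
  }
  coverage_track(region$chrom, region$start, cumsum(delta)[seq_len(len)])
}

#' Enriched-region mask
#'
#' A base belongs to an H3K27ac-enriched region when at least `min_reads`
#' (extended) reads map to it.
#'
#' @param track a [coverage_track()].
#' @param min_reads detection threshold in reads per base (default 5).
#' @return Logical vector, one element per base.
#' @export
enriched_mask <- function(track, min_reads = 5) {
  track$values >= min_reads
}

#' Locally normalized peak heights
#'
#' Within enriched regions the peak height at base `i` is the coverage at
#' `i` divided by the local maximum coverage in the adjacent 2-kbp
#' neighbourhood (`[i - w/2, i + w/2]`, clipped at track ends), so heights
#' lie in (0, 1] and equal 1 at each local maximum. Non-enriched bases get
#' height 0.
#'
#' @param track a [coverage_track()].
#' @param mask logical enriched mask (default [enriched_mask()] of `track`).
#' @param neighborhood neighbourhood width in bp; even, > 0 (default 2000).
#' @return A `peak_height_profile`: list with chrom, start, `h` (per-base
#'   heights) and `enriched` (the mask).
#' @export
peak_height <- function(track, mask = enriched_mask(track),
                        neighborhood = 2000L) {
  if (neighborhood <= 0 || neighborhood %% 2 != 0) {
    stop("neighborhood must be a positive even number of bases")
  }
  half <- as.integer(neighborhood / 2)
  locmax <- .sliding_max_cpp(track$values, half)
  stopifnot(all(locmax[mask] > 0))  # enriched implies coverage >= min_reads
  h <- numeric(length(track$values))
  h[mask] <- track$values[mask] / locmax[mask]
  structure(list(chrom = track$chrom, start = track$start, h = h,
                 enriched = mask),
            class = "peak_height_profile")
}

#' @export
print.peak_height_profile <- function(x, ...) {
  cat("peak_height_profile:", x$chrom, "[", x$start, ",",
      x$start + length(x$h), ");", sum(x$enriched), "enriched bases\n")
  invisible(x)
}

#' Peak-height features in 200-bp windows around the TSS
#'
#' Mean per-base peak height in `K = span / width` non-overlapping windows
#' oriented with the gene — the feature matrix of the logistic expression
#' model. The default spans the central 2,000 bp of the TSS window
#' (K = 10); `span = 1000` restricts to the central kilobase (K = 5).
#'
#' @param profiles a `peak_height_profile` or named per-chromosome list.
#' @param windows a `tss_windows` object.
#' @param span total span in bp centred on the TSS (multiple of `width`).
#' @param width feature window width in bp (default 200).
#' @return genes x K matrix of mean heights in `[0, 1]`.
#' @export
peak_height_features <- function(profiles, windows, span = 2000L,
                                 width = 200L) {
  if (span %% width != 0L) stop("span must be a multiple of width")
  if (inherits(profiles, "peak_height_profile")) {
    profiles <- setNames(list(profiles), profiles$chrom)
  }
  tracks <- lapply(profiles, function(p) coverage_track(p$chrom, p$start, p$h))
  window_enrichment(tracks, windows, span = span, width = width,
                    step = width) / width
}

#' Per-segment peak heights for TSS windows
#'
#' Reduces per-base heights to one value per 6-bp segment, oriented with the
#' gene (for minus-strand windows the segment order is reversed to match the
#' window's 5'->3' segment order). The default reduction is the mean of the
#' six per-base heights; `"max"` is available as an alternative.
#'
#' @param profiles a `peak_height_profile` or a named list of them (one per
#'   chromosome, each covering its windows).
#' @param windows a `tss_windows` object.
#' @param reduce `"mean"` or `"max"`.
#' @return Numeric matrix, genes x segments, values in `[0, 1]`.
#' @export
segment_heights <- function(profiles, windows, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  if (inherits(profiles, "peak_height_profile")) {
    profiles <- setNames(list(profiles), profiles$chrom)
  }
  g <- windows$genes
  n_seg <- ncol(windows$segments)
  out <- matrix(0, nrow = nrow(g), ncol = n_seg,
                dimnames = list(g$gene_id, NULL))
  red <- if (reduce == "mean") colMeans else function(m) apply(m, 2L, max)
  for (i in seq_len(nrow(g))) {
    p <- profiles[[g$chrom[i]]]
    if (is.null(p)) stop("no peak-height profile for chromosome ", g$chrom[i])
    lo <- g$start[i] - p$start
    hi <- g$end[i] - p$start
    if (lo < 0 || hi > length(p$h)) {
      stop("profile does not cover window for gene ", g$gene_id[i])
    }
    hv <- p$h[(lo + 1L):hi]
    m <- red(matrix(hv, nrow = KMER_K))
    if (windows$oriented && g$strand[i] == "-") m <- rev(m)
    out[i, ] <- m
  }
  out
}
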