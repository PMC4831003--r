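# Probability-weighted 6-mer counting and peak/dip emission spectra.
#
# The peak height of a segment is treated as the probability that the
# segment lies in an H3K27ac peak, so a segment with height h contributes h
# to the peak counts of its 6-mer; dip counts come from segments outside
# enriched regions (default) or additionally from the residual 1 - h mass.

#' Weighted 6-mer counts from TSS windows
#'
#' Each segment with 6-mer `s` and peak height `h` adds `h` to
#' `peak_counts[s]`. Dip counting depends on `dip_source`:
#' `"non_enriched_only"` (default) adds `1 - h` only for segments outside
#' enriched regions (where `h` is 0, i.e. weight 1);
#' `"residual_everywhere"` adds `1 - h` for every segment. Segments
#' containing `N` contribute nothing.
#'
#' @param windows a `tss_windows` object.
#' @param heights genes x segments matrix of heights in `[0, 1]` (see
#'   [segment_heights()]).
#' @param dip_source where the dip-state mass comes from (see above).
#' @param enriched optional logical matrix marking segments inside enriched
#'   regions; defaults to `heights > 0`.
#' @return List with `peak_counts` and `dip_counts`, numeric vectors of
#'   length 4096 named by 6-mer.
#' @export
count_weighted_kmers <- function(windows, heights,
                                 dip_source = c("non_enriched_only",
                                                "residual_everywhere"),
                                 enriched = NULL) {
  dip_source <- match.arg(dip_source)
  if (!all(dim(heights) == dim(windows$segments))) {
    stop("heights matrix does not match windows (", nrow(windows$segments),
         " x ", ncol(windows$segments), " expected)")
  }
  if (any(heights < 0 | heights > 1)) stop("heights must lie in [0, 1]")
  if (is.null(enriched)) enriched <- heights > 0
  idx <- kmer_index(as.vector(windows$segments))
  h <- as.vector(heights)
  keep <- !is.na(idx)  # N-containing segments contribute nothing
  idx <- idx[keep]
  h <- h[keep]
  enr <- as.vector(enriched)[keep]
  pc <- numeric(N_KMERS)
  tab <- rowsum(h, idx)
  pc[as.integer(rownames(tab))] <- tab[, 1L]
  dw <- if (dip_source == "residual_everywhere") 1 - h else (1 - h) * !enr
  dc <- numeric(N_KMERS)
  tab <- rowsum(dw, idx)
  dc[as.integer(rownames(tab))] <- tab[, 1L]
  list(peak_counts = setNames(pc, all_kmers()),
       dip_counts = setNames(dc, all_kmers()))
}

#' Estimate peak/dip emission spectra
#'
#' Normalizes weighted counts into the emission distributions of the peak
#' (M) and dip (d) states, with a Laplace pseudocount so that every 6-mer
#' has positive probability. Normalizing peak frequencies by the dip
#' frequencies of the same TSS neighbourhoods adjusts for the high GC
#' content of gene-rich regions.
#'
#' @param peak_counts,dip_counts length-4096 non-negative vectors (see
#'   [count_weighted_kmers()]).
#' @param pseudocount added to every cell before normalization (default 1).
#' @return A `kmer_spectrum` object: list with `p_peak`, `p_dip` (named
#'   probability vectors summing to 1), `pseudocount`, `n_peak`, `n_dip`
#'   (total weighted counts).
#' @export
estimate_spectrum <- function(peak_counts, dip_counts, pseudocount = 1) {
  stopifnot(length(peak_counts) == N_KMERS, length(dip_counts) == N_KMERS)
  if (any(peak_counts < 0) || any(dip_counts < 0)) stop("counts must be >= 0")
  if (pseudocount == 0 && (sum(peak_counts) == 0 || sum(dip_counts) == 0)) {
    stop("all-zero counts with pseudocount 0: spectrum undefined")
  }
  pp <- peak_counts + pseudocount
  pd <- dip_counts + pseudocount
  out <- list(
    p_peak = setNames(pp / sum(pp), all_kmers()),
    p_dip = setNames(pd / sum(pd), all_kmers()),
    pseudocount = pseudocount,
    n_peak = sum(peak_counts),
    n_dip = sum(dip_counts)
  )
  stopifnot(abs(sum(out$p_peak) - 1) < 1e-9, abs(sum(out$p_dip) - 1) < 1e-9)
  class(out) <- "kmer_spectrum"
  out
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: 4096 6-mers; weighted counts",
      signif(x$n_peak, 4), "(peak) /", signif(x$n_dip, 4), "(dip);",
      "pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Rank 6-mers by peak/dip enrichment
#'
#' @param spectrum a [estimate_spectrum()] result.
#' @param top_n number of 6-mers to report (clipped at 4096).
#' @return data.frame (kmer, p_peak, p_dip, ratio) in descending ratio
#'   order, ties broken lexicographically.
#' @export
enrichment_report <- function(spectrum, top_n = 20L) {
  top_n <- min(as.integer(top_n), N_KMERS)
  ratio <- spectrum$p_peak / spectrum$p_dip
  km <- all_kmers()
  ord <- order(-ratio, km)
  df <- data.frame(kmer = km[ord], p_peak = unname(spectrum$p_peak[ord]),
                   p_dip = unname(spectrum$p_dip[ord]),
                   ratio = unname(ratio[ord]), stringsAsFactors = FALSE)
  head(df, top_n)
}

#' Write / read a spectrum as TSV
#'
#' @param spectrum a `kmer_spectrum`.
#' @param path TSV path.
#' @return `path` (write) or a `kmer_spectrum` (read).
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(kmer = all_kmers(), p_peak = unname(spectrum$p_peak),
                   p_dip = unname(spectrum$p_dip))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(identical(df$kmer, all_kmers()))
  out <- list(p_peak = setNames(df$p_peak, df$kmer),
              p_dip = setNames(df$p_dip, df$kmer),
              pseudocount = NA_real_, n_peak = NA_real_, n_dip = NA_real_)
  class(out) <- "kmer_spectrum"
  out
}
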