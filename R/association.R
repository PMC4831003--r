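# Factor-by-position association screens: MIC and Pearson correlation of
# per-position factor enrichment against mRNA levels, and the pairwise
# position-position correlation map.

# coverage sum over a genomic half-open interval, via the track's prefix sums
track_prefix <- function(track) c(0, cumsum(track$values))

region_sum <- function(track, start, end, prefix = track_prefix(track)) {
  lo <- start - track$start
  hi <- end - track$start
  if (lo < 0 || hi > length(track$values)) {
    stop("interval [", start, ", ", end, ") outside track bounds")
  }
  prefix[hi + 1L] - prefix[lo + 1L]
}

as_track_list <- function(tracks) {
  if (inherits(tracks, "coverage_track")) {
    tracks <- setNames(list(tracks), tracks$chrom)
  }
  tracks
}

#' Per-position factor enrichment around TSSs
#'
#' Sums coverage in sliding windows (default 200 bp wide, 100 bp step,
#' spanning 2,200 bp around the TSS, giving 21 positions) oriented with the
#' gene: position 1 is the most upstream window, the central position
#' straddles the TSS.
#'
#' @param tracks a [coverage_track()] or named list of them (per
#'   chromosome).
#' @param windows a `tss_windows` object (supplies TSS and strand).
#' @param span total grid span in bp (even; default 2200).
#' @param width window width in bp (default 200).
#' @param step window step in bp (default 100).
#' @return genes x positions numeric matrix; column names are the oriented
#'   offsets of each window's upstream edge relative to the TSS.
#' @export
window_enrichment <- function(tracks, windows, span = 2200L, width = 200L,
                              step = 100L) {
  if (width > span) stop("grid width exceeds its span")
  if (step <= 0L || width <= 0L) stop("width and step must be positive")
  tracks <- as_track_list(tracks)
  half <- span %/% 2L
  offsets <- seq.int(-half, half - width, by = step)
  g <- windows$genes
  out <- matrix(0, nrow(g), length(offsets),
                dimnames = list(g$gene_id, offsets))
  prefixes <- lapply(tracks, track_prefix)
  for (i in seq_len(nrow(g))) {
    tr <- tracks[[g$chrom[i]]]
    if (is.null(tr)) stop("no track for chromosome ", g$chrom[i])
    pre <- prefixes[[g$chrom[i]]]
    for (j in seq_along(offsets)) {
      u0 <- offsets[j]
      if (g$strand[i] == "+" || !windows$oriented) {
        s <- g$tss[i] + u0
        e <- s + width
      } else {
        e <- g$tss[i] - u0 + 1L
        s <- e - width
      }
      out[i, j] <- region_sum(tr, s, e, pre)
    }
  }
  out
}

#' Maximal information coefficient (MINE-style approximation)
#'
#' Approximate MIC via grid search over axis partitions with at most
#' `B(n) = n^alpha` cells; on each grid shape one axis is equipartitioned
#' and the other optimized by dynamic programming over clumps (capped at
#' `c` times the column count). Captures non-linear as well as linear
#' dependence; 0 for independence, 1 for noiseless functional
#' relationships.
#'
#' @param x,y paired numeric vectors, n >= 20.
#' @param alpha grid-size exponent (default 0.6).
#' @param c clump cap factor (default 15).
#' @return MIC value in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 20L) stop("mic needs at least 20 paired finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: MIC set to 0 by convention")
    return(0)
  }
  .mic_cpp(as.numeric(x), as.numeric(y), alpha, as.integer(c))
}

#' Permutation null quantile for an association statistic
#'
#' @param x,y paired numeric vectors.
#' @param stat function of (x, y) returning a scalar (e.g. [mic()] or
#'   absolute Pearson correlation).
#' @param n_perm number of permutations.
#' @param probs quantiles of the null to report.
#' @return Named numeric vector of null quantiles.
#' @export
permutation_null <- function(x, y, stat, n_perm = 200L, probs = 0.95) {
  null <- vapply(seq_len(n_perm), function(i) stat(x, sample(y)), 0)
  quantile(null, probs)
}

#' Factor-by-position association screen
#'
#' For every factor track and every grid position around the TSS, computes
#' the MIC and the Pearson correlation between per-gene enrichment and the
#' expression level, and ranks (factor, position) cells by MIC.
#'
#' @param factor_tracks named list of factors; each element is a
#'   [coverage_track()] or per-chromosome list of them.
#' @param windows a `tss_windows` object.
#' @param expression an [expression_table()]; genes are matched by id and
#'   genes missing from either side are dropped (count reported via
#'   message).
#' @param span,width,step grid geometry (see [window_enrichment()]).
#' @param mic_alpha,mic_c MIC parameters.
#' @return An `association_matrix`: list with `mic`, `pcc`, `pcc_p`
#'   (factors x positions matrices), `ranked` (data.frame sorted by
#'   descending MIC), and `n_genes`.
#' @export
association_screen <- function(factor_tracks, windows, expression,
                               span = 2200L, width = 200L, step = 100L,
                               mic_alpha = 0.6, mic_c = 15L) {
  if (length(factor_tracks) < 2L) stop("need at least 2 factor tracks")
  ids <- intersect(windows$genes$gene_id, expression$gene_id)
  dropped <- length(union(windows$genes$gene_id, expression$gene_id)) -
    length(ids)
  if (dropped > 0L) message(dropped, " gene(s) without both window and ",
                            "expression entries dropped")
  keep <- windows$genes$gene_id %in% ids
  w <- windows
  w$genes <- w$genes[keep, , drop = FALSE]
  w$segments <- w$segments[keep, , drop = FALSE]
  yv <- setNames(expression$log_level, expression$gene_id)[w$genes$gene_id]
  enr <- lapply(factor_tracks, window_enrichment, windows = w, span = span,
                width = width, step = step)
  n_pos <- ncol(enr[[1L]])
  factors <- names(factor_tracks)
  micm <- pccm <- pccp <- matrix(NA_real_, length(factors), n_pos,
                                 dimnames = list(factors,
                                                 colnames(enr[[1L]])))
  for (f in seq_along(factors)) {
    for (j in seq_len(n_pos)) {
      xv <- enr[[f]][, j]
      micm[f, j] <- if (sd(xv) == 0) 0 else mic(xv, yv, mic_alpha, mic_c)
      if (sd(xv) > 0) {
        ct <- cor.test(xv, yv)
        pccm[f, j] <- unname(ct$estimate)
        pccp[f, j] <- ct$p.value
      }
    }
  }
  ranked <- data.frame(
    factor = rep(factors, n_pos),
    position = rep(colnames(micm), each = length(factors)),
    mic = as.vector(micm), pcc = as.vector(pccm),
    stringsAsFactors = FALSE
  )
  ranked <- ranked[order(-ranked$mic), ]
  rownames(ranked) <- NULL
  structure(list(mic = micm, pcc = pccm, pcc_p = pccp, ranked = ranked,
                 n_genes = length(yv)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("association_matrix:", nrow(x$mic), "factors x", ncol(x$mic),
      "positions over", x$n_genes, "genes; top cell:",
      x$ranked$factor[1], "@", x$ranked$position[1],
      "(MIC", signif(x$ranked$mic[1], 3), ")\n")
  invisible(x)
}

#' Pairwise position-position correlation map
#'
#' @param track_windows genes x positions enrichment matrix (see
#'   [window_enrichment()]).
#' @return Symmetric Pearson correlation matrix with unit diagonal;
#'   zero-variance positions give NA cells (flagged with a warning).
#' @export
position_correlation_map <- function(track_windows) {
  m <- as.matrix(track_windows)
  if (nrow(m) < 3L) stop("need at least 3 genes")
  zv <- apply(m, 2L, sd) == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance position(s): correlations undefined")
  }
  cc <- suppressWarnings(cor(m))
  diag(cc)[!zv] <- 1
  cc
}
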