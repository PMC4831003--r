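# Comparison of two cell types: common vs cell-type-specific loci from
# signatures or peak heights, rank-sum specificity tests, and expression
# fold-change summaries.

#' Classify loci from two cell types' signature probabilities
#'
#' A locus is `common` when the posterior peak probability exceeds `hi` in
#' both cell types, `typeA_specific` when it exceeds `hi` in A but falls
#' below `lo` in B (symmetric for B), and `unclassified` otherwise
#' (intermediate loci that the thresholds do not resolve).
#'
#' @param gamma_a,gamma_b numeric vectors in `[0, 1]`, aligned loci.
#' @param hi upper threshold (default 0.5).
#' @param lo lower threshold (default 0.1).
#' @return Character vector in `{"common", "typeA_specific",
#'   "typeB_specific", "unclassified"}`.
#' @export
classify_signature <- function(gamma_a, gamma_b, hi = 0.5, lo = 0.1) {
  if (hi <= lo) stop("hi must exceed lo")
  if (length(gamma_a) != length(gamma_b)) stop("misaligned loci")
  if (any(gamma_a < 0 | gamma_a > 1 | gamma_b < 0 | gamma_b > 1)) {
    stop("signature probabilities must lie in [0, 1]")
  }
  out <- rep("unclassified", length(gamma_a))
  out[gamma_a > hi & gamma_b > hi] <- "common"
  out[gamma_a > hi & gamma_b < lo] <- "typeA_specific"
  out[gamma_b > hi & gamma_a < lo] <- "typeB_specific"
  out
}

#' Classify loci from two cell types' normalized peak heights
#'
#' Same three-way logic as [classify_signature()] applied to ChIP-derived
#' peak heights. Loci must be aligned (equal length; matching names when
#' both are named).
#'
#' @param heights_a,heights_b numeric vectors in `[0, 1]`.
#' @param hi,lo thresholds (defaults as for signatures).
#' @return Character classification vector.
#' @export
classify_peaks <- function(heights_a, heights_b, hi = 0.5, lo = 0.1) {
  if (!is.null(names(heights_a)) && !is.null(names(heights_b)) &&
      !identical(names(heights_a), names(heights_b))) {
    stop("misaligned loci: names differ")
  }
  classify_signature(heights_a, heights_b, hi = hi, lo = lo)
}

#' Rank-sum specificity tests between locus classes
#'
#' Tests whether signature levels differ between every pair of classes
#' (e.g. that cell-A-specific peak loci carry higher cell-A signatures than
#' cell-B-specific peak loci). Classes with fewer than 2 loci are skipped
#' with a warning.
#'
#' @param levels numeric signature levels per locus.
#' @param classes classification per locus (see [classify_peaks()]).
#' @return data.frame with class_1, class_2, W, p_value, n_1, n_2.
#' @export
specificity_test <- function(levels, classes) {
  stopifnot(length(levels) == length(classes))
  cls <- unique(classes)
  sizes <- table(classes)[cls]
  small <- cls[sizes < 2L]
  if (length(small)) {
    warning("class(es) with < 2 loci skipped: ", paste(small, collapse = ", "))
    cls <- setdiff(cls, small)
  }
  if (length(cls) < 2L) stop("need at least 2 classes with >= 2 loci")
  pairs <- utils::combn(cls, 2L)
  out <- data.frame(class_1 = pairs[1L, ], class_2 = pairs[2L, ],
                    W = NA_real_, p_value = NA_real_,
                    n_1 = NA_integer_, n_2 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- levels[classes == pairs[1L, i]]
    b <- levels[classes == pairs[2L, i]]
    rs <- rank_sum_test(a, b)
    out$W[i] <- rs$W
    out$p_value[i] <- rs$p_value
    out$n_1[i] <- rs$n_x
    out$n_2[i] <- rs$n_y
  }
  out
}

#' Per-class expression fold-change summary
#'
#' Log2 fold changes `log2((fpkm_a + 1) / (fpkm_b + 1))` (the +1 offsets
#' match the log2(FPKM + 1) expression scale) summarized per gene class.
#'
#' @param expression_a,expression_b [expression_table()]s for cell types A
#'   and B (matched by gene_id).
#' @param gene_classes named character vector (names = gene ids) of classes
#'   (see [classify_signature()]).
#' @return List with `fold_changes` (named vector) and `summary`
#'   (data.frame with class, n, q25, median, q75).
#' @export
foldchange_summary <- function(expression_a, expression_b, gene_classes) {
  ids <- names(gene_classes)
  fa <- setNames(expression_a$fpkm, expression_a$gene_id)[ids]
  fb <- setNames(expression_b$fpkm, expression_b$gene_id)[ids]
  if (anyNA(fa) || anyNA(fb)) stop("expression missing for classified genes")
  lfc <- log2((fa + 1) / (fb + 1))
  cls <- sort(unique(gene_classes))
  summ <- data.frame(
    class = cls,
    n = as.integer(table(gene_classes)[cls]),
    q25 = NA_real_, median = NA_real_, q75 = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(cls)) {
    v <- lfc[gene_classes == cls[i]]
    q <- quantile(v, c(0.25, 0.5, 0.75))
    summ$q25[i] <- q[1L]; summ$median[i] <- q[2L]; summ$q75[i] <- q[3L]
  }
  list(fold_changes = lfc, summary = summ)
}
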