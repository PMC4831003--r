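# Seeded synthetic-data generator: plants a known two-state (peak/dip)
# Markov structure over 6-bp segments in TSS windows, draws window DNA from
# state-conditional 6-mer distributions, Poisson coverage conditioned on
# state for two cell types sharing a subset of peak runs, and expression
# coupled to the TSS-proximal peak arrangement through a logistic-scale
# link. Every stage of the analysis pipeline is testable against the
# returned ground truth without any external download.

#' Generator configuration
#'
#' Defaults define the generator's study conditions: 2,600 genes (a tenth
#' of the 26,000 the full-scale analysis uses), 2,004-bp windows of 334
#' segments, cooperative peak persistence `A[M->M] = 0.95` /
#' `A[d->d] = 0.98` (mean peak runs of ~120 bp at a ~29% marginal peak
#' frequency), peak coverage rate 20 reads/bp vs background 1 read/bp, a
#' dense log-ratio emission field of sd `tau = 1.2` plus `delta = 2`
#' boosts on 50 driver 6-mers per cell-type-specific set and 50 shared
#' ones, half of peak runs shared between the two cell types, and
#' expression noise sd 1 on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param n_chroms chromosomes the genes are spread over.
#' @param a_mm,a_dd true transition self-probabilities (peak persistence /
#'   dip persistence).
#' @param tau sd of the dense per-6-mer log-ratio field of each peak
#'   emission distribution relative to the dip distribution.
#' @param delta additional log-ratio boost on driver 6-mers.
#' @param n_drivers driver 6-mers per cell-type-specific set.
#' @param n_shared_drivers driver 6-mers boosted in peaks of both cell
#'   types.
#' @param lambda_m,lambda_d Poisson coverage rates (reads per base) in peak
#'   and dip states; `lambda_m > lambda_d` required.
#' @param shared_fraction probability that a cell-A peak run is reused by
#'   cell B.
#' @param expr_intercept,expr_slope,expr_sd expression link: the log2 level
#'   is `max(0, intercept + slope * proximal_score + N(0, sd))` where
#'   `proximal_score` is the weighted mean of the peak states in the 400 bp
#'   around the TSS (the downstream 200 bp weighted double).
#' @param gap background bp between consecutive windows.
#' @param seed mandatory integer seed; all randomness flows from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genes = 2600L, n_chroms = 10L,
                             a_mm = 0.95, a_dd = 0.98,
                             tau = 1.2, delta = 2,
                             n_drivers = 50L, n_shared_drivers = 50L,
                             lambda_m = 20, lambda_d = 1,
                             shared_fraction = 0.5,
                             expr_intercept = -1, expr_slope = 7,
                             expr_sd = 1,
                             gap = 1996L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (lambda_d >= lambda_m) {
    stop("lambda_d >= lambda_m: peak and dip coverage are unidentifiable")
  }
  stopifnot(a_mm > 0, a_mm < 1, a_dd > 0, a_dd < 1,
            shared_fraction >= 0, shared_fraction <= 1)
  cfg <- list(n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
              a_mm = a_mm, a_dd = a_dd, tau = tau, delta = delta,
              n_drivers = as.integer(n_drivers),
              n_shared_drivers = as.integer(n_shared_drivers),
              lambda_m = lambda_m, lambda_d = lambda_d,
              shared_fraction = shared_fraction,
              expr_intercept = expr_intercept, expr_slope = expr_slope,
              expr_sd = expr_sd, gap = as.integer(gap),
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# normalized emission distribution: dip base composition perturbed by a
# dense log-ratio field (sd tau) plus a delta boost on driver k-mers
perturb_spectrum <- function(p_dip, tau, delta, drivers) {
  lr <- rnorm(N_KMERS, sd = tau)
  lr[drivers] <- lr[drivers] + delta
  p <- p_dip * exp(lr)
  p / sum(p)
}

sample_markov_paths <- function(n, T_, a_mm, a_dd) {
  pi_m <- (1 - a_dd) / ((1 - a_mm) + (1 - a_dd))  # stationary
  s <- matrix(FALSE, n, T_)
  s[, 1L] <- runif(n) < pi_m
  u <- matrix(runif(n * (T_ - 1L)), n, T_ - 1L)
  for (t in 2:T_) {
    p_stay <- ifelse(s[, t - 1L], a_mm, 1 - a_dd)
    s[, t] <- u[, t - 1L] < p_stay
  }
  s
}

# second cell type: keep each cell-A peak run with prob shared_fraction,
# and add B-specific runs from an independent Markov path (thinned the same
# way so both cell types have comparable peak frequency)
derive_second_celltype <- function(states_a, cfg) {
  n <- nrow(states_a); T_ <- ncol(states_a)
  own <- sample_markov_paths(n, T_, cfg$a_mm, cfg$a_dd)
  states_b <- matrix(FALSE, n, T_)
  keep_run <- function(s, p_keep) {
    out <- logical(length(s))
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] && runif(1) < p_keep) {
        out[starts[i]:ends[i]] <- TRUE
      }
    }
    out
  }
  for (g in seq_len(n)) {
    shared <- keep_run(states_a[g, ], cfg$shared_fraction)
    specific <- keep_run(own[g, ], 1 - cfg$shared_fraction)
    states_b[g, ] <- shared | specific
  }
  states_b
}

expression_from_states <- function(states, cfg) {
  T_ <- ncol(states)
  mid <- T_ %/% 2L  # TSS sits between segments mid and mid + 1
  w <- numeric(T_)
  w[max(1L, mid - 33L):mid] <- 1        # upstream 200 bp
  w[(mid + 1L):min(T_, mid + 34L)] <- 2 # downstream 200 bp, most heavily
  score <- as.vector(states %*% w) / sum(w)
  eta <- cfg$expr_intercept + cfg$expr_slope * score
  log_level <- pmax(0, eta + rnorm(nrow(states), sd = cfg$expr_sd))
  2^log_level - 1  # FPKM
}

#' Generate a synthetic dataset
#'
#' Draws hidden peak/dip state paths from the true Markov chain, window DNA
#' from state-conditional 6-mer distributions (cell-A-specific peaks boost
#' the A driver set, B-specific peaks the B set, shared peaks the shared
#' set), per-base Poisson coverage tracks per cell type, and FPKM tables
#' coupled to the TSS-proximal peak arrangement. Byte-identical outputs for
#' identical configs (one seed drives everything).
#'
#' @param config a [generator_config()].
#' @return A `synthetic_dataset` list: `genome` (named sequences), `genes`
#'   (gene records), `windows` (`tss_windows`), `coverage` (per cell type,
#'   named list of [coverage_track()] per chromosome), `expression` (per
#'   cell type [expression_table()]), and `truth` (state matrices, segment
#'   classes, emission distributions, driver sets, config).
#' @export
generate_dataset <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  T_ <- SEGMENTS_PER_WINDOW
  n <- cfg$n_genes

  # emission distributions
  p_dip <- exp(rnorm(N_KMERS, sd = 0.3))
  p_dip <- p_dip / sum(p_dip)
  drv <- sample.int(N_KMERS, cfg$n_drivers * 2L + cfg$n_shared_drivers)
  drivers_a <- drv[seq_len(cfg$n_drivers)]
  drivers_b <- drv[cfg$n_drivers + seq_len(cfg$n_drivers)]
  drivers_shared <- drv[2L * cfg$n_drivers + seq_len(cfg$n_shared_drivers)]
  p_peak_a <- perturb_spectrum(p_dip, cfg$tau, cfg$delta, drivers_a)
  p_peak_b <- perturb_spectrum(p_dip, cfg$tau, cfg$delta, drivers_b)
  p_common <- perturb_spectrum(p_dip, cfg$tau, cfg$delta, drivers_shared)

  # hidden states
  states_a <- sample_markov_paths(n, T_, cfg$a_mm, cfg$a_dd)
  states_b <- derive_second_celltype(states_a, cfg)
  seg_class <- matrix("dip", n, T_)
  seg_class[states_a & states_b] <- "common"
  seg_class[states_a & !states_b] <- "a_only"
  seg_class[!states_a & states_b] <- "b_only"

  # window sequences (oriented 5'->3' with the gene)
  km <- all_kmers()
  idx <- matrix(0L, n, T_)
  for (cl in c("dip", "common", "a_only", "b_only")) {
    p <- switch(cl, dip = p_dip, common = p_common,
                a_only = p_peak_a, b_only = p_peak_b)
    sel <- seg_class == cl
    idx[sel] <- sample.int(N_KMERS, sum(sel), replace = TRUE, prob = p)
  }
  seg_str <- matrix(km[idx], n, T_)
  win_seq <- apply(seg_str, 1L, paste0, collapse = "")

  # genome layout: equal spacing, oriented windows placed on random strands
  spacing <- WINDOW_LENGTH + cfg$gap
  per_chrom <- ceiling(n / cfg$n_chroms)
  chrom_of <- rep(seq_len(cfg$n_chroms), each = per_chrom)[seq_len(n)]
  slot <- sequence(tabulate(chrom_of, cfg$n_chroms))
  w_start <- 2000L + (slot - 1L) * spacing
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", w_start + 1002L, w_start + 1001L)
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_len <- setNames(integer(cfg$n_chroms), chrom_names)
  for (cc in seq_len(cfg$n_chroms)) {
    k <- sum(chrom_of == cc)
    chrom_len[cc] <- if (k) 2000L + (k - 1L) * spacing + WINDOW_LENGTH + 2000L
                     else 4000L
  }
  base_marg <- dip_base_marginal(p_dip)
  genome <- character(cfg$n_chroms)
  names(genome) <- chrom_names
  fwd_seq <- win_seq
  neg <- strand == "-"
  fwd_seq[neg] <- revcomp(win_seq[neg])
  for (cc in seq_len(cfg$n_chroms)) {
    sel <- which(chrom_of == cc)
    pieces <- character(2L * length(sel) + 1L)
    pos <- 0L
    pi_ <- 1L
    for (g in sel) {
      flank_len <- w_start[g] - pos
      pieces[pi_] <- rand_bases(flank_len, base_marg)
      pieces[pi_ + 1L] <- fwd_seq[g]
      pos <- w_start[g] + WINDOW_LENGTH
      pi_ <- pi_ + 2L
    }
    pieces[pi_] <- rand_bases(chrom_len[cc] - pos, base_marg)
    genome[cc] <- paste0(pieces, collapse = "")
  }

  gene_id <- sprintf("g%04d", seq_len(n))
  body_start <- ifelse(strand == "+", tss, tss - 599L)
  genes <- data.frame(gene_id = gene_id, chrom = chrom_names[chrom_of],
                      tss = as.integer(tss), strand = strand,
                      start = as.integer(body_start),
                      end = as.integer(body_start + 600L),
                      stringsAsFactors = FALSE)

  # per-base Poisson coverage conditioned on state, per cell type
  coverage <- list()
  for (ct in c("A", "B")) {
    st <- if (ct == "A") states_a else states_b
    tracks <- list()
    for (cc in seq_len(cfg$n_chroms)) {
      rate <- rep(cfg$lambda_d, chrom_len[cc])
      for (g in which(chrom_of == cc)) {
        mseg <- which(st[g, ])
        if (!length(mseg)) next
        if (strand[g] == "+") {
          starts <- w_start[g] + (mseg - 1L) * KMER_K
        } else {
          starts <- w_start[g] + WINDOW_LENGTH - mseg * KMER_K
        }
        for (s0 in starts) rate[(s0 + 1L):(s0 + KMER_K)] <- cfg$lambda_m
      }
      tracks[[chrom_names[cc]]] <-
        coverage_track(chrom_names[cc], 0L, rpois(chrom_len[cc], rate))
    }
    coverage[[ct]] <- tracks
  }

  expression <- list(
    A = expression_table(gene_id, expression_from_states(states_a, cfg)),
    B = expression_table(gene_id, expression_from_states(states_b, cfg))
  )

  rownames(states_a) <- rownames(states_b) <- rownames(seg_class) <- gene_id
  rownames(seg_str) <- gene_id
  windows <- structure(
    list(genes = data.frame(genes[, c("gene_id", "chrom", "tss", "strand")],
                            start = w_start,
                            end = w_start + WINDOW_LENGTH,
                            stringsAsFactors = FALSE),
         segments = seg_str, half_width = 1002L, oriented = TRUE),
    class = "tss_windows")

  structure(list(
    genome = genome, genes = genes, windows = windows,
    coverage = coverage, expression = expression,
    truth = list(states_a = states_a, states_b = states_b,
                 seg_class = seg_class,
                 emissions = list(p_dip = setNames(p_dip, km),
                                  p_peak_a = setNames(p_peak_a, km),
                                  p_peak_b = setNames(p_peak_b, km),
                                  p_common = setNames(p_common, km)),
                 drivers = list(a = km[drivers_a], b = km[drivers_b],
                                shared = km[drivers_shared]),
                 config = cfg)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$genes), "genes on",
      length(x$genome), "chromosomes; 2 cell types\n")
  invisible(x)
}

# single-base marginal of a 6-mer distribution (position-averaged)
dip_base_marginal <- function(p) {
  km <- all_kmers()
  freq <- numeric(4L)
  names(freq) <- c("A", "C", "G", "T")
  m <- matrix(unlist(strsplit(km, "")), ncol = KMER_K, byrow = TRUE)
  for (b in names(freq)) freq[b] <- sum(p * rowSums(m == b)) / KMER_K
  freq / sum(freq)
}

rand_bases <- function(len, marg) {
  if (len <= 0L) return("")
  paste0(sample(names(marg), len, replace = TRUE, prob = marg),
         collapse = "")
}

#' Simulate mapped reads whose extended pileup matches target rates
#'
#' Emits 36-bp reads on random strands positioned so that after 150-bp
#' extension from the 5' end the expected pileup at each base equals the
#' supplied per-base rate. Used to exercise the read-extension/pileup path;
#' [generate_dataset()] itself emits coverage tracks directly.
#'
#' @param rate numeric per-base target coverage over `[0, length(rate))`.
#' @param chrom chromosome name.
#' @param read_length reported read length (default 36).
#' @param ext_length extension length the pileup is matched to (default
#'   150).
#' @return data.frame of reads (chrom, start, end, strand).
#' @export
simulate_reads <- function(rate, chrom = "chr1", read_length = 36L,
                           ext_length = 150L) {
  counts <- rpois(length(rate), rate / ext_length)
  s <- rep(seq_along(counts) - 1L, counts)  # extended-interval starts
  strand <- sample(c("+", "-"), length(s), replace = TRUE)
  start <- ifelse(strand == "+", s, s + ext_length - read_length)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_length), strand = strand,
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to standard formats
#'
#' FASTA genome, BED6 genes, bedGraph coverage and TSV expression per cell
#' type.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_regions(dataset$genes, file.path(dir, "genes.bed"))
  for (ct in names(dataset$coverage)) {
    path <- file.path(dir, sprintf("coverage_%s.bedgraph", ct))
    con <- file(path, "w")
    for (tr in dataset$coverage[[ct]]) {
      v <- tr$values
      r <- rle(v)
      e <- tr$start + cumsum(r$lengths)
      s <- e - r$lengths
      writeLines(sprintf("%s\t%d\t%d\t%g", tr$chrom, s, e, r$values), con)
    }
    close(con)
    write_expression(dataset$expression[[ct]],
                     file.path(dir, sprintf("expression_%s.tsv", ct)))
  }
  invisible(dir)
}

#' Read a bedGraph file into coverage tracks
#'
#' @param path bedGraph path.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return Named list of [coverage_track()]s (zero-filled outside recorded
#'   intervals).
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  out <- list()
  for (cc in names(chrom_lengths)) {
    v <- numeric(chrom_lengths[[cc]])
    sub <- df[df$chrom == cc, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    out[[cc]] <- coverage_track(cc, 0L, v)
  }
  out
}

#' Evaluate pipeline outputs against the ground truth
#'
#' Collects the recovery metrics for whichever pipeline outputs are
#' supplied: state-detection AUC of the posterior signatures, Pearson
#' correlation of estimated vs planted emission log-ratios, max absolute
#' transition-estimate error, validation metrics of predicted expression,
#' and classification recall of cell-type-specific loci.
#'
#' @param truth the `truth` component of a [generate_dataset()] result.
#' @param gamma genes x segments posterior matrix (rownames = gene ids).
#' @param spectrum a `kmer_spectrum` estimated for the cell type.
#' @param transitions result of [estimate_transitions()].
#' @param predicted_expression named numeric vector of predicted log
#'   levels.
#' @param measured_expression the matching [expression_table()].
#' @param locus_classes genes x segments matrix of locus classes (see
#'   [classify_peaks()]).
#' @param celltype `"A"` or `"B"`: which cell type the supplied outputs
#'   describe.
#' @return Named list of recovery metrics (only those computable from the
#'   supplied outputs).
#' @export
truth_eval <- function(truth, gamma = NULL, spectrum = NULL,
                       transitions = NULL, predicted_expression = NULL,
                       measured_expression = NULL, locus_classes = NULL,
                       celltype = "A") {
  states <- if (celltype == "A") truth$states_a else truth$states_b
  out <- list()
  if (!is.null(gamma)) {
    if (!identical(rownames(gamma), rownames(states))) {
      stop("gamma gene ids do not match ground truth")
    }
    out$state_auc <- auc(as.vector(gamma), as.vector(states))
  }
  if (!is.null(spectrum)) {
    out$spectrum_logratio_pearson <-
      cor(log(spectrum$p_peak / spectrum$p_dip),
          planted_logratio(truth, celltype))
  }
  if (!is.null(transitions)) {
    A_true <- matrix(c(truth$config$a_mm, 1 - truth$config$a_mm,
                       1 - truth$config$a_dd, truth$config$a_dd),
                     2L, 2L, byrow = TRUE)
    out$transition_max_error <- max(abs(transitions$A - A_true))
  }
  if (!is.null(predicted_expression)) {
    ids <- names(predicted_expression)
    me <- measured_expression
    if (is.null(me)) stop("measured_expression required with predictions")
    y <- setNames(me$log_level, me$gene_id)[ids]
    det <- setNames(me$detected, me$gene_id)[ids]
    if (anyNA(y)) stop("predicted gene ids do not match ground truth")
    out$expression_spearman <- cor(predicted_expression, y,
                                   method = "spearman")
    out$expression_auc <- auc(predicted_expression, det)
  }
  if (!is.null(locus_classes)) {
    if (!identical(rownames(locus_classes), rownames(truth$seg_class))) {
      stop("locus class gene ids do not match ground truth")
    }
    true_cls <- truth$seg_class
    spec_a <- true_cls == "a_only"
    spec_b <- true_cls == "b_only"
    hit <- sum(locus_classes[spec_a] == "typeA_specific") +
      sum(locus_classes[spec_b] == "typeB_specific")
    out$specific_locus_recall <- hit / (sum(spec_a) + sum(spec_b))
  }
  out
}

#' Planted emission log-ratio for a cell type
#'
#' The generator draws each segment's 6-mer from a class-conditional
#' distribution, so the planted peak-vs-dip log-ratio for one cell type is
#' the log ratio of the class-mixture distributions its own peak and dip
#' segments are actually drawn from (mixture weights = true segment-class
#' frequencies).
#'
#' @param truth ground truth from [generate_dataset()].
#' @param celltype `"A"` or `"B"`.
#' @return Named numeric vector of length 4096.
#' @export
planted_logratio <- function(truth, celltype = "A") {
  cls <- truth$seg_class
  em <- truth$emissions
  if (celltype == "A") {
    own <- "a_only"; other <- "b_only"
    p_own <- em$p_peak_a; p_other <- em$p_peak_b
  } else {
    own <- "b_only"; other <- "a_only"
    p_own <- em$p_peak_b; p_other <- em$p_peak_a
  }
  n_own <- sum(cls == own); n_common <- sum(cls == "common")
  n_other <- sum(cls == other); n_dip <- sum(cls == "dip")
  peak_mix <- (n_own * p_own + n_common * em$p_common) / (n_own + n_common)
  dip_mix <- (n_dip * em$p_dip + n_other * p_other) / (n_dip + n_other)
  log(peak_mix / dip_mix)
}
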