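# Independent oracles and small fixture builders used across the suite.

# Exhaustive path-enumeration posterior for a two-state HMM: P(state_i = M |
# observations), summing over all 2^T state paths. Independent of the
# forward-backward implementation.
brute_posterior <- function(pi, A, e) {
  T_ <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  probs <- apply(paths, 1L, function(st) {
    p <- pi[st[1L]] * e[1L, st[1L]]
    if (T_ > 1L) for (t in 2:T_) p <- p * A[st[t - 1L], st[t]] * e[t, st[t]]
    p
  })
  vapply(seq_len(T_),
         function(i) sum(probs[paths[, i] == 1L]) / sum(probs), 0)
}

random_spectrum <- function() {
  pp <- runif(4096)
  pd <- runif(4096)
  structure(list(p_peak = setNames(pp / sum(pp), all_kmers()),
                 p_dip = setNames(pd / sum(pd), all_kmers()),
                 pseudocount = 0, n_peak = 1, n_dip = 1),
            class = "kmer_spectrum")
}

random_hmm <- function(spectrum = random_spectrum()) {
  a <- runif(2L, 0.05, 0.95)
  A <- matrix(c(a[1L], 1 - a[1L], 1 - a[2L], a[2L]), 2L, 2L, byrow = TRUE)
  p <- runif(1L, 0.05, 0.95)
  hmm_model(c(p, 1 - p), A, spectrum)
}

random_segments <- function(T_) {
  all_kmers()[sample.int(4096L, T_, replace = TRUE)]
}

# minimal tss_windows object around a segment matrix
windows_from_segments <- function(segs) {
  n <- nrow(segs)
  structure(list(
    genes = data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                       chrom = "chr1", tss = seq_len(n) * 10000L,
                       strand = "+",
                       start = seq_len(n) * 10000L - 1002L,
                       end = seq_len(n) * 10000L + 1002L,
                       stringsAsFactors = FALSE),
    segments = `rownames<-`(segs, sprintf("g%03d", seq_len(n))),
    half_width = 1002L, oriented = TRUE), class = "tss_windows")
}

# brute-force sliding-window maximum, O(n * w)
brute_sliding_max <- function(v, half) {
  n <- length(v)
  vapply(seq_len(n),
         function(i) max(v[max(1L, i - half):min(n, i + half)]), 0)
}
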