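# 6-mer alphabet utilities shared by the spectrum and HMM modules.

KMER_K <- 6L
N_KMERS <- 4096L  # 4^6
SEGMENTS_PER_WINDOW <- 334L
WINDOW_LENGTH <- 2004L  # 334 * 6

#' Enumerate all 6-mers
#'
#' Returns the 4,096 DNA 6-mers over `{A,C,G,T}` in lexicographic order.
#' This fixed ordering defines the k-mer index used throughout the package
#' (emission vectors, spectra, counts).
#'
#' @return Character vector of length 4096.
#' @export
all_kmers <- function() {
  if (is.null(.kmer_cache$kmers)) {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; reverse for lexicographic
    .kmer_cache$kmers <- sort(do.call(paste0, g))
  }
  .kmer_cache$kmers
}

.kmer_cache <- new.env(parent = emptyenv())

#' Map 6-mer strings to indices
#'
#' @param kmers character vector of 6-base strings.
#' @return Integer vector of indices into [all_kmers()]; `NA` for any k-mer
#'   containing a base outside `{A,C,G,T}` (ambiguity codes collapse to N).
#' @export
kmer_index <- function(kmers) {
  match(kmers, all_kmers())
}

# Split length-2004 oriented window sequences into a n x 334 matrix of 6-mers.
tile_segments <- function(seqs) {
  n <- length(seqs)
  stopifnot(all(nchar(seqs) == WINDOW_LENGTH))
  starts <- seq.int(1L, WINDOW_LENGTH, by = KMER_K)
  m <- matrix("", nrow = n, ncol = SEGMENTS_PER_WINDOW)
  for (j in seq_along(starts)) {
    m[, j] <- substr(seqs, starts[j], starts[j] + KMER_K - 1L)
  }
  m
}

# Reverse complement preserving N, vectorized over character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
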