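# Reading the standard formats and resolving strand-oriented TSS windows.
#
# Coordinates are 0-based half-open internally (BED-native); GTF input is
# converted at the boundary.

#' Read a FASTA file
#'
#' Sequences are uppercased and every non-ACGT letter (IUPAC ambiguity codes
#' included) is collapsed to `N`.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(ss) == 0L)) {
    stop("empty FASTA record: ", names(ss)[Biostrings::width(ss) == 0L][1])
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGT]", "N", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of ACGTN sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene records from BED6 or GTF
#'
#' The TSS is the 5' end of the record in 0-based coordinates: `start` for
#' plus-strand genes and `end - 1` for minus-strand genes (after the 1-based
#' closed GTF interval is converted to 0-based half-open).
#'
#' @param path input file.
#' @param format `"bed"`, `"gtf"`, or `"auto"` (by file extension).
#' @return data.frame with columns gene_id, chrom, tss, strand, start, end.
#' @export
read_regions <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no records in ", path)
  fields <- strsplit(lines[idx], "\t")
  if (format == "bed") {
    bad <- which(vapply(fields, length, 0L) < 6L)
    if (length(bad)) {
      stop("malformed BED line ", idx[bad[1]], ": expected >= 6 tab-separated fields")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    name <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    bad <- which(is.na(start) | is.na(end) | !(strand %in% c("+", "-")))
    if (length(bad)) stop("malformed BED line ", idx[bad[1]])
  } else {
    bad <- which(vapply(fields, length, 0L) < 9L)
    if (length(bad)) {
      stop("malformed GTF line ", idx[bad[1]], ": expected 9 tab-separated fields")
    }
    feature <- vapply(fields, `[[`, "", 3L)
    if (any(feature == "gene")) {
      sel <- feature == "gene"
      fields <- fields[sel]
      idx <- idx[sel]
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, `[[`, "", 9L)
    name <- rep(NA_character_, length(attrs))
    m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
    has <- grepl('gene_id "', attrs)
    name[has] <- sub('gene_id "([^"]+)"', "\\1", m)
    bad <- which(is.na(start1) | is.na(end1) | !(strand %in% c("+", "-")) | is.na(name))
    if (length(bad)) stop("malformed GTF line ", idx[bad[1]])
    start <- start1 - 1L  # 1-based closed -> 0-based half-open
    end <- end1
  }
  tss <- ifelse(strand == "+", start, end - 1L)
  data.frame(
    gene_id = name, chrom = chrom, tss = as.integer(tss), strand = strand,
    start = as.integer(start), end = as.integer(end),
    stringsAsFactors = FALSE
  )
}

#' Write gene records to BED6
#'
#' @param genes data.frame as returned by [read_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                   0L, genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an expression table from FPKM values
#'
#' Derives `log_level = log2(fpkm + 1)` and the detection flag at the 1-FPKM
#' threshold: transcripts with FPKM between 0 and 1 count as not
#' significantly detected, so `detected` is strictly `fpkm > 1`.
#'
#' @param gene_id character vector.
#' @param fpkm non-negative numeric vector.
#' @return data.frame of class `expression_table` with columns gene_id,
#'   fpkm, log_level, detected.
#' @export
expression_table <- function(gene_id, fpkm) {
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  }
  if (any(fpkm < 0)) stop("negative FPKM values are not allowed")
  out <- data.frame(
    gene_id = as.character(gene_id), fpkm = as.numeric(fpkm),
    log_level = log2(fpkm + 1), detected = fpkm > 1,
    stringsAsFactors = FALSE
  )
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Read an expression TSV
#'
#' Expects a header line with `gene_id` followed by one or more numeric FPKM
#' columns; replicate columns are averaged.
#'
#' @param path TSV path.
#' @return An [expression_table()].
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs gene_id plus >= 1 FPKM column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric or missing FPKM values in ", path)
  expression_table(df[[1]], rowMeans(vals))
}

#' Write an expression table to TSV
#'
#' @param table an [expression_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  write.table(table[, c("gene_id", "fpkm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract strand-oriented TSS windows
#'
#' Each in-bounds gene yields a 2 x `half_width` bp window centred on its TSS
#' and tiled into non-overlapping 6-bp segments ordered 5'->3' relative to
#' the gene. With the default `half_width = 1002` the window is 2,004 bp and
#' tiles into exactly 334 segments, the TSS falling on the boundary between
#' segments 167 and 168. Plus-strand genes span `[tss - hw, tss + hw)`;
#' minus-strand genes span `[tss - hw + 1, tss + hw + 1)` and are
#' reverse-complemented (when `orient_minus` is TRUE) so that segment 1 is
#' the most upstream segment of the gene on either strand.
#'
#' @param genes data.frame of gene records (see [read_regions()]).
#' @param genome named character vector of chromosome sequences.
#' @param half_width half window width in bp; `2 * half_width` must be a
#'   multiple of 6.
#' @param orient_minus reverse-complement minus-strand windows (default TRUE).
#' @return A `tss_windows` object: list with `genes` (the retained records
#'   plus window start/end) and `segments` (gene x segment character matrix).
#' @export
extract_tss_windows <- function(genes, genome, half_width = 1002L,
                                orient_minus = TRUE) {
  half_width <- as.integer(half_width)
  width <- 2L * half_width
  if (width %% KMER_K != 0L) stop("2 * half_width must be a multiple of 6")
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  clen <- nchar(genome)[genes$chrom]
  w_start <- ifelse(genes$strand == "+", genes$tss - half_width,
                    genes$tss - half_width + 1L)
  w_end <- w_start + width
  ok <- w_start >= 0L & w_end <= clen
  if (any(!ok)) {
    warning(sum(!ok), " window(s) extend beyond chromosome bounds; skipped")
  }
  genes <- genes[ok, , drop = FALSE]
  w_start <- w_start[ok]
  w_end <- w_end[ok]
  seqs <- substr(genome[genes$chrom], w_start + 1L, w_end)
  if (orient_minus && any(genes$strand == "-")) {
    neg <- genes$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
  }
  segs <- tile_segments_general(seqs, width %/% KMER_K)
  rownames(segs) <- genes$gene_id
  out <- list(
    genes = data.frame(genes[, c("gene_id", "chrom", "tss", "strand")],
                       start = w_start, end = w_end,
                       stringsAsFactors = FALSE),
    segments = segs,
    half_width = half_width,
    oriented = orient_minus
  )
  class(out) <- "tss_windows"
  out
}

# tile_segments for arbitrary window widths (multiples of 6)
tile_segments_general <- function(seqs, n_seg) {
  starts <- seq.int(1L, by = KMER_K, length.out = n_seg)
  m <- matrix("", nrow = length(seqs), ncol = n_seg)
  for (j in seq_along(starts)) {
    m[, j] <- substr(seqs, starts[j], starts[j] + KMER_K - 1L)
  }
  m
}

#' @export
print.tss_windows <- function(x, ...) {
  cat("tss_windows:", nrow(x$segments), "windows x", ncol(x$segments),
      "segments (", 2L * x$half_width, "bp )\n")
  invisible(x)
}

#' Number of windows / segments
#' @param x a `tss_windows` object.
#' @export
n_windows <- function(x) nrow(x$segments)

# Oriented window sequence (concatenated segments); used by tests.
window_sequence <- function(x) {
  apply(x$segments, 1L, paste0, collapse = "")
}
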