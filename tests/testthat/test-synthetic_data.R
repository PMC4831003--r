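test_that("config validation catches unidentifiable settings", {
  expect_error(generator_config(seed = 1, lambda_m = 2, lambda_d = 5),
               "unidentifiable")
  expect_error(generator_config(), "seed")
})

test_that("the generator is deterministic per seed", {
  cfg <- generator_config(n_genes = 40L, n_chroms = 2L, seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$genome, d2$genome)
  expect_identical(d1$coverage$A$chr1$values, d2$coverage$A$chr1$values)
  expect_identical(d1$expression$B, d2$expression$B)
  d3 <- generate_dataset(generator_config(n_genes = 40L, n_chroms = 2L,
                                          seed = 34))
  expect_false(identical(d1$genome, d3$genome))
})

test_that("windows extracted from the written genome match the planted ones", {
  cfg <- generator_config(n_genes = 30L, n_chroms = 2L, seed = 35)
  ds <- generate_dataset(cfg)
  w <- extract_tss_windows(ds$genes, ds$genome)
  expect_identical(w$segments, ds$windows$segments)
  expect_identical(w$genes$start, ds$windows$genes$start)
})

test_that("datasets round-trip through the standard file formats", {
  cfg <- generator_config(n_genes = 12L, n_chroms = 1L, seed = 36)
  ds <- generate_dataset(cfg)
  dir <- tempfile("synth")
  write_dataset(ds, dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(genome, ds$genome)
  genes <- read_regions(file.path(dir, "genes.bed"))
  expect_identical(genes$tss, ds$genes$tss)
  expr <- read_expression(file.path(dir, "expression_A.tsv"))
  expect_equal(expr$fpkm, ds$expression$A$fpkm, tolerance = 1e-6)
  cov <- read_bedgraph(file.path(dir, "coverage_A.bedgraph"),
                       setNames(nchar(ds$genome), names(ds$genome)))
  expect_equal(cov$chr1$values, ds$coverage$A$chr1$values)
})

test_that("state paths follow the planted transition matrix", {
  set.seed(37)
  cfg <- generator_config(n_genes = 320L, seed = 38)  # ~1e5 transitions
  ds <- generate_dataset(cfg)
  tr <- estimate_transitions(ds$truth$states_a)
  expect_lt(abs(tr$A["M", "M"] - cfg$a_mm), 0.02)
  expect_lt(abs(tr$A["d", "d"] - cfg$a_dd), 0.02)
})

test_that("peak-segment 6-mer frequencies follow the planted distribution", {
  # with all peak runs shared, every peak segment draws from the common
  # distribution; bin the 4096 cells so expected counts support a chi^2 GOF
  cfg <- generator_config(n_genes = 320L, shared_fraction = 1,
                          seed = 39)
  ds <- generate_dataset(cfg)
  sel <- ds$truth$seg_class == "common"
  expect_gt(sum(sel), 2e4)
  idx <- kmer_index(ds$windows$segments[sel])
  bins <- (idx - 1L) %/% 64L
  obs <- tabulate(bins + 1L, 64L)
  p_bin <- as.vector(rowsum(unname(ds$truth$emissions$p_common),
                            (seq_len(4096) - 1L) %/% 64L))
  gof <- chisq.test(obs, p = p_bin)
  expect_gt(gof$p.value, 0.01)
})

test_that("coverage recovers planted peak bases at the >= 5 read rule", {
  cfg <- generator_config(n_genes = 60L, n_chroms = 2L, seed = 40)
  ds <- generate_dataset(cfg)
  # pool sensitivity over all windows of one chromosome
  hits <- 0L; total <- 0L
  g <- ds$windows$genes
  st <- ds$truth$states_a
  for (i in which(g$chrom == "chr1")) {
    mask <- enriched_mask(ds$coverage$A$chr1)
    mseg <- which(st[i, ])
    if (!length(mseg)) next
    if (g$strand[i] == "+") {
      starts <- g$start[i] + (mseg - 1L) * 6L
    } else {
      starts <- g$start[i] + 2004L - mseg * 6L
    }
    bases <- as.vector(outer(1:6, starts, `+`))
    hits <- hits + sum(mask[bases])
    total <- total + length(bases)
  }
  expect_gte(hits / total, 0.95)
})

test_that("a zeroed emission signal yields chance-level inference", {
  cfg <- generator_config(n_genes = 400L, tau = 0, delta = 0, seed = 41)
  ds <- generate_dataset(cfg)
  # estimate on the first half of the genes, score the held-out half
  est <- seq_len(200L)
  w_est <- ds$windows
  w_est$genes <- w_est$genes[est, ]; w_est$segments <- w_est$segments[est, ]
  w_val <- ds$windows
  w_val$genes <- w_val$genes[-est, ]; w_val$segments <- w_val$segments[-est, ]
  cts_all <- count_weighted_kmers(ds$windows,
                                  matrix(as.numeric(ds$truth$states_a),
                                         nrow(ds$truth$states_a)))
  spec_all <- estimate_spectrum(cts_all$peak_counts, cts_all$dip_counts)
  # ratios approximately 1: no planted enrichment survives
  expect_lt(mean(abs(log(spec_all$p_peak / spec_all$p_dip))), 0.35)
  cts <- count_weighted_kmers(w_est,
                              matrix(as.numeric(ds$truth$states_a[est, ]),
                                     length(est)))
  spec <- estimate_spectrum(cts$peak_counts, cts$dip_counts)
  m <- hmm_model(c(0.3, 0.7),
                 matrix(c(0.95, 0.05, 0.02, 0.98), 2, 2, byrow = TRUE),
                 spec)
  G <- signature_profiles(m, w_val)
  a <- auc(as.vector(G), as.vector(ds$truth$states_a[-est, ]))
  expect_lt(abs(a - 0.5), 0.05)
})

test_that("simulated reads reproduce the target pileup after extension", {
  set.seed(43)
  rate <- c(rep(1, 20000), rep(20, 4000), rep(1, 6000))
  rd <- simulate_reads(rate, chrom = "c")
  ext <- extend_reads(rd, 150L, chrom_lengths = c(c = 30000L))
  pu <- pileup(ext, list(chrom = "c", start = 0L, end = 30000L))
  expect_equal(mean(pu$values[20301:23850]), 20, tolerance = 0.15)
  expect_equal(mean(pu$values[500:19800]), 1, tolerance = 0.15)
})

test_that("truth_eval is at ceiling against the truth and at chance shuffled", {
  cfg <- generator_config(n_genes = 50L, n_chroms = 2L, seed = 44)
  ds <- generate_dataset(cfg)
  st <- ds$truth$states_a
  g_perfect <- matrix(as.numeric(st), nrow(st),
                      dimnames = dimnames(st))
  ev <- truth_eval(ds$truth, gamma = g_perfect)
  expect_equal(ev$state_auc, 1)
  ey <- setNames(ds$expression$A$log_level, ds$expression$A$gene_id)
  ev2 <- truth_eval(ds$truth, predicted_expression = ey,
                    measured_expression = ds$expression$A)
  expect_equal(ev2$expression_spearman, 1)
  expect_equal(ev2$expression_auc, 1)
  set.seed(45)
  shuf <- matrix(sample(as.numeric(st)), nrow(st), dimnames = dimnames(st))
  expect_lt(abs(truth_eval(ds$truth, gamma = shuf)$state_auc - 0.5), 0.02)
  bad <- g_perfect
  rownames(bad) <- rev(rownames(bad))
  expect_error(truth_eval(ds$truth, gamma = bad), "match")
})
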