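test_that("reads are extended 150 bp from their 5' ends and clipped", {
  r <- data.frame(chrom = "c", start = c(100L, 500L), end = c(136L, 536L),
                  strand = c("+", "-"))
  e <- extend_reads(r)
  expect_equal(e$start, c(100L, 386L))
  expect_equal(e$end, c(250L, 536L))
  # clipping at chromosome bounds
  r2 <- data.frame(chrom = "c", start = c(980L, 10L), end = c(1000L, 46L),
                   strand = c("+", "-"))
  e2 <- extend_reads(r2, 150L, chrom_lengths = c(c = 1000L))
  expect_true(all(e2$start >= 0L) && all(e2$end <= 1000L))
  expect_error(extend_reads(r, length = 0), "> 0")
})

test_that("pileup counts covering intervals and conserves mass", {
  iv <- data.frame(chrom = "c", start = c(0L, 1L), end = c(3L, 4L))
  tr <- pileup(iv, list(chrom = "c", start = 0L, end = 5L))
  expect_equal(tr$values, c(1, 2, 2, 1, 0))
  # disjoint intervals never exceed 1
  iv2 <- data.frame(chrom = "c", start = c(0L, 10L), end = c(5L, 15L))
  expect_equal(max(pileup(iv2, list(chrom = "c", start = 0L,
                                    end = 20L))$values), 1)
  # conservation on random intervals (clipped to the region)
  set.seed(5)
  for (i in 1:10) {
    s <- sample(0:900, 40, TRUE)
    iv3 <- data.frame(chrom = "c", start = s,
                      end = pmin(s + sample(5:120, 40, TRUE), 1000L))
    tr3 <- pileup(iv3, list(chrom = "c", start = 0L, end = 1000L))
    expect_equal(sum(tr3$values), sum(iv3$end - iv3$start))
  }
  # empty input gives an all-zero track
  expect_equal(sum(pileup(iv[0, ], list(chrom = "c", start = 0L,
                                        end = 10L))$values), 0)
})

test_that("enriched mask applies the >= 5 reads-per-base rule", {
  tr <- coverage_track("c", 0L, c(3, 5, 5, 2))
  expect_equal(enriched_mask(tr), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(enriched_mask(coverage_track("c", 0L, numeric(10)))))
})

test_that("peak heights equal coverage over the local 2-kbp maximum", {
  v <- numeric(3000)
  v[1000:1200] <- 8
  v[1100] <- 16
  tr <- coverage_track("c", 0L, v)
  ph <- peak_height(tr)
  expect_equal(ph$h[1000], 0.5)   # 8 / local max 16
  expect_equal(ph$h[1100], 1.0)   # the local maximum itself
  expect_equal(ph$h[10], 0)       # non-enriched
  expect_error(peak_height(tr, neighborhood = 0), "even")
  expect_error(peak_height(tr, neighborhood = 11), "even")
})

test_that("optimized sliding-max normalization equals the brute-force oracle", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(200:2000, 1)
    half <- sample(20:400, 1)
    v <- rpois(n, sample(2:8, 1))
    tr <- coverage_track("c", 0L, v)
    mask <- enriched_mask(tr, 4)
    ph <- peak_height(tr, mask, neighborhood = 2L * half)
    expected <- ifelse(mask, v / brute_sliding_max(v, half), 0)
    expect_identical(ph$h, expected)
  }
})

test_that("peak heights are scale-invariant and idempotent on plateaus", {
  set.seed(7)
  v <- rpois(1500, 4)
  tr1 <- coverage_track("c", 0L, v)
  tr2 <- coverage_track("c", 0L, 7 * v)
  m <- enriched_mask(tr1, 5)
  expect_equal(peak_height(tr1, m)$h, peak_height(tr2, m)$h)
  # an already-normalized single plateau yields 1 on the plateau
  v0 <- numeric(3000); v0[1400:1600] <- 1
  ph <- peak_height(coverage_track("c", 0L, v0), v0 > 0)
  expect_true(all(ph$h[1400:1600] == 1))
})

test_that("segment heights reduce per-base values and respect strand", {
  n_bases <- 20000L
  h <- numeric(n_bases)
  g <- data.frame(gene_id = c("gp", "gn"), chrom = "c",
                  tss = c(5000L, 12000L), strand = c("+", "-"),
                  start = c(5000L - 1002L, 12000L - 1001L), end = 0L)
  g$end <- g$start + 2004L
  w <- structure(list(genes = g,
                      segments = matrix("AAAAAA", 2, 334,
                                        dimnames = list(g$gene_id, NULL)),
                      half_width = 1002L, oriented = TRUE),
                 class = "tss_windows")
  # uniform 0.4 over the first segment of the plus-strand window
  h[(g$start[1] + 1):(g$start[1] + 6)] <- 0.4
  # mark the genomically-last 6 bases of the minus-strand window: segment 1
  h[(g$end[2] - 5):g$end[2]] <- c(0.6, 0.6, 0.6, 0.6, 0.6, 0.0)
  prof <- structure(list(chrom = "c", start = 0L, h = h,
                         enriched = h > 0), class = "peak_height_profile")
  sh <- segment_heights(prof, w)
  expect_equal(unname(sh["gp", 1]), 0.4)
  expect_equal(unname(sh["gn", 1]), 0.5)  # mean of five 0.6s and one 0
  expect_equal(unname(sh["gp", 2]), 0)    # outside the enriched mask
  shm <- segment_heights(prof, w, reduce = "max")
  expect_equal(unname(shm["gn", 1]), 0.6)
  # random profile equals the per-segment mean oracle
  set.seed(8)
  h2 <- runif(n_bases)
  prof2 <- structure(list(chrom = "c", start = 0L, h = h2,
                          enriched = h2 > 0), class = "peak_height_profile")
  sh2 <- segment_heights(prof2, w)
  oracle <- colMeans(matrix(h2[(g$start[1] + 1):g$end[1]], nrow = 6))
  expect_equal(unname(sh2["gp", ]), oracle)
  oracle_n <- rev(colMeans(matrix(h2[(g$start[2] + 1):g$end[2]], nrow = 6)))
  expect_equal(unname(sh2["gn", ]), oracle_n)
})

test_that("peak-height features average heights in oriented 200-bp windows", {
  h <- rep(seq(0.1, 1, by = 0.1), each = 200)  # 2000 bp staircase
  hfull <- c(numeric(4000), h, numeric(4000))
  prof <- structure(list(chrom = "c", start = 0L, h = hfull,
                         enriched = hfull > 0), class = "peak_height_profile")
  g <- data.frame(gene_id = c("gp", "gn"), chrom = "c", tss = 5000L,
                  strand = c("+", "-"), start = c(3998L, 3999L), end = 0L)
  g$end <- g$start + 2004L
  w <- structure(list(genes = g,
                      segments = matrix("AAAAAA", 2, 334,
                                        dimnames = list(g$gene_id, NULL)),
                      half_width = 1002L, oriented = TRUE),
                 class = "tss_windows")
  X <- peak_height_features(prof, w)
  expect_equal(dim(X), c(2L, 10L))
  expect_equal(unname(X["gp", ]), seq(0.1, 1, by = 0.1))
  # minus-strand features run in the opposite genomic direction
  expect_equal(unname(X["gn", ]),
               rev(unname(X["gp", ])), tolerance = 0.03)
})
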