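test_that("read_peaks handles BED defaults and MACS coordinate shift", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t300", "chr2\t10\t20\tname\t42\t+"), bed)
  ps <- read_peaks(bed, "bed")
  expect_equal(ps$peaks$start, c(100, 10))
  expect_equal(ps$peaks$summit[1], 200)   # midpoint default
  expect_equal(ps$peaks$intensity, c(0, 42))

  macs <- tempfile(fileext = ".xls")
  writeLines(c("chr\tstart\tend\tsummit\ttags\tpvalue\tfdr_pct",
               "chr1\t101\t300\t151\t55\t1e-8\t0.2"), macs)
  pm <- read_peaks(macs, "macs_xls")
  expect_equal(pm$peaks$start, 100)       # 1-based inclusive -> 0-based
  expect_equal(pm$peaks$end, 300)
  expect_equal(pm$peaks$summit, 150)
})

test_that("read_peaks reports malformed lines and bad intervals by line number", {
  bad <- tempfile()
  writeLines(c("chr1\t100\t300", "chr1\txx\t400"), bad)
  expect_error(read_peaks(bad, "bed"), "line 2")
  rev_coords <- tempfile()
  writeLines("chr1\t400\t100", rev_coords)
  expect_error(read_peaks(rev_coords, "bed"), "end <= start")
})

test_that("peak files written by the generator round-trip exactly", {
  set.seed(11)
  ps <- peak_set(random_peak_df(5), condition = "resistant",
                 library_size = 2.4e7)
  f <- tempfile()
  write_peaks(ps, f, "macs_xls")
  back <- read_peaks(f, "macs_xls")
  expect_equal(back, ps)
})

test_that("FDR filter is inclusive at the cutoff and order-preserving", {
  df <- random_peak_df(3)
  df$fdr_pct <- c(0.4, 0.5, 0.6)
  ps <- peak_set(df)
  kept <- filter_by_fdr(ps, 0.5)
  expect_equal(kept$peaks$fdr_pct, c(0.4, 0.5))
  expect_equal(nrow(filter_by_fdr(peak_set(df[0, ]), 0.5)$peaks), 0)
  set.seed(1)
  ps100 <- peak_set(random_peak_df(100))
  expect_equal(nrow(filter_by_fdr(ps100, 100)$peaks), 100)
  expect_error(filter_by_fdr(ps, 101), "\\[0, 100\\]")
  # idempotent, and commutes with normalization
  expect_equal(filter_by_fdr(kept, 0.5), kept)
  expect_equal(filter_by_fdr(normalize_intensities(ps, 5e6), 0.5)$peaks,
               normalize_intensities(filter_by_fdr(ps, 0.5), 5e6)$peaks)
})

test_that("intensity normalization scales by depth exactly once", {
  df <- random_peak_df(50)
  ps <- peak_set(df, library_size = 2e7)
  norm <- normalize_intensities(ps, 1e7)
  expect_equal(norm$peaks$intensity, df$intensity / 2)
  expect_equal(sum(norm$peaks$intensity), sum(df$intensity) * 1e7 / 2e7)
  expect_true(norm$normalized)
  expect_error(normalize_intensities(norm, 1e7), "already normalized")
  same <- normalize_intensities(peak_set(df, library_size = 1e7), 1e7)
  expect_equal(same$peaks$intensity, df$intensity)
})

test_that("overlap uses half-open >= 1 bp semantics", {
  mk <- function(start, end) {
    ps <- peak_set(data.frame(chrom = "chr1", start = start, end = end,
                              summit = floor((start + end) / 2), intensity = 10,
                              pvalue = 0.01, fdr_pct = 0.1))
    normalize_intensities(ps, 1e7)
  }
  one_bp <- overlap_peaks(mk(100, 300), mk(299, 400))
  expect_equal(nrow(one_bp$pairs), 1)
  abutting <- overlap_peaks(mk(100, 300), mk(300, 400))
  expect_equal(nrow(abutting$pairs), 0)
  expect_equal(abutting$unique_a, 1)
  expect_equal(abutting$unique_b, 1)
  expect_error(overlap_peaks(mk(1, 5), peak_set(random_peak_df(2))),
               "normalized")
})

test_that("overlap classification matches the all-pairs oracle and is symmetric", {
  set.seed(21)
  for (rep in 1:20) {
    a <- random_peakset(sample(20:200, 1))
    b <- random_peakset(sample(20:200, 1), condition = "B")
    ov <- overlap_peaks(a, b)
    ref <- bf_overlap_classify(a$peaks, b$peaks)
    got <- as.matrix(ov$pairs[order(ov$pairs$a, ov$pairs$b), c("a", "b")])
    dimnames(got) <- NULL
    ref_pairs <- ref$pairs; dimnames(ref_pairs) <- NULL
    expect_equal(got, ref_pairs)
    expect_equal(sort(ov$unique_a), sort(ref$unique_a))
    expect_equal(sort(ov$unique_b), sort(ref$unique_b))
    # symmetry: transposed pairs
    ba <- overlap_peaks(b, a)
    expect_equal(got, as.matrix(ba$pairs[order(ba$pairs$b, ba$pairs$a),
                                         c("b", "a")], dimnames = NULL),
                 ignore_attr = TRUE)
    # count conservation
    expect_equal(length(unique(ov$pairs$a)) + length(ov$unique_a),
                 nrow(a$peaks))
  }
})

test_that("resistant-associated selection applies the ratio cutoff inclusively", {
  mk_pair <- function(int_a, int_b, n_unique_a = 0) {
    n <- length(int_a)
    pa <- data.frame(chrom = "chr1", start = (seq_len(n + n_unique_a) - 1) * 1000,
                     end = (seq_len(n + n_unique_a) - 1) * 1000 + 500)
    pa$summit <- pa$start + 250
    pa$intensity <- c(int_a, rep(7, n_unique_a))
    pa$pvalue <- 0.01; pa$fdr_pct <- 0.1
    pb <- pa[seq_len(n), ]
    pb$intensity <- int_b
    ov <- overlap_peaks(normalize_intensities(peak_set(pa), 1e7),
                        normalize_intensities(peak_set(pb), 1e7))
    ov
  }
  exact <- resistant_associated_sites(mk_pair(9, 10), 0.9)
  expect_equal(nrow(exact$peaks), 1)              # ratio exactly 0.9 retained
  below <- resistant_associated_sites(mk_pair(8.9, 10), 0.9)
  expect_equal(nrow(below$peaks), 0)
  # 3 passing common, 2 failing common, 4 unique -> 7
  ov <- mk_pair(c(10, 9, 20, 8, 1), c(10, 10, 10, 10, 10), n_unique_a = 4)
  sel <- resistant_associated_sites(ov, 0.9)
  expect_equal(nrow(sel$peaks), 7)
  expect_equal(sum(is.infinite(sel$peaks$best_ratio)), 4)
  no_unique <- resistant_associated_sites(ov, 0.9, include_unique = FALSE)
  expect_equal(nrow(no_unique$peaks), 3)
  expect_error(resistant_associated_sites(ov, -1), "positive")
})

test_that("annotation window is inclusive and matches the double-loop oracle", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 50000)
  mk <- function(summit) peak_set(data.frame(
    chrom = "chr1", start = summit - 100, end = summit + 100, summit = summit,
    intensity = 1, pvalue = 0.5, fdr_pct = 0))
  at_edge <- annotate_sites(mk(70000), genes, 20000)
  expect_equal(at_edge$gene_id, "g1")
  expect_equal(at_edge$distance, 20000)
  beyond <- annotate_sites(mk(70001), genes, 20000)
  expect_true(is.na(beyond$gene_id))
  # minus strand flips the sign
  genes$strand <- "-"
  expect_equal(annotate_sites(mk(60000), genes, 20000)$distance, -10000)

  set.seed(31)
  for (rep in 1:10) {
    ps <- random_peakset(sample(20:100, 1), normalized = FALSE,
                         max_pos = 80000)
    g <- random_gene_df(sample(5:50, 1))
    got <- as.data.frame(annotate_sites(ps, g, 15000))
    got <- got[!is.na(got$gene_id), c("peak_id", "gene_id", "distance")]
    ref <- bf_annotate(ps$peaks, g, 15000)
    got <- got[order(got$peak_id, got$gene_id), ]
    ref <- ref[order(ref$peak_id, ref$gene_id), ]
    expect_equal(got, ref, ignore_attr = TRUE)
  }
})

test_that("TSS distance histogram conserves counts and places mass correctly", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(10000, 30000))
  at_tss <- peak_set(data.frame(chrom = "chr1", start = 9900, end = 10100,
                                summit = 10000, intensity = 1, pvalue = 0.5,
                                fdr_pct = 0))
  h <- tss_distance_histogram(at_tss, genes, bin_width = 1000, max_dist = 5000)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$bin_start == 0], 1)  # distance 0 in the [0,1000) bin
  # equidistant from two TSSs: tie goes to the lexicographically smaller id
  mid <- peak_set(data.frame(chrom = "chr1", start = 19900, end = 20100,
                             summit = 20000, intensity = 1, pvalue = 0.5,
                             fdr_pct = 0))
  hm <- tss_distance_histogram(mid, genes, 1000, 15000)
  expect_equal(sum(hm$count), 1)
  expect_equal(hm$count[hm$bin_start == 10000], 1)  # +10 kb from g1

  set.seed(41)
  n <- 500
  g <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                  strand = "+", tss = (1:20) * 100000)
  summits <- g$tss[sample.int(20, n, TRUE)] + round(rnorm(n, 0, 1000))
  sim <- peak_set(data.frame(chrom = "chr1", start = summits - 200,
                             end = summits + 200, summit = summits,
                             intensity = 1, pvalue = 0.5, fdr_pct = 0))
  hs <- tss_distance_histogram(sim, g, 1000, 10000)
  expect_equal(sum(hs$count), n)
  core <- hs$bin_start >= -3000 & hs$bin_end <= 3000
  expect_gte(sum(hs$count[core]) / n, 0.95)
  expect_error(tss_distance_histogram(sim, g, 0, 1000), "positive")
})

test_that("ERE scanner matches brute force and respects strand symmetry", {
  cons <- "GGTCANNNTGACC"
  # a concrete ERE instance: the palindromic consensus hits on both strands
  self_hit <- scan_ere("GGTCAATATGACC", cons, 0)
  expect_equal(nrow(self_hit), 2)
  expect_equal(self_hit$offset, c(0, 0))
  expect_equal(self_hit$mismatches, c(0, 0))
  # sequence identical to a non-palindromic consensus: one forward hit only
  ident <- scan_ere("GGTCAA", "GGTCAA", 0)
  expect_equal(nrow(ident), 1)
  expect_equal(ident$strand, "+")
  expect_equal(ident$offset, 0)
  expect_equal(nrow(scan_ere("ACGT", cons, 0)), 0)  # consensus longer than seq
  # N in the sequence always a mismatch, even against N in the consensus
  expect_equal(scan_ere("GGTCANNNTGACC", cons, 3)$mismatches, c(3, 3))

  set.seed(51)
  for (rep in 1:5) {
    seq <- random_dna(1000)
    got <- scan_ere(seq, cons, 2)
    ref <- bf_scan(seq, cons, 2)
    ref <- ref[order(ref$offset, ref$strand), ]
    expect_equal(got[c("offset", "strand", "mismatches")], ref,
                 ignore_attr = TRUE)
    # reverse-complement invariance: hits reflect and swap strand
    rc <- scan_ere(revcomp(seq), cons, 2)
    reflected <- data.frame(offset = nchar(seq) - nchar(cons) - rc$offset,
                            strand = as.character(ifelse(rc$strand == "+", "-", "+")),
                            mismatches = rc$mismatches)
    reflected <- reflected[order(reflected$offset, reflected$strand), ]
    expect_equal(got[c("offset", "strand", "mismatches")], reflected,
                 ignore_attr = TRUE)
  }
})
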