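# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals.

bf_overlap_classify <- function(pa, pb) {
  # all-pairs O(n^2) classification under half-open semantics
  pairs <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] == pb$chrom[j] &&
          min(pa$end[i], pb$end[j]) - max(pa$start[i], pb$start[j]) >= 1)
        pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  m <- if (length(pairs)) do.call(rbind, pairs) else matrix(0L, 0, 2)
  list(pairs = m[order(m[, 1], m[, 2]), , drop = FALSE],
       unique_a = setdiff(seq_len(nrow(pa)), m[, 1]),
       unique_b = setdiff(seq_len(nrow(pb)), m[, 2]))
}

bf_annotate <- function(peaks, genes, window) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] == genes$chrom[j] &&
          abs(peaks$summit[i] - genes$tss[j]) <= window) {
        d <- peaks$summit[i] - genes$tss[j]
        if (genes$strand[j] == "-") d <- -d
        out[[length(out) + 1]] <- data.frame(peak_id = i,
                                             gene_id = genes$gene_id[j],
                                             distance = d)
      }
    }
  }
  if (!length(out)) return(data.frame(peak_id = integer(0),
                                      gene_id = character(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

bf_bh <- function(p) {
  # naive min-over-tail step-up: q_i = min_{j: p_j >= p_i} m * p_j / rank(p_j)
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(seq_len(m), function(k) m * p[ord[k]] / k, numeric(1))
    pos <- which(ord == i)
    q[i] <- min(1, min(vals[pos:m]))
  }
  q
}

bf_cox_score <- function(x, time, event) {
  U <- 0; I <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    xb <- mean(x[rs])
    U <- U + (x[i] - xb)
    I <- I + (mean(x[rs]^2) - xb^2)
  }
  if (I <= 1e-12) return(0)
  U / sqrt(I)
}

bf_logrank_chisq <- function(time, event, groups) {
  groups <- as.integer(factor(groups))
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & groups == 1)
    e1 <- d * n1 / n
    oe <- oe + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  oe^2 / v
}

bf_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, survival = s, at_risk = n,
                                 events = d))
  }
  out
}

IUPAC_ORACLE <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

bf_scan_one_strand <- function(seq, cons) {
  # mismatch count per window, substring at a time
  s <- strsplit(seq, "")[[1]]
  k <- strsplit(cons, "")[[1]]
  n_win <- length(s) - length(k) + 1
  if (n_win < 1) return(integer(0))
  vapply(seq_len(n_win), function(o) {
    win <- s[o:(o + length(k) - 1)]
    sum(vapply(seq_along(k), function(j)
      win[j] == "N" || !(win[j] %in% IUPAC_ORACLE[[k[j]]]), logical(1)))
  }, integer(1))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

bf_scan <- function(seq, cons, max_mm) {
  fwd <- bf_scan_one_strand(seq, cons)
  rev_ <- bf_scan_one_strand(seq, oracle_revcomp(cons))
  fi <- which(fwd <= max_mm); ri <- which(rev_ <= max_mm)
  rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               mismatches = fwd[fi]),
    data.frame(offset = ri - 1L, strand = rep("-", length(ri)),
               mismatches = rev_[ri]))
}

# quick random fixtures ------------------------------------------------------

random_peak_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 50000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(50:500, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + w, summit = start + floor(w / 2),
             intensity = round(runif(n, 1, 100), 3),
             pvalue = runif(n, 1e-10, 1), fdr_pct = round(runif(n, 0, 5), 3),
             stringsAsFactors = FALSE)
}

random_peakset <- function(n, condition = "A", normalized = TRUE, ...) {
  ps <- peak_set(random_peak_df(n, ...), condition = condition,
                 library_size = 1e7)
  if (normalized) ps <- normalize_intensities(ps, 1e7)
  ps
}

random_gene_df <- function(n, chroms = c("chr1", "chr2"), max_pos = 60000) {
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             tss = sample.int(max_pos, n), stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
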