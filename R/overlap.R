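peaks_to_granges <- function(ps) {
  p <- ps$peaks
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end))  # 0-based half-open -> 1-based closed
}

#' Compare two peak sets by genomic overlap
#'
#' Classifies binding sites as "common" when a site in set A shares at least
#' 1 bp with a site in set B (half-open interval semantics: overlap length
#' `min(endA, endB) - max(startA, startB) >= 1`; abutting intervals do not
#' overlap), and "unique" otherwise. Each common pair carries the intensity
#' change ratio `intensity(A) / intensity(B)` of depth-normalized
#' intensities; a peak overlapping several partners contributes one pair per
#' partner but is counted once in the common totals.
#'
#' @param a,b normalized PeakSets ([normalize_intensities()]) with the same
#'   `scale_to`. By convention `a` is the resistant condition (ratio
#'   numerator) and `b` the responsive condition.
#' @return an object of class `OverlapResult`: `pairs` (data.frame `a`, `b`
#'   row indices and `ratio`), `unique_a`, `unique_b` (row indices), and the
#'   input sets.
#' @export
overlap_peaks <- function(a, b) {
  stopifnot(inherits(a, "PeakSet"), inherits(b, "PeakSet"))
  if (!a$normalized || !b$normalized)
    stop("both PeakSets must be normalized before overlap analysis")
  if (!isTRUE(all.equal(a$scale_to, b$scale_to)))
    stop("PeakSets were normalized to different read depths")
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(a), peaks_to_granges(b),
                                      minoverlap = 1L)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(a = ia, b = ib,
                      ratio = a$peaks$intensity[ia] / b$peaks$intensity[ib])
  structure(
    list(pairs = pairs,
         unique_a = setdiff(seq_len(nrow(a$peaks)), unique(ia)),
         unique_b = setdiff(seq_len(nrow(b$peaks)), unique(ib)),
         set_a = a, set_b = b),
    class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: %s vs %s\n", x$set_a$condition, x$set_b$condition))
  cat(sprintf("  common: %d A-peaks / %d B-peaks (%d pairs)\n",
              length(unique(x$pairs$a)), length(unique(x$pairs$b)),
              nrow(x$pairs)))
  cat(sprintf("  unique to A: %d; unique to B: %d\n",
              length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Select resistant-associated binding sites
#'
#' From an overlap of resistant (A) over responsive (B) peaks, keeps the
#' A-side peaks whose binding persists in the resistant condition: common
#' peaks with change ratio at or above the cutoff (default 0.9, i.e. 90% or
#' greater of the responsive-condition intensity), plus, by default, peaks
#' found only in the resistant condition, for which the ratio is undefined
#' but binding is trivially persistent. Each retained peak appears once,
#' annotated with its best ratio (`Inf` for unique peaks).
#'
#' @param ov an [overlap_peaks()] result with A = resistant condition.
#' @param min_ratio inclusive change-ratio cutoff (> 0), default 0.9.
#' @param include_unique include A-only peaks (default `TRUE`).
#' @return a PeakSet of resistant-associated A peaks with an extra
#'   `best_ratio` column.
#' @export
resistant_associated_sites <- function(ov, min_ratio = 0.9, include_unique = TRUE) {
  stopifnot(inherits(ov, "OverlapResult"))
  if (!is.numeric(min_ratio) || length(min_ratio) != 1 || min_ratio <= 0)
    stop("min_ratio must be a single positive number")
  best <- tapply(ov$pairs$ratio, ov$pairs$a, max)
  pass_common <- as.integer(names(best))[best >= min_ratio]
  idx <- sort(unique(c(pass_common,
                       if (include_unique) ov$unique_a else integer(0))))
  out <- subset_peakset(ov$set_a, idx)
  ratio <- rep(Inf, length(idx))
  m <- match(idx, as.integer(names(best)))
  ratio[!is.na(m)] <- as.numeric(best)[m[!is.na(m)]]
  out$peaks$best_ratio <- ratio
  out
}
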