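#' Annotate peaks with genes near the TSS
#'
#' A gene is assigned to a peak when the peak summit lies within `window` bp
#' of the gene's transcription start site (inclusive: `|summit - tss| <=
#' window`, default +/-20 kb). Distances are signed strand-aware:
#' `summit - tss` on the + strand, `tss - summit` on the - strand, so
#' upstream is negative for either orientation. Peaks with no gene in range
#' are retained with `gene_id = NA`.
#'
#' @param ps a PeakSet (the resistant-associated set in the pipeline; a
#'   `best_ratio` column, when present, is carried through).
#' @param genes gene annotation table (`gene_id`, `chrom`, `strand`, `tss`).
#' @param window half-width of the annotation window in bp (default 20000).
#' @return data.frame of class `AnnotatedSites`, one row per (peak, gene)
#'   pair: peak coordinates, `peak_id` (row index in `ps`), `best_ratio` if
#'   available, `gene_id`, `distance`.
#' @export
annotate_sites <- function(ps, genes, window = 20000) {
  stopifnot(inherits(ps, "PeakSet"))
  genes <- validate_gene_table(genes)
  if (!is.numeric(window) || length(window) != 1 || window <= 0)
    stop("window must be a single positive number")
  p <- ps$peaks
  summits <- GenomicRanges::GRanges(p$chrom,
                                    IRanges::IRanges(p$summit + 1L, p$summit + 1L))
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss - window + 1L,
                                                 genes$tss + window + 1L))
  hits <- GenomicRanges::findOverlaps(summits, win)
  ip <- S4Vectors::queryHits(hits)
  ig <- S4Vectors::subjectHits(hits)
  d <- p$summit[ip] - genes$tss[ig]
  d <- ifelse(genes$strand[ig] == "+", d, -d)

  no_gene <- setdiff(seq_len(nrow(p)), unique(ip))
  idx <- c(ip, no_gene)
  out <- data.frame(
    peak_id = idx,
    chrom = p$chrom[idx], start = p$start[idx], end = p$end[idx],
    summit = p$summit[idx],
    gene_id = c(genes$gene_id[ig], rep(NA_character_, length(no_gene))),
    distance = c(d, rep(NA_real_, length(no_gene))),
    stringsAsFactors = FALSE)
  if (!is.null(p$best_ratio)) out$best_ratio <- p$best_ratio[idx]
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AnnotatedSites", "data.frame")
  out
}

closest_tss <- function(summit, chrom, genes) {
  ## signed strand-aware distance to the closest TSS on the same chromosome;
  ## ties broken by lexicographically smaller gene_id. +Inf when the
  ## chromosome carries no annotated gene.
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(Inf)
  dd <- abs(g$tss - summit)
  cand <- which(dd == min(dd))
  if (length(cand) > 1) cand <- cand[order(g$gene_id[cand])][1]
  d <- summit - g$tss[cand]
  if (g$strand[cand] == "-") d <- -d
  d
}

#' Histogram of peak distances to the closest TSS
#'
#' For each peak, the signed strand-aware distance from its summit to the
#' closest TSS on the same chromosome is computed and binned. Distances
#' beyond `+/-max_dist` (including peaks on chromosomes with no annotated
#' gene) fall into open-ended edge bins, so counts always sum to the number
#' of peaks. This is the distribution used to compare TSS-proximal ER
#' recruitment between conditions.
#'
#' @param ps a PeakSet.
#' @param genes gene annotation table.
#' @param bin_width bin width in bp (> 0).
#' @param max_dist extent of the regular bins in bp.
#' @return data.frame `bin_start`, `bin_end`, `count`; edge bins have
#'   infinite bounds.
#' @export
tss_distance_histogram <- function(ps, genes, bin_width = 1000, max_dist = 20000) {
  stopifnot(inherits(ps, "PeakSet"))
  genes <- validate_gene_table(genes)
  if (!nrow(genes)) stop("gene table is empty")
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("bin_width must be a single positive number")
  p <- ps$peaks
  d <- vapply(seq_len(nrow(p)),
              function(i) closest_tss(p$summit[i], p$chrom[i], genes),
              numeric(1))
  breaks <- c(-Inf, seq(-max_dist, max_dist, by = bin_width), Inf)
  counts <- as.integer(table(cut(d, breaks = breaks, right = FALSE)))
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}

#' Write resistant-associated sites as BED6
#'
#' The score column carries the change ratio scaled by 1000 and clamped to
#' `[0, 1000]` (unique peaks, ratio `Inf`, clamp to 1000).
#'
#' @param ps PeakSet with a `best_ratio` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(ps, path) {
  p <- ps$peaks
  ratio <- if (is.null(p$best_ratio)) rep(NA_real_, nrow(p)) else p$best_ratio
  score <- pmin(pmax(round(ratio * 1000), 0), 1000)
  score[!is.finite(ratio)] <- 1000
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", p$chrom, as.integer(p$start),
                     as.integer(p$end), sprintf("site_%d", seq_len(nrow(p))),
                     as.integer(score)), path)
  invisible(path)
}

#' Write a peak-gene annotation table as TSV
#' @param annot an [annotate_sites()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
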