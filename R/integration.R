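#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order. A thin validated front-end over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must be in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression on log2 data
#'
#' Per gene: linear fold change `2^(mean(A) - mean(B))` where `A` is the
#' first group label encountered (the resistant condition in the pipeline),
#' a two-sided Welch (unequal-variance) t-test p-value, and Benjamini-
#' Hochberg q-values across all genes. Genes with zero variance in both
#' groups get `p = 1` when the means are equal and `p = 0` otherwise.
#'
#' @param expr numeric matrix, genes x replicates, log2 scale; rownames are
#'   gene ids.
#' @param groups length-`ncol(expr)` two-level labels.
#' @return data.frame `gene_id`, `fold_change`, `pvalue`, `qvalue`.
#' @export
differential_expression <- function(expr, groups) {
  expr <- as.matrix(expr)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("groups must have exactly two levels")
  a <- groups == lv[1]; b <- groups == lv[2]
  if (sum(a) < 2 || sum(b) < 2) stop("need >= 2 replicates per group")
  na <- sum(a); nb <- sum(b)
  ma <- rowMeans(expr[, a, drop = FALSE]); mb <- rowMeans(expr[, b, drop = FALSE])
  va <- apply(expr[, a, drop = FALSE], 1, stats::var)
  vb <- apply(expr[, b, drop = FALSE], 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             fold_change = 2^(ma - mb), pvalue = p, qvalue = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Candidate ER target genes from binding plus expression evidence
#'
#' A gene becomes a candidate when (i) it is annotated to at least one
#' resistant-associated binding site, (ii) its cell-line fold change passes
#' the cutoff -- two-sided by default, `max(fc, 1/fc) >= min_fc` -- and
#' (iii) its FDR-adjusted p-value is strictly below `max_q`. Genes annotated
#' to a site but absent from the expression table are excluded. This is the
#' stage that produced the 350-gene list in the motivating analysis.
#'
#' @param annot an [annotate_sites()] result over resistant-associated sites.
#' @param de differential-expression table (`gene_id`, `fold_change`,
#'   `pvalue`, `qvalue`).
#' @param min_fc inclusive fold-change cutoff (>= 1), default 1.2.
#' @param max_q strict adjusted-p cutoff, default 0.05.
#' @param two_sided treat down-regulation symmetrically (default `TRUE`).
#' @return data.frame of class `CandidateGeneList`, ordered by `qvalue`:
#'   `gene_id`, `n_peaks`, `best_ratio`, `fold_change`, `pvalue`, `qvalue`.
#' @export
candidate_genes <- function(annot, de, min_fc = 1.2, max_q = 0.05,
                            two_sided = TRUE) {
  if (!is.numeric(min_fc) || length(min_fc) != 1 || min_fc < 1)
    stop("min_fc must be a single value >= 1")
  if (!is.numeric(max_q) || length(max_q) != 1 || max_q <= 0 || max_q > 1)
    stop("max_q must be in (0, 1]")
  a <- as.data.frame(annot)
  a <- a[!is.na(a$gene_id), , drop = FALSE]
  if (is.null(a$best_ratio)) a$best_ratio <- NA_real_
  n_peaks <- tapply(a$peak_id, a$gene_id, function(x) length(unique(x)))
  best_ratio <- tapply(a$best_ratio, a$gene_id, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  bound <- data.frame(gene_id = names(n_peaks),
                      n_peaks = as.integer(n_peaks),
                      best_ratio = as.numeric(best_ratio),
                      stringsAsFactors = FALSE)
  m <- merge(bound, as.data.frame(de), by = "gene_id")
  eff_fc <- if (two_sided) pmax(m$fold_change, 1 / m$fold_change) else m$fold_change
  keep <- eff_fc >= min_fc & m$qvalue < max_q
  out <- m[keep, c("gene_id", "n_peaks", "best_ratio", "fold_change",
                   "pvalue", "qvalue"), drop = FALSE]
  out <- out[order(out$qvalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CandidateGeneList", "data.frame")
  out
}

#' Read / write a differential-expression table
#' @param path TSV with header `gene_id fold_change pvalue qvalue`.
#' @return data.frame of DE records.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "fold_change", "pvalue", "qvalue")
  if (!all(required %in% names(de)))
    stop("DE table needs columns: ", paste(required, collapse = ", "))
  de
}

#' @rdname read_de_table
#' @param de differential-expression data.frame.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a candidate gene list
#'
#' Writes the provenance table as TSV and, optionally, a plain one-id-per-
#' line gene list for downstream tools.
#'
#' @param candidates a [candidate_genes()] result.
#' @param path output TSV.
#' @param list_path optional plain-text gene list path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, list_path = NULL) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(list_path)) writeLines(candidates$gene_id, list_path)
  invisible(path)
}
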