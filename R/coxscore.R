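#' Univariate Cox score statistic
#'
#' The partial-likelihood score statistic at `beta = 0` for one covariate,
#' `s = U / sqrt(I)`, with Breslow handling of tied event times:
#' `U = sum over events i of (x_i - mean(x over risk set R_i))` and
#' `I = sum over events i of (mean(x^2 over R_i) - mean(x over R_i)^2)`,
#' where `R_i = {j : time_j >= time_i}`. Asymptotically standard normal for
#' a gene unrelated to survival; the sign is positive when higher expression
#' accompanies higher hazard. Used to rank genes for survival screening
#' (cutoff 2.39 in [select_genes_by_cox()]). Constant covariates give a
#' degenerate score of 0.
#'
#' @param x per-patient covariate (one gene's expression).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators; at least one event required.
#' @return the score statistic (single number).
#' @export
cox_score <- function(x, time, event) {
  as.numeric(cox_score_matrix(matrix(as.numeric(x), ncol = 1), time, event))
}

#' Cox scores for a matrix of covariates
#'
#' Vectorized form of [cox_score()]: one score per column of `x`.
#'
#' @param x numeric matrix, patients x genes.
#' @param time,event as in [cox_score()].
#' @return named numeric vector of scores.
#' @export
cox_score_matrix <- function(x, time, event) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(time) != n || length(event) != n)
    stop("time/event length must match nrow(x)")
  if (n < 2) stop("need at least 2 patients")
  if (!any(event == 1)) stop("Cox score undefined with no events")

  ord <- order(time, decreasing = TRUE)
  xs <- x[ord, , drop = FALSE]
  cs1 <- apply(xs, 2, cumsum)
  cs2 <- apply(xs * xs, 2, cumsum)
  if (n == 1) { cs1 <- matrix(cs1, nrow = 1); cs2 <- matrix(cs2, nrow = 1) }

  ts <- time[ord]; ev <- event[ord]
  ## size of the risk set at each subject's time: #{j : time_j >= time_i}
  r <- rank(-ts, ties.method = "max")
  idx <- which(ev == 1)
  ri <- r[idx]
  mean1 <- cs1[ri, , drop = FALSE] / ri
  mean2 <- cs2[ri, , drop = FALSE] / ri
  U <- colSums(xs[idx, , drop = FALSE]) - colSums(mean1)
  I <- colSums(mean2 - mean1^2)
  s <- ifelse(I > 1e-12, U / sqrt(pmax(I, 1e-300)), 0)
  names(s) <- colnames(x)
  s
}

#' Cox scores for every gene of a cohort
#'
#' Expression is z-scored per gene before scoring by default, which puts the
#' score of every gene on the same per-SD scale that a fixed cutoff such as
#' 2.39 presupposes. Constant genes score 0.
#'
#' @param x a [cohort()].
#' @param genes gene ids to score (default all).
#' @param standardize z-score each gene first (default `TRUE`).
#' @return data.frame `gene_id`, `score`.
#' @export
cox_scores <- function(x, genes = colnames(x$expr), standardize = TRUE) {
  stopifnot(inherits(x, "Cohort"))
  missing_genes <- setdiff(genes, colnames(x$expr))
  if (length(missing_genes))
    stop("genes not in cohort: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  em <- x$expr[, genes, drop = FALSE]
  if (standardize) {
    sds <- apply(em, 2, stats::sd)
    em <- sweep(em, 2, colMeans(em), "-")
    ok <- sds > 0
    em[, ok] <- sweep(em[, ok, drop = FALSE], 2, sds[ok], "/")
  }
  data.frame(gene_id = genes,
             score = as.numeric(cox_score_matrix(em, x$time, x$event)),
             stringsAsFactors = FALSE)
}

#' Select genes by absolute Cox score
#'
#' Scores every requested gene and keeps those with `|score| >= cutoff`
#' (default 2.39), sorted by decreasing `|score|`. Both signs are retained:
#' a negative score marks a gene whose high expression accompanies better
#' survival (protective), a positive score the reverse.
#'
#' @param x a [cohort()].
#' @param genes gene ids to screen (default all; ids absent from the cohort
#'   are dropped and reported in the `"not_evaluated"` attribute).
#' @param cutoff absolute-score cutoff (default 2.39).
#' @param standardize z-score genes before scoring (default `TRUE`).
#' @return data.frame `gene_id`, `score`, ranked by `|score|` descending,
#'   with attribute `not_evaluated`.
#' @export
select_genes_by_cox <- function(x, genes = colnames(x$expr), cutoff = 2.39,
                                standardize = TRUE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    stop("cutoff must be a single non-negative number")
  present <- intersect(genes, colnames(x$expr))
  sc <- cox_scores(x, present, standardize = standardize)
  sc <- sc[abs(sc$score) >= cutoff, , drop = FALSE]
  sc <- sc[order(-abs(sc$score), sc$gene_id), , drop = FALSE]
  rownames(sc) <- NULL
  attr(sc, "not_evaluated") <- setdiff(genes, present)
  attr(sc, "cutoff") <- cutoff
  sc
}
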