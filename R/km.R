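#' Split patients at the median of one gene
#'
#' `low` is `x <= median(x)`, `high` is `x > median(x)`; values tied with
#' the median go to the low group. A constant vector cannot be split.
#'
#' @param x per-patient expression of one gene (length >= 2).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  if (length(x) < 2) stop("need at least 2 patients")
  if (length(unique(x)) == 1) stop("degenerate grouping: expression is constant")
  m <- stats::median(x)
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` and returns the curve at event times only:
#' `S(t_i) = S(t_{i-1}) * (1 - d_i / n_i)` with `d_i` events among `n_i` at
#' risk. With censored-only data the curve has no steps (S is identically 1).
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return data.frame of class `KMCurve`: `time`, `survival`, `at_risk`,
#'   `events` (one row per distinct event time).
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("need at least 1 patient")
  if (any(!is.finite(time) | time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], survival = fit$surv[keep],
                    at_risk = fit$n.risk[keep], events = fit$n.event[keep])
  rownames(out) <- NULL
  class(out) <- c("KMCurve", "data.frame")
  attr(out, "n") <- length(time)
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#' @param curve a [km_estimate()] result.
#' @param t time at which to read off survival.
#' @return `S(t)` (1 before the first event).
#' @export
km_survival_at <- function(curve, t) {
  if (!nrow(curve)) return(1)
  i <- findInterval(t, curve$time)
  if (i == 0) 1 else curve$survival[i]
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Compares the survival experience of two groups with the log-rank
#' chi-square statistic (1 df), `(sum_i (d_1i - e_1i))^2 / sum_i v_i`, where
#' at each distinct event time `e_1i` and `v_i` are the hypergeometric mean
#' and variance of events in group 1. Computed via `survival::survdiff`.
#' When the statistic is degenerate (no events, or every event in a risk set
#' of one) the convention `statistic = 0, p = 1` applies.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param groups two-level labels, both levels non-empty.
#' @return object of class `SurvivalComparison`: `group_labels`, per-group
#'   `curves` ([km_estimate()]), `statistic`, `pvalue`, group sizes `n`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("need exactly two non-empty groups")
  if (any(!is.finite(time) | time <= 0)) stop("time must be positive")
  if (sum(event) == 0) {
    chisq <- 0; p <- 1
  } else {
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ groups)
    chisq <- as.numeric(sd_fit$chisq)
    if (!is.finite(chisq)) { chisq <- 0; p <- 1 }
    else p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  curves <- lapply(levels(groups), function(g)
    km_estimate(time[groups == g], event[groups == g]))
  names(curves) <- levels(groups)
  structure(list(group_labels = groups, curves = curves,
                 statistic = chisq, pvalue = p, n = table(groups)),
            class = "SurvivalComparison")
}

#' @export
print.SurvivalComparison <- function(x, ...) {
  meta <- attr(x, "meta")
  if (!is.null(meta)) cat(sprintf("Survival comparison: %s\n", meta))
  sizes <- paste(sprintf("%s n=%d", names(x$n), as.integer(x$n)), collapse = ", ")
  cat(sprintf("  groups: %s\n", sizes))
  cat(sprintf("  log-rank chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$pvalue))
  invisible(x)
}

#' Plot the Kaplan-Meier curves of a comparison
#' @param x a [logrank_test()] / [single_gene_km()] result.
#' @param ... passed to `plot`.
#' @export
plot.SurvivalComparison <- function(x, ...) {
  cols <- c("#1f77b4", "#d62728")
  xmax <- max(unlist(lapply(x$curves, function(k)
    if (nrow(k)) max(k$time) else 1)))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = "time",
       ylab = "survival probability", ...)
  for (i in seq_along(x$curves)) {
    k <- x$curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$survival)), col = cols[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(x$curves), col = cols, lty = 1,
                   bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$pvalue), side = 3, adj = 1,
                  cex = 0.8)
  invisible(x)
}

#' Median-split survival comparison for a single gene
#'
#' Splits patients at the median expression of one gene and compares the
#' high- and low-expression groups by Kaplan-Meier / log-rank. Deterministic:
#' no randomness on this path.
#'
#' @param x a [cohort()].
#' @param gene_id gene present in the cohort.
#' @return a [logrank_test()] result with groups `low` / `high`.
#' @export
single_gene_km <- function(x, gene_id) {
  stopifnot(inherits(x, "Cohort"))
  if (!gene_id %in% colnames(x$expr)) stop("gene not in cohort: ", gene_id)
  grp <- median_split(x$expr[, gene_id])
  out <- logrank_test(x$time, x$event, grp)
  attr(out, "meta") <- sprintf("%s, median split, endpoint %s", gene_id,
                               x$endpoint)
  out
}

#' Two-means risk stratification on a gene panel
#'
#' Clusters patients into two groups by k-means (k = 2, 20 restarts,
#' Euclidean distance) on per-gene standardized expression of the selected
#' panel, then names the cluster with the lower Kaplan-Meier survival at the
#' last event time shared by both groups `high_risk` (the log-rank p-value
#' does not depend on this labeling).
#'
#' @param expr patients x selected-genes matrix (>= 2 distinct rows).
#' @param time,event survival data used only to orient the risk labels.
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 20).
#' @return factor with levels `low_risk`, `high_risk`.
#' @export
kmeans2_risk_groups <- function(expr, time, event, seed = 1L, nstart = 20L) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 patients")
  if (nrow(unique(expr)) < 2)
    stop("degenerate grouping: fewer than 2 distinct expression profiles")
  sds <- apply(expr, 2, stats::sd)
  z <- sweep(expr, 2, colMeans(expr), "-")
  ok <- sds > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sds[ok], "/")
  set.seed(as.integer(seed) %% 2147483647L)
  km <- stats::kmeans(z, centers = 2, nstart = nstart)
  cl <- km$cluster

  surv_end <- function(g) {
    k <- km_estimate(time[cl == g], event[cl == g])
    k
  }
  k1 <- surv_end(1); k2 <- surv_end(2)
  last_event <- function(k) if (nrow(k)) max(k$time) else -Inf
  t_shared <- min(last_event(k1), last_event(k2))
  s1 <- km_survival_at(k1, t_shared); s2 <- km_survival_at(k2, t_shared)
  high <- if (s1 < s2) 1 else if (s2 < s1) 2 else
    which.max(c(mean(event[cl == 1]), mean(event[cl == 2])))
  factor(ifelse(cl == high, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Write a Kaplan-Meier comparison as TSV
#'
#' One row per (group, event time): `group`, `time`, `survival`, `at_risk`,
#' `events`; statistic and p-value in `#` header comments.
#'
#' @param cmp a [logrank_test()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_km_table <- function(cmp, path) {
  hdr <- c(sprintf("# logrank_chisq = %.10g", cmp$statistic),
           sprintf("# pvalue = %.10g", cmp$pvalue),
           paste(c("group", "time", "survival", "at_risk", "events"),
                 collapse = "\t"))
  body <- unlist(lapply(names(cmp$curves), function(g) {
    k <- cmp$curves[[g]]
    if (!nrow(k)) return(character(0))
    sprintf("%s\t%.10g\t%.10g\t%d\t%d", g, k$time, k$survival,
            as.integer(k$at_risk), as.integer(k$events))
  }))
  writeLines(c(hdr, body), path)
  invisible(path)
}
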