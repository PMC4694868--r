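#' Construct a patient cohort
#'
#' Bundles a patient-by-gene expression matrix with survival follow-up and
#' receptor status. `time` is survival/follow-up time (> 0, any consistent
#' unit), `event` is 1 for an observed event and 0 for censoring, and the
#' endpoint label (`"OS"` overall survival or `"DFS"` disease-free survival)
#' is metadata only -- the same computations apply to either.
#'
#' @param expr numeric matrix, patients x genes, with dimnames.
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param er_status,her2_status per-patient `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @param patient_ids unique ids (default from `rownames(expr)`).
#' @param endpoint `"OS"` or `"DFS"`.
#' @return object of class `Cohort`.
#' @export
cohort <- function(expr, time, event, er_status = "unknown",
                   her2_status = "unknown", patient_ids = rownames(expr),
                   endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  expr <- as.matrix(expr)
  n <- nrow(expr)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  er_status <- rep_len(as.character(er_status), n)
  her2_status <- rep_len(as.character(her2_status), n)
  levels_ok <- c("positive", "negative", "unknown")
  if (!all(er_status %in% levels_ok) || !all(her2_status %in% levels_ok))
    stop("receptor status must be 'positive', 'negative' or 'unknown'")
  if (length(time) != n || length(event) != n)
    stop("time/event length must match the number of patients")
  if (any(!is.finite(time) | time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  rownames(expr) <- patient_ids
  structure(list(patient_ids = as.character(patient_ids), expr = expr,
                 time = as.numeric(time), event = as.integer(event),
                 er_status = er_status, her2_status = her2_status,
                 endpoint = endpoint),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients x %d genes, endpoint %s\n",
              nrow(x$expr), ncol(x$expr), x$endpoint))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$event),
              100 * mean(x$event == 0)))
  cat(sprintf("  ER +/-/unk: %d/%d/%d;  HER2 +/-/unk: %d/%d/%d\n",
              sum(x$er_status == "positive"), sum(x$er_status == "negative"),
              sum(x$er_status == "unknown"), sum(x$her2_status == "positive"),
              sum(x$her2_status == "negative"), sum(x$her2_status == "unknown")))
  invisible(x)
}

#' Subset a cohort by receptor status
#'
#' Retains patients matching the requested ER and HER2 status; patients with
#' unknown status on a constrained axis are excluded (cohort tables report
#' "Unknown" separately, and such patients cannot be assigned to either
#' subgroup). `"any"` leaves an axis unconstrained.
#'
#' @param x a [cohort()].
#' @param er,her2 `"positive"`, `"negative"` or `"any"`.
#' @return the subset Cohort (a warning, not an error, when empty).
#' @export
subgroup <- function(x, er = "any", her2 = "any") {
  stopifnot(inherits(x, "Cohort"))
  er <- match.arg(er, c("any", "positive", "negative"))
  her2 <- match.arg(her2, c("any", "positive", "negative"))
  keep <- rep(TRUE, length(x$patient_ids))
  if (er != "any") keep <- keep & x$er_status == er
  if (her2 != "any") keep <- keep & x$her2_status == her2
  if (!any(keep)) warning("subgroup is empty")
  subset_cohort(x, which(keep))
}

subset_cohort <- function(x, idx) {
  structure(list(patient_ids = x$patient_ids[idx],
                 expr = x$expr[idx, , drop = FALSE],
                 time = x$time[idx], event = x$event[idx],
                 er_status = x$er_status[idx], her2_status = x$her2_status[idx],
                 endpoint = x$endpoint),
            class = "Cohort")
}

#' Read a cohort from clinical and expression files
#'
#' The clinical TSV has header `patient_id time event er_status her2_status
#' endpoint`; the expression TSV is a matrix with gene columns and a
#' `patient_id` first column (`orientation = "patients_by_genes"`), or
#' transposed with a `gene_id` first column.
#'
#' @param clinical_path,expr_path input files.
#' @param orientation matrix layout of `expr_path`.
#' @return a [cohort()].
#' @export
read_cohort <- function(clinical_path, expr_path,
                        orientation = c("patients_by_genes", "genes_by_patients")) {
  orientation <- match.arg(orientation)
  clin <- utils::read.table(clinical_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  em <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (orientation == "patients_by_genes") {
    ids <- em[[1]]
    expr <- as.matrix(em[, -1, drop = FALSE])
    rownames(expr) <- ids
  } else {
    genes <- em[[1]]
    expr <- t(as.matrix(em[, -1, drop = FALSE]))
    colnames(expr) <- genes
  }
  expr <- expr[match(clin$patient_id, rownames(expr)), , drop = FALSE]
  cohort(expr, time = clin$time, event = clin$event,
         er_status = clin$er_status, her2_status = clin$her2_status,
         patient_ids = clin$patient_id, endpoint = clin$endpoint[1])
}

#' Write a cohort to clinical and expression TSV files
#' @param x a [cohort()].
#' @param clinical_path,expr_path output files.
#' @return invisible list of the two paths.
#' @export
write_cohort <- function(x, clinical_path, expr_path) {
  clin <- data.frame(patient_id = x$patient_ids, time = x$time,
                     event = x$event, er_status = x$er_status,
                     her2_status = x$her2_status, endpoint = x$endpoint)
  utils::write.table(clin, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  em <- data.frame(patient_id = x$patient_ids,
                   as.data.frame(x$expr, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(em, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(clinical = clinical_path, expression = expr_path))
}
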