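#' Pipeline run configuration
#'
#' Collects every input and threshold of the discovery and survival stages.
#' Inputs may be file paths (read with the package's readers) or in-memory
#' objects. Threshold defaults are the reference analysis settings: peak FDR
#' 0.5%, change ratio 0.9, TSS window 20 kb, fold change 1.2, adjusted p
#' 0.05, Cox score 2.39. Thresholds are validated here, before any
#' computation.
#'
#' @param peaks_a,peaks_b resistant / responsive peak inputs (path or
#'   PeakSet).
#' @param genes gene table (path or data.frame).
#' @param de differential-expression table (path or data.frame); may be
#'   omitted when `expression` + `groups` are given instead.
#' @param expression,groups optional log2 expression matrix (genes x
#'   replicates; path to the TSV written by [write_fixtures()] or a matrix)
#'   and its two-level group labels (inferred from column-name prefixes when
#'   omitted).
#' @param clinical,cohort_expression cohort input files for the survival
#'   stage, or `cohort_obj` as an in-memory [cohort()].
#' @param cohort_obj optional in-memory cohort.
#' @param fdr_pct,min_ratio,window,min_fc,max_q,cox_cutoff stage thresholds.
#' @param include_unique,two_sided filter semantics (see
#'   [resistant_associated_sites()], [candidate_genes()]).
#' @param scale_to common read depth for intensity normalization.
#' @param subgroups list of receptor-status selections for the survival
#'   stage, each a named character vector with entries `er` and `her2`.
#' @param peak_dialect dialect of the peak files.
#' @param seed RNG seed (k-means restarts).
#' @param out_dir optional output directory; when set, result tables and the
#'   run report are written there.
#' @param verbose log stage progress to standard error.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(peaks_a = NULL, peaks_b = NULL, genes = NULL, de = NULL,
                       expression = NULL, groups = NULL, clinical = NULL,
                       cohort_expression = NULL, cohort_obj = NULL,
                       fdr_pct = 0.5, min_ratio = 0.9, window = 20000,
                       min_fc = 1.2, max_q = 0.05, cox_cutoff = 2.39,
                       include_unique = TRUE, two_sided = TRUE, scale_to = 1e7,
                       subgroups = list(c(er = "any", her2 = "any")),
                       peak_dialect = "macs_xls", seed = 1L, out_dir = NULL,
                       verbose = FALSE) {
  if (fdr_pct < 0 || fdr_pct > 100) stop("fdr_pct must be in [0, 100]")
  if (min_ratio <= 0) stop("min_ratio must be positive")
  if (window <= 0) stop("window must be positive")
  if (min_fc < 1) stop("min_fc must be >= 1")
  if (max_q <= 0 || max_q > 1) stop("max_q must be in (0, 1]")
  if (cox_cutoff < 0) stop("cox_cutoff must be non-negative")
  if (scale_to <= 0) stop("scale_to must be positive")
  structure(as.list(environment()), class = "RunConfig")
}

log_stage <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

resolve_peaks <- function(x, cfg) {
  if (inherits(x, "PeakSet")) return(x)
  if (is.character(x)) return(read_peaks(x, dialect = cfg$peak_dialect))
  stop("peak input must be a PeakSet or a file path")
}

resolve_genes <- function(x) {
  if (is.character(x)) read_gene_table(x) else validate_gene_table(x)
}

read_expression_matrix <- function(path) {
  em <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(em[, -1, drop = FALSE])
  rownames(m) <- em[[1]]
  m
}

resolve_de <- function(cfg) {
  if (!is.null(cfg$de)) {
    if (is.character(cfg$de)) return(read_de_table(cfg$de))
    return(as.data.frame(cfg$de))
  }
  if (is.null(cfg$expression))
    stop("config error: need either 'de' or 'expression'")
  expr <- if (is.character(cfg$expression))
    read_expression_matrix(cfg$expression) else as.matrix(cfg$expression)
  groups <- cfg$groups %||% sub("_[0-9]+$", "", colnames(expr))
  differential_expression(expr, groups)
}

resolve_cohort <- function(cfg) {
  if (!is.null(cfg$cohort_obj)) return(cfg$cohort_obj)
  if (is.null(cfg$clinical) || is.null(cfg$cohort_expression))
    stop("config error: need 'cohort_obj' or 'clinical' + 'cohort_expression'")
  read_cohort(cfg$clinical, cfg$cohort_expression)
}

#' Run the discovery stage of the pipeline
#'
#' Executes the binding-to-expression funnel: FDR-filter both peak sets,
#' depth-normalize, overlap, select resistant-associated sites by change
#' ratio, annotate genes within the TSS window, and intersect with the
#' differential-expression filters. The report records the record count
#' entering and leaving every stage, the thresholds used, and wall time.
#'
#' @param cfg a [run_config()] with discovery inputs set.
#' @return list: `candidates` ([candidate_genes()] result), `sites`
#'   (resistant-associated PeakSet), `annotation`, and `report` (class
#'   `RunReport`).
#' @export
run_discovery <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cfg$peaks_a) || is.null(cfg$peaks_b) || is.null(cfg$genes))
    stop("config error: peaks_a, peaks_b and genes are required")
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  mark <- function(stage, n_in, n_out) {
    t1 <- proc.time()[["elapsed"]]
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(t1 - get("t_prev", parent.frame()), 3))
    assign("t_prev", t1, parent.frame())
  }
  t_prev <- t0

  a_raw <- resolve_peaks(cfg$peaks_a, cfg)
  b_raw <- resolve_peaks(cfg$peaks_b, cfg)
  genes <- resolve_genes(cfg$genes)
  de <- resolve_de(cfg)
  log_stage(cfg, "inputs: %d + %d peaks, %d genes, %d DE records",
            nrow(a_raw$peaks), nrow(b_raw$peaks), nrow(genes), nrow(de))

  a <- filter_by_fdr(a_raw, cfg$fdr_pct)
  b <- filter_by_fdr(b_raw, cfg$fdr_pct)
  mark("fdr_filter", nrow(a_raw$peaks) + nrow(b_raw$peaks),
       nrow(a$peaks) + nrow(b$peaks))
  a <- normalize_intensities(a, cfg$scale_to)
  b <- normalize_intensities(b, cfg$scale_to)
  ov <- overlap_peaks(a, b)
  n_common_a <- length(unique(ov$pairs$a))
  mark("overlap", nrow(a$peaks), n_common_a)
  sites <- resistant_associated_sites(ov, cfg$min_ratio, cfg$include_unique)
  mark("change_ratio", n_common_a + length(ov$unique_a), nrow(sites$peaks))
  annot <- annotate_sites(sites, genes, cfg$window)
  genes_annotated <- length(unique(stats::na.omit(annot$gene_id)))
  mark("annotate", nrow(sites$peaks), genes_annotated)
  cand <- candidate_genes(annot, de, cfg$min_fc, cfg$max_q, cfg$two_sided)
  mark("expression_filter", genes_annotated, nrow(cand))
  log_stage(cfg, "funnel: %d resistant sites -> %d annotated genes -> %d candidates",
            nrow(sites$peaks), genes_annotated, nrow(cand))

  report <- structure(list(
    kind = "discovery",
    stages = do.call(rbind, stages),
    counts = list(peaks_a_raw = nrow(a_raw$peaks), peaks_b_raw = nrow(b_raw$peaks),
                  peaks_a_fdr = nrow(a$peaks), peaks_b_fdr = nrow(b$peaks),
                  common_a = n_common_a,
                  common_b = length(unique(ov$pairs$b)),
                  unique_a = length(ov$unique_a), unique_b = length(ov$unique_b),
                  resistant_sites = nrow(sites$peaks),
                  genes_annotated = genes_annotated,
                  genes_in_de = nrow(de), candidates = nrow(cand)),
    thresholds = cfg[c("fdr_pct", "min_ratio", "window", "min_fc", "max_q",
                       "include_unique", "two_sided", "scale_to")],
    version = as.character(utils::packageVersion("ertargets")),
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)),
    class = "RunReport")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_candidates(cand, file.path(cfg$out_dir, "candidates.tsv"),
                     file.path(cfg$out_dir, "candidate_gene_ids.txt"))
    write_sites_bed(sites, file.path(cfg$out_dir, "resistant_sites.bed"))
    write_annotation(annot, file.path(cfg$out_dir, "annotation.tsv"))
    write_report(report, cfg$out_dir)
  }
  list(candidates = cand, sites = sites, annotation = annot, report = report)
}

#' Run the survival stage of the pipeline
#'
#' For each requested receptor-status subgroup: screen the supplied genes by
#' absolute Cox score at the configured cutoff, run a median-split
#' Kaplan-Meier / log-rank comparison for every selected gene, and, when at
#' least two genes are selected, a 2-means panel risk stratification. Empty
#' subgroups and genes absent from the cohort are recorded, not fatal.
#'
#' @param cfg a [run_config()] with cohort inputs set.
#' @param genes character vector of gene ids to evaluate (e.g. the
#'   discovery-stage candidate list).
#' @return list: `results` (per-subgroup list with `selected`, per-gene
#'   `km` comparisons, optional `panel`), and `report` (class `RunReport`).
#' @export
run_survival <- function(cfg, genes) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!length(genes)) stop("config error: gene list is empty")
  t0 <- proc.time()[["elapsed"]]
  coh <- resolve_cohort(cfg)
  results <- list()
  summary_rows <- list()

  for (sg in cfg$subgroups) {
    er <- if (is.na(sg["er"])) "any" else unname(sg["er"])
    her2 <- if (is.na(sg["her2"])) "any" else unname(sg["her2"])
    label <- sprintf("ER%s_HER2%s", substr(er, 1, 3), substr(her2, 1, 3))
    sub <- suppressWarnings(subgroup(coh, er = er, her2 = her2))
    n_sub <- length(sub$patient_ids)
    log_stage(cfg, "subgroup %s: %d patients", label, n_sub)
    if (n_sub < 2 || sum(sub$event) == 0) {
      results[[label]] <- list(skipped = TRUE, n = n_sub)
      summary_rows[[label]] <- data.frame(subgroup = label, n = n_sub,
                                          gene = NA, score = NA, p = NA,
                                          note = "skipped")
      next
    }
    sel <- select_genes_by_cox(sub, genes, cutoff = cfg$cox_cutoff)
    kms <- lapply(sel$gene_id, function(g) single_gene_km(sub, g))
    names(kms) <- sel$gene_id
    panel <- NULL
    if (nrow(sel) >= 2) {
      grp <- kmeans2_risk_groups(sub$expr[, sel$gene_id, drop = FALSE],
                                 sub$time, sub$event, seed = cfg$seed)
      panel <- logrank_test(sub$time, sub$event, grp)
      attr(panel, "meta") <- sprintf("%d-gene panel, 2-means risk groups",
                                     nrow(sel))
    }
    results[[label]] <- list(skipped = FALSE, n = n_sub, selected = sel,
                             km = kms, panel = panel,
                             not_evaluated = attr(sel, "not_evaluated"))
    summary_rows[[label]] <- data.frame(
      subgroup = label, n = n_sub,
      gene = if (nrow(sel)) sel$gene_id else NA,
      score = if (nrow(sel)) sel$score else NA,
      p = if (nrow(sel)) vapply(kms, function(k) k$pvalue, numeric(1)) else NA,
      note = "")
  }

  report <- structure(list(
    kind = "survival",
    summary = do.call(rbind, summary_rows),
    counts = list(genes_requested = length(genes),
                  subgroups = length(cfg$subgroups)),
    thresholds = cfg["cox_cutoff"],
    version = as.character(utils::packageVersion("ertargets")),
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3)),
    class = "RunReport")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (label in names(results)) {
      r <- results[[label]]
      if (isTRUE(r$skipped)) next
      utils::write.table(r$selected,
                         file.path(cfg$out_dir, sprintf("cox_scores_%s.tsv", label)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (g in names(r$km))
        write_km_table(r$km[[g]],
                       file.path(cfg$out_dir, sprintf("km_%s_%s.tsv", label, g)))
      if (!is.null(r$panel))
        write_km_table(r$panel,
                       file.path(cfg$out_dir, sprintf("km_%s_panel.tsv", label)))
    }
    write_report(report, cfg$out_dir, prefix = "survival_report")
  }
  list(results = results, report = report)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (%s), ertargets %s, %.2fs\n", x$kind, x$version,
              x$total_seconds))
  if (!is.null(x$stages)) { cat("stages:\n"); print(x$stages) }
  if (!is.null(x$summary)) { cat("summary:\n"); print(x$summary) }
  cat("counts:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

write_report <- function(report, out_dir, prefix = "report") {
  jsonlite::write_json(
    list(kind = report$kind, counts = report$counts,
         thresholds = report$thresholds, version = report$version,
         stages = report$stages, summary = report$summary,
         total_seconds = report$total_seconds),
    file.path(out_dir, paste0(prefix, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null", force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, paste0(prefix, ".txt")))
  invisible(NULL)
}
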