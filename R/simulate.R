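#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' define the package's reference study conditions: a 3 x 50 Mb genome with
#' 500 genes, two peak sets with 300 common / 100 resistant-only / 60
#' responsive-only background sites, 10 planted candidate genes that pass
#' every discovery filter and 8 decoy genes per single-filter-failing class,
#' a 4-vs-4 replicate cell-line expression design (planted log2 fold change
#' 1.0, residual SD 0.15), and a 400-patient cohort with exponential
#' proportional hazards (baseline 0.1), independent exponential censoring at
#' rate 0.043 (about 30% censored), and receptor-status prevalences matching
#' a large ER+ breast-cancer cohort (73% ER+; HER2 +/-/unknown =
#' 0.155/0.557/0.288). The seed fully determines all outputs.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of annotated genes.
#' @param n_peaks_common,n_peaks_unique_a,n_peaks_unique_b background peak
#'   counts (condition A = resistant, B = responsive).
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model for
#'   depth-normalized intensities.
#' @param ratio_sdlog spread (SD of log ratio) of background common-peak A/B
#'   intensity ratios around 1.
#' @param ratio_noise measurement noise (SD of log ratio) around planted
#'   ratio targets.
#' @param tss_sigma SD (bp) of TSS-proximal summit placement.
#' @param fraction_tss_proximal fraction of background peaks anchored near a
#'   TSS rather than placed uniformly.
#' @param fdr_fail_rate fraction of background peaks drawn to fail the 0.5%
#'   peak FDR filter.
#' @param n_planted_candidates genes planted to pass all discovery filters.
#' @param n_decoys_per_class decoy genes per failing class (`fdr`, `ratio`,
#'   `window`, `fc`, `q`).
#' @param planted_ratio change ratio planted for candidate common peaks.
#' @param decoy_ratio change ratio planted for ratio-failing decoys.
#' @param de_log2fc,de_sigma,de_reps cell-line expression model: planted
#'   log2 fold change, residual SD, replicates per group.
#' @param cohort_n patients in the simulated cohort.
#' @param beta_map named numeric vector of log-hazard coefficients per SD of
#'   expression; `NULL` lets [simulate_study()] assign +/-0.6 to 5 of the
#'   planted candidates (3 positive, 2 negative).
#' @param baseline_hazard,weibull_shape event-time model (shape 1 =
#'   exponential).
#' @param censoring_rate rate of the independent exponential censoring time
#'   (0 disables censoring).
#' @param er_prevalence probability a patient is ER positive.
#' @param her2_prevalence,unknown_rate probability a patient is HER2
#'   positive / HER2 unknown (the remainder are HER2 negative).
#' @param library_size_a,library_size_b,scale_to sequencing depths and the
#'   common depth intensities are normalized to.
#' @param endpoint survival endpoint label.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_length = 5e7, n_genes = 500L,
                       n_peaks_common = 300L, n_peaks_unique_a = 100L,
                       n_peaks_unique_b = 60L,
                       intensity_meanlog = 3, intensity_sdlog = 0.5,
                       ratio_sdlog = 0.35, ratio_noise = 0.05,
                       tss_sigma = 1000, fraction_tss_proximal = 0.7,
                       fdr_fail_rate = 0.1,
                       n_planted_candidates = 10L, n_decoys_per_class = 8L,
                       planted_ratio = 2.0, decoy_ratio = 0.5,
                       de_log2fc = 1.0, de_sigma = 0.15, de_reps = 4L,
                       cohort_n = 400L, beta_map = NULL,
                       baseline_hazard = 0.1, weibull_shape = 1,
                       censoring_rate = 0.043,
                       er_prevalence = 0.73, her2_prevalence = 0.155,
                       unknown_rate = 0.288,
                       library_size_a = 2.4e7, library_size_b = 1.6e7,
                       scale_to = 1e7, endpoint = "OS") {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_peaks_common,
              cfg$n_peaks_unique_a, cfg$n_peaks_unique_b,
              cfg$n_planted_candidates, cfg$n_decoys_per_class, cfg$de_reps,
              cfg$cohort_n)
  if (any(counts < 0)) stop("counts must be non-negative")
  probs <- c(cfg$fraction_tss_proximal, cfg$fdr_fail_rate, cfg$er_prevalence,
             cfg$her2_prevalence, cfg$unknown_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$her2_prevalence + cfg$unknown_rate > 1)
    stop("her2_prevalence + unknown_rate must be <= 1")
  cfg$seed <- as.integer(seed) %% 2147483647L
  class(cfg) <- "sim_config"
  cfg
}

GENE_SPACING <- 50000

#' Generate a synthetic gene/TSS annotation table
#'
#' Genes are spread over the chromosomes on a 50 kb lattice (uniformly
#' sampled slots), guaranteeing at least 50 kb spacing between TSSs;
#' strands are Bernoulli(0.5). Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return gene annotation data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @export
make_genome <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  set.seed((cfg$seed + 1L) %% 2147483647L)
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  slots <- floor(cfg$chrom_length / GENE_SPACING) - 1L
  if (any(per_chrom > slots))
    stop("genome too small to place genes with ", GENE_SPACING, " bp spacing")
  out <- do.call(rbind, lapply(seq_len(cfg$n_chroms), function(ci) {
    k <- per_chrom[ci]
    if (!k) return(NULL)
    pos <- sort(sample.int(slots, k)) * GENE_SPACING - GENE_SPACING / 2
    data.frame(chrom = sprintf("chr%d", ci), tss = pos,
               stringsAsFactors = FALSE)
  }))
  data.frame(gene_id = sprintf("G%04d", seq_len(nrow(out))),
             chrom = out$chrom,
             strand = sample(c("+", "-"), nrow(out), replace = TRUE),
             tss = out$tss, stringsAsFactors = FALSE)
}

## interval placer that protects the planted common/unique classification:
## a peak must not overlap peaks of any OTHER class (a unique-A peak touching
## any B-side interval, or vice versa, would be re-classified as common by
## overlap analysis). Same-class overlaps are harmless and allowed, so
## TSS-proximal peaks can pile up around start sites.
new_placer <- function(chrom_length) {
  occupied <- list()  # [[class]][[chrom]] -> 2-column matrix of intervals
  place <- function(chrom, start, width, class) {
    start <- max(0, min(start, chrom_length - width - 1))
    others <- setdiff(names(occupied), class)
    avoid <- do.call(rbind, lapply(others, function(cl) occupied[[cl]][[chrom]]))
    repeat {
      end <- start + width
      clash <- !is.null(avoid) &&
        any(avoid[, 1] < end + 10 & avoid[, 2] + 10 > start)
      if (!clash) break
      start <- (start + 800) %% (chrom_length - width - 1)
    }
    if (is.null(occupied[[class]])) occupied[[class]] <<- list()
    occupied[[class]][[chrom]] <<- rbind(occupied[[class]][[chrom]],
                                         c(start, start + width))
    start
  }
  place
}

#' Simulate a pair of ChIP-seq peak sets with planted structure
#'
#' Generates background peaks in three classes -- common to both conditions
#' (identical locations, intensity ratio drawn log-normally around 1),
#' unique to the resistant condition A, and unique to the responsive
#' condition B -- plus optional role-driven peaks anchored at specific genes
#' (used by [simulate_study()] to plant candidates and decoys). A fraction
#' of background summits is drawn Normal(TSS, `tss_sigma`) around gene TSSs,
#' the rest uniformly; peaks are kept mutually non-overlapping so that the
#' recorded class is exactly what [overlap_peaks()] recovers. A configurable
#' fraction of background peaks is drawn to fail the 0.5% FDR filter.
#' Intensities are drawn on the depth-normalized scale and then scaled to
#' each library's raw depth, so pipelines must re-normalize.
#'
#' @param cfg a [sim_config()].
#' @param genes gene table from [make_genome()].
#' @param roles optional data.frame (`gene_id`, `role`) with roles among
#'   `candidate_common`, `candidate_unique`, `decoy_fdr`, `decoy_ratio`,
#'   `decoy_window`, `decoy_fc`, `decoy_q`.
#' @return list with PeakSets `a`, `b` and a `truth` data.frame (one row per
#'   planted site: class, coordinates, planted ratio, FDR, role, anchor
#'   gene, row indices `idx_a`/`idx_b` into the two sets).
#' @export
simulate_peaks <- function(cfg, genes, roles = NULL) {
  set.seed((cfg$seed + 2L) %% 2147483647L)
  genes <- validate_gene_table(genes)
  place <- new_placer(cfg$chrom_length)
  rows <- list()

  add_row <- function(class, chrom, summit, width, ratio_true, fdr, role, gene_id) {
    start <- place(chrom, round(summit - width / 2), width, class)
    summit <- start + floor(width / 2)
    rows[[length(rows) + 1]] <<- data.frame(
      class = class, chrom = chrom, start = start, end = start + width,
      summit = summit, ratio_true = ratio_true, fdr = fdr, role = role,
      gene_id = gene_id, stringsAsFactors = FALSE)
  }

  ## role-driven peaks first: they own their gene's neighbourhood
  if (!is.null(roles) && nrow(roles)) {
    for (i in seq_len(nrow(roles))) {
      g <- genes[genes$gene_id == roles$gene_id[i], ]
      role <- roles$role[i]
      w <- sample(400:800, 1)
      anchor <- switch(role, decoy_window = g$tss + 24000,
                       g$tss + round(stats::rnorm(1, 0, min(cfg$tss_sigma, 500))))
      cls <- switch(role, candidate_unique = "unique_a", "common")
      ratio <- switch(role,
                      candidate_unique = NA_real_,
                      decoy_ratio = cfg$decoy_ratio,
                      cfg$planted_ratio)
      fdr <- if (role == "decoy_fdr") 2.5 else 0.1
      add_row(cls, g$chrom, anchor, w, ratio, fdr, role, g$gene_id)
    }
  }

  ## background peaks stay clear of role genes' annotation windows so the
  ## planted single-filter-failure classes stay exactly that
  role_genes <- if (is.null(roles)) character(0) else roles$gene_id
  anchor_pool <- which(!genes$gene_id %in% role_genes)
  if (!length(anchor_pool)) anchor_pool <- seq_len(nrow(genes))
  near_role_tss <- function(chrom, summit) {
    sel <- genes$gene_id %in% role_genes & genes$chrom == chrom
    any(abs(genes$tss[sel] - summit) <= 30000)
  }
  bg_summit <- function() {
    for (try in 1:100) {
      if (stats::runif(1) < cfg$fraction_tss_proximal) {
        gi <- anchor_pool[sample.int(length(anchor_pool), 1)]
        cand <- list(chrom = genes$chrom[gi],
                     summit = genes$tss[gi] + round(stats::rnorm(1, 0, cfg$tss_sigma)))
      } else {
        cand <- list(chrom = sprintf("chr%d", sample.int(cfg$n_chroms, 1)),
                     summit = round(stats::runif(1, 1000, cfg$chrom_length - 1000)))
      }
      if (!near_role_tss(cand$chrom, cand$summit)) return(cand)
    }
    cand
  }
  bg_fdr <- function(n)
    round(ifelse(stats::runif(n) < cfg$fdr_fail_rate,
                 stats::runif(n, 0.6, 5), stats::runif(n, 0, 0.5)), 4)

  bg_class <- rep(c("common", "unique_a", "unique_b"),
                  c(cfg$n_peaks_common, cfg$n_peaks_unique_a, cfg$n_peaks_unique_b))
  fdrs <- bg_fdr(length(bg_class))
  for (i in seq_along(bg_class)) {
    loc <- bg_summit()
    ratio <- if (bg_class[i] == "common")
      round(stats::rlnorm(1, 0, cfg$ratio_sdlog), 6) else NA_real_
    add_row(bg_class[i], loc$chrom, loc$summit, sample(300:800, 1),
            ratio, fdrs[i], "background", NA_character_)
  }

  truth <- do.call(rbind, rows)
  n <- nrow(truth)
  in_a <- truth$class %in% c("common", "unique_a")
  in_b <- truth$class %in% c("common", "unique_b")
  ## depth-normalized intensities, then scaled to raw library depth
  base_b <- stats::rlnorm(n, cfg$intensity_meanlog, cfg$intensity_sdlog)
  meas_ratio <- truth$ratio_true * exp(stats::rnorm(n, 0, cfg$ratio_noise))
  int_a_norm <- ifelse(truth$class == "common", base_b * meas_ratio,
                       stats::rlnorm(n, cfg$intensity_meanlog, cfg$intensity_sdlog))
  int_b_norm <- base_b
  pval <- signif(10^(-stats::runif(n, 5, 12)), 6)

  mk_set <- function(sel, int_norm, lib, condition) {
    t2 <- truth[sel, , drop = FALSE]
    peak_set(data.frame(chrom = t2$chrom, start = t2$start, end = t2$end,
                        summit = t2$summit,
                        intensity = round(int_norm[sel] * lib / cfg$scale_to, 3),
                        pvalue = pval[sel], fdr_pct = t2$fdr),
             condition = condition, library_size = lib)
  }
  a <- mk_set(in_a, int_a_norm, cfg$library_size_a, "resistant")
  b <- mk_set(in_b, int_b_norm, cfg$library_size_b, "responsive")
  truth$idx_a <- NA_integer_; truth$idx_b <- NA_integer_
  truth$idx_a[in_a] <- seq_len(sum(in_a))
  truth$idx_b[in_b] <- seq_len(sum(in_b))
  rownames(truth) <- NULL
  list(a = a, b = b, truth = truth)
}

#' Simulate cell-line log2 expression with planted fold changes
#'
#' Two groups (`resistant` first, `responsive` second) of `de_reps`
#' replicates per gene. Non-planted genes share a gene-level baseline drawn
#' uniformly on [4, 10] with Normal residuals; planted genes shift the
#' resistant group by their planted log2 fold change. Per-gene residual SDs
#' can be overridden (used to plant fold-change-failing decoys that still
#' reach significance).
#'
#' @param cfg a [sim_config()].
#' @param genes gene table or character vector of gene ids.
#' @param planted named numeric vector of planted log2 fold changes (or a
#'   character vector of gene ids, all planted at `cfg$de_log2fc`).
#' @param sigma_override optional named numeric vector of per-gene residual
#'   SDs.
#' @return list: `expr` (genes x replicates log2 matrix), `groups`
#'   (column labels), `truth` (`gene_id`, `true_log2fc`, `sigma`).
#' @export
simulate_cellline_expression <- function(cfg, genes, planted = numeric(0),
                                         sigma_override = NULL) {
  set.seed((cfg$seed + 3L) %% 2147483647L)
  if (cfg$de_reps < 2) stop("de_reps must be >= 2")
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  if (is.character(planted))
    planted <- stats::setNames(rep(cfg$de_log2fc, length(planted)), planted)
  lfc <- stats::setNames(rep(0, length(ids)), ids)
  lfc[names(planted)] <- planted
  sigma <- stats::setNames(rep(cfg$de_sigma, length(ids)), ids)
  if (!is.null(sigma_override)) sigma[names(sigma_override)] <- sigma_override

  nrep <- cfg$de_reps
  groups <- rep(c("resistant", "responsive"), each = nrep)
  mu <- stats::runif(length(ids), 4, 10)
  shift <- outer(lfc, as.numeric(groups == "resistant"))
  expr <- round(mu + shift +
                  matrix(stats::rnorm(length(ids) * 2 * nrep, 0, sigma),
                         nrow = length(ids)), 6)
  dimnames(expr) <- list(ids, paste(groups, rep(seq_len(nrep), 2), sep = "_"))
  list(expr = expr, groups = groups,
       truth = data.frame(gene_id = ids, true_log2fc = unname(lfc),
                          sigma = unname(sigma), stringsAsFactors = FALSE))
}

#' Simulate a survival cohort under proportional hazards
#'
#' Patient-by-gene expression is standard normal on the log scale. Event
#' times follow a Weibull (default exponential) proportional-hazards model
#' `h(t) = baseline_hazard * shape * t^(shape-1) * exp(sum_g beta_g z_g)`
#' with `z_g` the cohort-standardized expression of each planted gene;
#' censoring times are independent exponentials at `censoring_rate`. ER and
#' HER2 statuses are drawn at the configured prevalences, independent of
#' survival; HER2 can be `unknown` to exercise subgroup exclusion.
#'
#' @param cfg a [sim_config()].
#' @param genes gene table or character vector of gene ids.
#' @param beta_map named numeric vector of per-SD log-hazard coefficients
#'   (default `cfg$beta_map`; empty means a null cohort).
#' @return list: `cohort` (a [cohort()]) and `truth` (`beta` vector,
#'   planted prevalences, realized censoring fraction).
#' @export
simulate_cohort <- function(cfg, genes, beta_map = cfg$beta_map) {
  set.seed((cfg$seed + 4L) %% 2147483647L)
  if (cfg$cohort_n < 2) stop("cohort_n must be >= 2")
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  n <- cfg$cohort_n
  expr <- matrix(round(stats::rnorm(n * length(ids)), 6), nrow = n,
                 dimnames = list(sprintf("P%04d", seq_len(n)), ids))
  lp <- rep(0, n)
  if (length(beta_map)) {
    bad <- setdiff(names(beta_map), ids)
    if (length(bad)) stop("beta_map genes not in gene table: ",
                          paste(bad, collapse = ", "))
    z <- scale(expr[, names(beta_map), drop = FALSE])
    lp <- as.numeric(z %*% beta_map)
  }
  e <- stats::rexp(n)
  t_event <- (e / (cfg$baseline_hazard * exp(lp)))^(1 / cfg$weibull_shape)
  t_cens <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate)
            else rep(Inf, n)
  event <- as.integer(t_event <= t_cens)
  time <- round(pmin(t_event, t_cens), 6)
  time <- pmax(time, 1e-6)

  er <- ifelse(stats::runif(n) < cfg$er_prevalence, "positive", "negative")
  u <- stats::runif(n)
  her2 <- ifelse(u < cfg$her2_prevalence, "positive",
                 ifelse(u < cfg$her2_prevalence + cfg$unknown_rate,
                        "unknown", "negative"))
  ch <- cohort(expr, time = time, event = event, er_status = er,
               her2_status = her2, endpoint = cfg$endpoint)
  list(cohort = ch,
       truth = list(beta = beta_map,
                    censoring_fraction = mean(event == 0),
                    er_positive = sum(er == "positive"),
                    her2_counts = table(factor(her2, c("positive", "negative",
                                                       "unknown")))))
}

#' Simulate a complete study with planted ground truth
#'
#' Orchestrates the whole generator: a genome, two peak sets in which
#' `n_planted_candidates` genes carry resistant-persistent binding (half via
#' common peaks at change ratio `planted_ratio`, half via resistant-only
#' peaks) and each decoy class fails exactly one discovery filter (peak FDR,
#' change ratio, TSS window, fold change, adjusted p), a cell-line
#' expression matrix in which candidates (and binding-stage decoys) are
#' differentially expressed, and a patient cohort in which a subset of
#' candidates is prognostic (3 hazardous, 2 protective at |beta| = 0.6/SD
#' unless `cfg$beta_map` overrides).
#'
#' @param cfg a [sim_config()].
#' @return list of class `er_simulation`: `config`, `genes`, `peaks_a`,
#'   `peaks_b`, `peak_truth`, `expr`, `groups`, `expr_truth`, `cohort`,
#'   `cohort_truth`, `gene_truth` (per-gene role, planted log2 fold change,
#'   beta).
#' @export
simulate_study <- function(cfg = sim_config()) {
  genes <- make_genome(cfg)
  set.seed((cfg$seed + 5L) %% 2147483647L)
  classes <- c("decoy_fdr", "decoy_ratio", "decoy_window", "decoy_fc", "decoy_q")
  n_roles <- cfg$n_planted_candidates + length(classes) * cfg$n_decoys_per_class
  if (n_roles > nrow(genes)) stop("not enough genes for the requested roles")
  picked <- sample(genes$gene_id, n_roles)
  cand <- utils::head(picked, cfg$n_planted_candidates)
  cand_role <- rep(c("candidate_common", "candidate_unique"),
                   length.out = length(cand))
  decoys <- utils::tail(picked, length(classes) * cfg$n_decoys_per_class)
  roles <- data.frame(
    gene_id = c(cand, decoys),
    role = c(cand_role, rep(classes, each = cfg$n_decoys_per_class)),
    stringsAsFactors = FALSE)

  pk <- simulate_peaks(cfg, genes, roles)

  ## expression: candidates and binding-stage decoys are truly DE; decoy_fc
  ## shifts only 1.1-fold (tight residuals so it fails ONLY the fc filter);
  ## decoy_q stays null.
  de_genes <- roles$gene_id[roles$role %in% c("candidate_common",
                                              "candidate_unique", "decoy_fdr",
                                              "decoy_ratio", "decoy_window")]
  fc_genes <- roles$gene_id[roles$role == "decoy_fc"]
  planted <- c(stats::setNames(rep(cfg$de_log2fc, length(de_genes)), de_genes),
               stats::setNames(rep(log2(1.1), length(fc_genes)), fc_genes))
  sim_expr <- simulate_cellline_expression(
    cfg, genes, planted,
    sigma_override = stats::setNames(rep(0.02, length(fc_genes)), fc_genes))

  beta_map <- cfg$beta_map
  if (is.null(beta_map)) {
    k <- min(5L, length(cand))
    beta_map <- stats::setNames(
      c(0.6, 0.6, 0.6, -0.6, -0.6)[seq_len(k)], utils::head(cand, k))
  }
  sim_coh <- simulate_cohort(cfg, genes, beta_map)

  gene_truth <- data.frame(gene_id = genes$gene_id, role = "background",
                           stringsAsFactors = FALSE)
  gene_truth$role[match(roles$gene_id, gene_truth$gene_id)] <- roles$role
  gene_truth$true_log2fc <- sim_expr$truth$true_log2fc[
    match(gene_truth$gene_id, sim_expr$truth$gene_id)]
  gene_truth$beta <- 0
  gene_truth$beta[match(names(beta_map), gene_truth$gene_id)] <- beta_map

  structure(list(config = cfg, genes = genes,
                 peaks_a = pk$a, peaks_b = pk$b, peak_truth = pk$truth,
                 expr = sim_expr$expr, groups = sim_expr$groups,
                 expr_truth = sim_expr$truth,
                 cohort = sim_coh$cohort, cohort_truth = sim_coh$truth,
                 gene_truth = gene_truth),
            class = "er_simulation")
}

#' @export
print.er_simulation <- function(x, ...) {
  cat(sprintf("er_simulation (seed %d): %d genes, %d + %d peaks, %d patients\n",
              x$config$seed, nrow(x$genes), nrow(x$peaks_a$peaks),
              nrow(x$peaks_b$peaks), length(x$cohort$patient_ids)))
  cat("  gene roles:\n")
  print(table(x$gene_truth$role))
  invisible(x)
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Emits every data product in the exact dialects the reader operations
#' accept (MACS-style peak tables, TSV gene/expression/clinical files), plus
#' the per-gene and per-peak truth tables and the configuration as a flat
#' key = value record. Two runs from the same seed produce byte-identical
#' directories.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return data.frame manifest (`file`, `rows`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  write_peaks(sim$peaks_a, pth("peaks_resistant.xls"), "macs_xls")
  write_peaks(sim$peaks_b, pth("peaks_responsive.xls"), "macs_xls")
  write_gene_table(sim$genes, pth("genes.tsv"))
  em <- data.frame(gene_id = rownames(sim$expr),
                   as.data.frame(sim$expr, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(em, pth("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_cohort(sim$cohort, pth("clinical.tsv"), pth("cohort_expression.tsv"))
  utils::write.table(sim$gene_truth, pth("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$peak_truth, pth("truth_peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  keys <- setdiff(names(cfg), "beta_map")
  writeLines(c(sprintf("%s = %s", keys,
                       vapply(cfg[keys], function(v) paste(format(v), collapse = ","),
                              character(1))),
               if (length(cfg$beta_map) || !is.null(cfg$beta_map))
                 sprintf("beta_map = %s",
                         paste(sprintf("%s:%g", names(cfg$beta_map), cfg$beta_map),
                               collapse = ","))),
             pth("config.txt"))
  files <- c("peaks_resistant.xls", "peaks_responsive.xls", "genes.tsv",
             "expression.tsv", "clinical.tsv", "cohort_expression.tsv",
             "truth_genes.tsv", "truth_peaks.tsv", "config.txt")
  rows <- c(nrow(sim$peaks_a$peaks), nrow(sim$peaks_b$peaks), nrow(sim$genes),
            nrow(sim$expr), length(sim$cohort$patient_ids),
            length(sim$cohort$patient_ids), nrow(sim$gene_truth),
            nrow(sim$peak_truth), NA_integer_)
  manifest <- data.frame(file = files, rows = rows)
  utils::write.table(manifest, pth("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
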