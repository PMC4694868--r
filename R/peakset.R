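#' Construct a PeakSet
#'
#' A `PeakSet` holds called ChIP-seq binding sites for one condition, the
#' sequencing library size used for depth normalization, and a flag saying
#' whether intensities have already been normalized. Coordinates are 0-based,
#' half-open (`[start, end)`), the convention used throughout the package.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `intensity`, `pvalue`, `fdr_pct`. `summit` must lie in `[start, end)`,
#'   `intensity >= 0`, `fdr_pct` in `[0, 100]`.
#' @param condition label for the biological condition (e.g. `"LTEDaro_DMSO"`).
#' @param library_size positive total mapped-read count for the library.
#' @param normalized logical; `TRUE` once [normalize_intensities()] has run.
#' @param scale_to read depth intensities were scaled to (NA when raw).
#' @return an object of class `PeakSet`.
#' @export
peak_set <- function(peaks, condition = "unknown", library_size = 1e7,
                     normalized = FALSE, scale_to = NA_real_) {
  required <- c("chrom", "start", "end", "summit", "intensity", "pvalue", "fdr_pct")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols))
    stop("peaks is missing columns: ", paste(missing_cols, collapse = ", "))
  peaks <- as.data.frame(peaks)[required]
  peaks$chrom <- as.character(peaks$chrom)
  for (col in required[-1]) peaks[[col]] <- as.numeric(peaks[[col]])
  if (nrow(peaks)) {
    if (any(peaks$end <= peaks$start))
      stop("invalid interval: end <= start at row ",
           which(peaks$end <= peaks$start)[1])
    if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end))
      stop("summit outside [start, end) at row ",
           which(peaks$summit < peaks$start | peaks$summit >= peaks$end)[1])
    if (any(peaks$intensity < 0)) stop("negative intensity")
    if (any(peaks$fdr_pct < 0 | peaks$fdr_pct > 100))
      stop("fdr_pct must be in [0, 100]")
  }
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0)
    stop("library_size must be a single positive number")
  rownames(peaks) <- NULL
  structure(
    list(peaks = peaks, condition = as.character(condition),
         library_size = as.numeric(library_size),
         normalized = isTRUE(normalized), scale_to = as.numeric(scale_to)),
    class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks, condition '%s'\n", nrow(x$peaks), x$condition))
  cat(sprintf("  library size %g; intensities %s\n", x$library_size,
              if (x$normalized) sprintf("normalized to %g reads", x$scale_to)
              else "raw"))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$peaks)

## subset of a PeakSet by row index, preserving metadata
subset_peakset <- function(ps, idx) {
  out <- ps
  out$peaks <- ps$peaks[idx, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      meta[[key]] <- val
    }
  }
  meta
}

num_or_stop <- function(x, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop(sprintf("parse error at line %d: non-numeric %s '%s'",
                 lineno, what, x[is.na(v)][1]))
  v
}

#' Read a peak-call table
#'
#' Reads called peaks from either a BED file (3--6 columns, 0-based
#' half-open; column 5, when present, is taken as the intensity) or a
#' MACS-style tab-delimited table with a header row
#' (`chr  start  end  summit  tags  pvalue  fdr_pct`), whose 1-based
#' inclusive `start` and `summit` are shifted to the internal 0-based
#' convention on read. Leading `#` comment lines of the form `key = value`
#' may carry `condition` and `library_size` metadata; explicit arguments
#' override them. When a summit column is absent the interval midpoint is
#' used.
#'
#' @param path file to read.
#' @param dialect `"bed"` or `"macs_xls"`.
#' @param condition,library_size optional overrides for file metadata.
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("bed", "macs_xls"),
                       condition = NULL, library_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^#", lines) | grepl("^(track|browser)\\b", lines)
  meta <- parse_meta_comments(lines[grepl("^#", lines)])
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (dialect == "macs_xls" && length(body_idx)) body_idx <- body_idx[-1] # header row
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)

  n <- length(rows)
  chrom <- character(n); start <- end <- summit <- numeric(n)
  intensity <- numeric(n); pvalue <- rep(1, n); fdr <- numeric(n)
  for (i in seq_len(n)) {
    f <- rows[[i]]; lineno <- body_idx[i]
    if (dialect == "bed") {
      if (length(f) < 3)
        stop(sprintf("parse error at line %d: expected >= 3 BED fields, got %d",
                     lineno, length(f)))
      chrom[i] <- f[1]
      start[i] <- num_or_stop(f[2], lineno, "start")
      end[i]   <- num_or_stop(f[3], lineno, "end")
      summit[i] <- floor((start[i] + end[i]) / 2)
      intensity[i] <- if (length(f) >= 5) num_or_stop(f[5], lineno, "score") else 0
    } else {
      if (length(f) < 7)
        stop(sprintf("parse error at line %d: expected 7 fields, got %d",
                     lineno, length(f)))
      chrom[i] <- f[1]
      start[i] <- num_or_stop(f[2], lineno, "start") - 1  # 1-based inclusive -> 0-based
      end[i]   <- num_or_stop(f[3], lineno, "end")
      summit[i] <- num_or_stop(f[4], lineno, "summit") - 1
      intensity[i] <- num_or_stop(f[5], lineno, "tags")
      pvalue[i] <- num_or_stop(f[6], lineno, "pvalue")
      fdr[i] <- num_or_stop(f[7], lineno, "fdr")
    }
    if (end[i] <= start[i])
      stop(sprintf("validation error at line %d: end <= start", lineno))
  }
  peak_set(data.frame(chrom = chrom, start = start, end = end, summit = summit,
                      intensity = intensity, pvalue = pvalue, fdr_pct = fdr),
           condition = condition %||% meta$condition %||% "unknown",
           library_size = as.numeric(library_size %||% meta$library_size %||% 1e7))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a PeakSet to disk
#'
#' Writes the MACS-style dialect accepted by [read_peaks()] (1-based
#' inclusive start/summit), with `# condition` and `# library_size`
#' metadata comments so a write/read cycle is lossless; or BED6 with the
#' intensity in the score column.
#'
#' @param ps a PeakSet.
#' @param path output file.
#' @param dialect `"macs_xls"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(ps, path, dialect = c("macs_xls", "bed")) {
  dialect <- match.arg(dialect)
  p <- ps$peaks
  if (dialect == "macs_xls") {
    hdr <- c(sprintf("# condition = %s", ps$condition),
             sprintf("# library_size = %.10g", ps$library_size),
             paste(c("chr", "start", "end", "summit", "tags", "pvalue", "fdr_pct"),
                   collapse = "\t"))
    body <- sprintf("%s\t%d\t%d\t%d\t%.10g\t%.10g\t%.10g",
                    p$chrom, as.integer(p$start) + 1L, as.integer(p$end),
                    as.integer(p$summit) + 1L, p$intensity, p$pvalue, p$fdr_pct)
  } else {
    hdr <- character(0)
    body <- sprintf("%s\t%d\t%d\t%s\t%.10g\t.", p$chrom, as.integer(p$start),
                    as.integer(p$end), sprintf("peak_%d", seq_len(nrow(p))),
                    p$intensity)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter peaks by false-discovery rate
#'
#' Retains exactly the peaks whose FDR (percent scale) is less than or equal
#' to the cutoff; order is preserved. The discovery pipeline applies this at
#' 0.5% to both conditions before any comparison.
#'
#' @param ps a PeakSet.
#' @param max_fdr_pct inclusive cutoff, percent, in `[0, 100]`.
#' @return the filtered PeakSet.
#' @export
filter_by_fdr <- function(ps, max_fdr_pct = 0.5) {
  stopifnot(inherits(ps, "PeakSet"))
  if (!is.numeric(max_fdr_pct) || length(max_fdr_pct) != 1 ||
      is.na(max_fdr_pct) || max_fdr_pct < 0 || max_fdr_pct > 100)
    stop("max_fdr_pct must be a single value in [0, 100]")
  subset_peakset(ps, which(ps$peaks$fdr_pct <= max_fdr_pct))
}

#' Normalize peak intensities to a common read depth
#'
#' Scales every intensity by `scale_to / library_size` so that peak sets
#' from libraries of different depth are comparable; intensity ratios
#' between conditions are then ratios of depth-normalized signal. A second
#' normalization of the same set is refused.
#'
#' @param ps a PeakSet with raw intensities.
#' @param scale_to target read depth (default 1e7).
#' @return the normalized PeakSet (`normalized = TRUE`).
#' @export
normalize_intensities <- function(ps, scale_to = 1e7) {
  stopifnot(inherits(ps, "PeakSet"))
  if (ps$normalized) stop("PeakSet is already normalized")
  if (!is.numeric(scale_to) || length(scale_to) != 1 || scale_to <= 0)
    stop("scale_to must be a single positive number")
  ps$peaks$intensity <- ps$peaks$intensity * (scale_to / ps$library_size)
  ps$normalized <- TRUE
  ps$scale_to <- scale_to
  ps
}

#' Read a gene/TSS annotation table
#'
#' Tab-delimited with header `gene_id  chrom  strand  tss` (TSS 0-based).
#'
#' @param path file to read.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  validate_gene_table(g)
}

validate_gene_table <- function(genes) {
  required <- c("gene_id", "chrom", "strand", "tss")
  if (!all(required %in% names(genes)))
    stop("gene table needs columns: ", paste(required, collapse = ", "))
  genes <- as.data.frame(genes)[required]
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  genes$tss <- as.numeric(genes$tss)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  rownames(genes) <- NULL
  genes
}

#' Write a gene/TSS table
#' @param genes gene annotation data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(validate_gene_table(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
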