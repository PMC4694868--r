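IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", V = "B", D = "H", H = "D")

#' Reverse-complement a nucleotide string
#' @param seq string over `A C G T N` (IUPAC codes allowed).
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "")[[1]])
  paste(COMPLEMENT[ch], collapse = "")
}

## mismatch counts of a consensus against every window of a character vector
consensus_mismatches <- function(seq_chars, consensus_chars) {
  n <- length(seq_chars); m <- length(consensus_chars)
  n_win <- n - m + 1
  if (n_win < 1) return(integer(0))
  mm <- integer(n_win)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[consensus_chars[j]]]
    obs <- seq_chars[j:(j + n_win - 1)]
    # an N in the observed sequence never counts as a match
    mm <- mm + as.integer(!(obs %in% allowed) | obs == "N")
  }
  mm
}

#' Scan a sequence for a consensus motif with mismatches
#'
#' Slides an IUPAC consensus (default the palindromic estrogen response
#' element core `GGTCANNNTGACC`) over both strands of a sequence and reports
#' every window with at most `max_mismatch` mismatches. An `N` in the
#' scanned sequence always counts as a mismatch. Reverse-strand hits are
#' reported at the 0-based offset of the matching window on the forward
#' sequence.
#'
#' @param seq nucleotide string over `A C G T N`.
#' @param consensus IUPAC consensus string.
#' @param max_mismatch maximum mismatches allowed (default 0).
#' @param sequence_name label copied into the output.
#' @return data.frame `sequence_name`, `offset`, `strand`, `mismatches`;
#'   zero rows when the consensus is longer than the sequence.
#' @export
scan_ere <- function(seq, consensus = "GGTCANNNTGACC", max_mismatch = 0,
                     sequence_name = "seq") {
  seq_chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(seq_chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence may only contain A, C, G, T, N")
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (!all(cons %in% names(IUPAC_SETS))) stop("invalid IUPAC code in consensus")
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")

  hit_rows <- function(mm, strand) {
    off <- which(mm <= max_mismatch)
    data.frame(sequence_name = rep(sequence_name, length(off)),
               offset = off - 1L, strand = rep(strand, length(off)),
               mismatches = mm[off], stringsAsFactors = FALSE)
  }
  rc_cons <- strsplit(revcomp(paste(cons, collapse = "")), "")[[1]]
  out <- rbind(hit_rows(consensus_mismatches(seq_chars, cons), "+"),
               hit_rows(consensus_mismatches(seq_chars, rc_cons), "-"))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
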