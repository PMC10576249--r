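#' Overlap-align two nucleotide sequences
#'
#' Best end-gap-free (semi-global) placement of the shorter sequence
#' within the longer: the longer sequence's unaligned overhangs are free,
#' while within the aligned overlap substitutions and internal gaps each
#' count as one mismatch. The optimum minimizes the mismatch count and,
#' among co-optimal alignments, maximizes the number of matching columns,
#' which makes the reported overlap length, mismatch count and percent
#' identity unique. Identity is computed over the aligned overlap:
#' `identity_pct = 100 * (overlap_bp - mismatches) / overlap_bp`.
#'
#' Ambiguous bases (N and other non-ACGT symbols) are accepted on input but
#' never match anything, a conservative choice that pushes uncertain
#' sequences toward "no match".
#'
#' @param query query nucleotide string (e.g. a 145 bp amplicon variant).
#' @param reference reference nucleotide string (e.g. a full-length barcode).
#' @param min_overlap_bp minimum usable overlap; shorter overlaps are
#'   returned but marked `coverage_failed` rather than dropped.
#' @return an object of class `match_hit`: a list with `identity_pct`,
#'   `overlap_bp`, `mismatches`, `coverage_frac` (overlap / query length),
#'   `coverage_failed`, `mismatch_positions` (0-based offsets in the aligned
#'   overlap), and the aligned strings `query_aln` / `reference_aln`.
#' @export
#' @examples
#' a <- paste(rep("ACGT", 10), collapse = "")
#' overlap_align(a, paste0("GGGGG", a, "CCCCC"))$identity_pct # 100
overlap_align <- function(query, reference, min_overlap_bp = 140L) {
  stopifnot(is.character(query), length(query) == 1L, nzchar(query),
            is.character(reference), length(reference) == 1L, nzchar(reference))
  res <- overlap_align_cpp(query, reference)
  hit <- list(
    identity_pct = res$identity_pct,
    overlap_bp = res$overlap_bp,
    mismatches = res$mismatches,
    coverage_frac = res$overlap_bp / nchar(query),
    coverage_failed = res$overlap_bp < min_overlap_bp,
    mismatch_positions = as.integer(res$mismatch_positions),
    query_aln = res$a_aln,
    reference_aln = res$b_aln,
    query_start = res$a_start,
    reference_start = res$b_start
  )
  class(hit) <- "match_hit"
  hit
}

#' @export
print.match_hit <- function(x, ...) {
  cat(sprintf("match_hit: identity %.2f%%, overlap %d bp, %d mismatch(es)%s\n",
              x$identity_pct, x$overlap_bp, x$mismatches,
              if (x$coverage_failed) " [coverage failed]" else ""))
  invisible(x)
}
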