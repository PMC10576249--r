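#' Match flagged sequences against suspect source sets
#'
#' For each flagged sequence and each suspect set (e.g. sequences handled
#' in the same lab by unrelated projects), finds the nearest source
#' sequence under overlap alignment, reporting the mismatch count and the
#' 0-based mismatch offsets within the aligned overlap. Identical
#' sequences short-circuit the search. A match is `exact` when there are
#' no mismatches and the shorter sequence is fully covered.
#'
#' @param flagged named character vector of flagged ASV sequences
#'   (names = asv_id).
#' @param suspect_sets named list; each element a named character vector
#'   of source sequences.
#' @param min_overlap_bp minimum overlap passed to the aligner.
#' @return data.frame: asv_id, source_set, best_source_id, mismatches,
#'   mismatch_positions (comma-joined 0-based offsets), exact.
#' @export
cross_match <- function(flagged, suspect_sets, min_overlap_bp = 140L) {
  stopifnot(length(suspect_sets) > 0, !is.null(names(suspect_sets)))
  rows <- list()
  for (qi in seq_along(flagged)) {
    q <- toupper(flagged[[qi]]); qid <- names(flagged)[qi]
    for (set_name in names(suspect_sets)) {
      set <- suspect_sets[[set_name]]
      # exact short-circuit: identical sequence or full containment
      ex <- which(vapply(set, function(s) {
        s <- toupper(s)
        q == s || grepl(q, s, fixed = TRUE) || grepl(s, q, fixed = TRUE)
      }, logical(1)))
      if (length(ex)) {
        best_id <- sort(names(set)[ex])[1]
        rows[[length(rows) + 1L]] <- data.frame(
          asv_id = qid, source_set = set_name, best_source_id = best_id,
          mismatches = 0L, mismatch_positions = "", exact = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      best <- NULL; best_id <- NA_character_
      for (si in order(names(set))) {
        h <- overlap_align(q, set[[si]], min_overlap_bp)
        if (is.null(best) || h$mismatches < best$mismatches) {
          best <- h; best_id <- names(set)[si]
        }
      }
      full <- best$overlap_bp >= min(nchar(q), nchar(set[[best_id]]))
      rows[[length(rows) + 1L]] <- data.frame(
        asv_id = qid, source_set = set_name, best_source_id = best_id,
        mismatches = best$mismatches,
        mismatch_positions = paste(best$mismatch_positions, collapse = ","),
        exact = best$mismatches == 0L && full, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing positions (substitutions and internal gaps)
#' over the aligned overlap, for every sequence pair. Pairs whose overlap
#' falls below the minimum get `NA`. No substitution-model correction is
#' applied: for short fixed-locus fragments the raw proportion is the
#' appropriate distance.
#'
#' @param sequences named character vector (at least 2).
#' @param min_overlap_bp minimum usable overlap.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(sequences, min_overlap_bp = 140L) {
  n <- length(sequences)
  stopifnot(n >= 2L, !is.null(names(sequences)))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      h <- overlap_align(sequences[[i]], sequences[[j]], min_overlap_bp)
      d[i, j] <- d[j, i] <-
        if (h$coverage_failed) NA_real_ else h$mismatches / h$overlap_bp
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration returning an unrooted tree in
#' Newick form. Negative branch lengths, which NJ can produce on
#' non-additive inputs, are clamped to zero with the deficit transferred
#' to the sister edge so the joined pair's mutual distance is preserved.
#' When several pairs minimize the Q criterion the pair with the smallest
#' (lexicographic) label pair is joined, making the output deterministic.
#'
#' @param d complete symmetric distance matrix (n >= 3).
#' @param labels tip labels; defaults to the matrix dimnames.
#' @return Newick string (trifurcating root, i.e. unrooted).
#' @export
nj_tree <- function(d, labels = rownames(d)) {
  n <- nrow(d)
  stopifnot(n >= 3L, ncol(d) == n, !is.null(labels), length(labels) == n)
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("missing distances for pair(s): ",
         paste(paste(labels[idx[, 1]], labels[idx[, 2]], sep = "/"),
               collapse = ", "))
  }
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  nodes <- as.list(labels)          # newick fragment per active cluster
  reps <- labels                    # smallest leaf label, for tie-breaks
  D <- d
  while (length(nodes) > 2L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij)
      paste(sort(c(reps[ij[1]], reps[ij[2]])), collapse = "\r"))
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[[i]], fmt(vi),
                        nodes[[j]], fmt(vj))
    new_rep <- min(reps[i], reps[j])
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1, m - 1)
    if (length(keep)) {
      D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
      D2[m - 1, seq_along(keep)] <- D2[seq_along(keep), m - 1] <- dk[keep]
    }
    D <- D2
    nodes <- c(nodes[keep], new_node)
    reps <- c(reps[keep], new_rep)
  }
  # graft the final pair: attach one cluster into the other's root so the
  # result is an unrooted (trifurcating) newick
  x <- nodes[[1]]; y <- nodes[[2]]; dxy <- D[1, 2]
  if (startsWith(y, "(") && !startsWith(x, "(")) { tmp <- x; x <- y; y <- tmp }
  if (startsWith(x, "(")) {
    inner <- substr(x, 2, nchar(x) - 1)
    sprintf("(%s,%s:%s);", inner, y, fmt(dxy))
  } else {
    sprintf("(%s:%s,%s:0);", x, fmt(dxy), y)
  }
}

#' Homopolymer run-length discrepancies between two sequences
#'
#' Detects the classic single-base run-shortening error of semiconductor
#' sequencing (e.g. a run of seven T bases read as six): aligns the two
#' sequences and reports every location where the alignment's only local
#' difference is a length change inside a homopolymer run of length at
#' least 2 in both sequences. Substitutions are never reported.
#'
#' @param sequence_a,sequence_b nucleotide strings.
#' @param min_overlap_bp minimum alignable overlap; shorter overlaps give
#'   an empty result with a warning.
#' @return data.frame: base, run_length_a, run_length_b, offset (0-based
#'   start of the run in `sequence_a`). Zero rows when no event is found.
#' @export
#' @examples
#' homopolymer_discrepancies("AAATTTTTTTGCA", "AAATTTTTTGCA",
#'                           min_overlap_bp = 10)
homopolymer_discrepancies <- function(sequence_a, sequence_b,
                                      min_overlap_bp = 140L) {
  empty <- data.frame(base = character(0), run_length_a = integer(0),
                      run_length_b = integer(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  h <- overlap_align(sequence_a, sequence_b, min_overlap_bp)
  if (h$coverage_failed) {
    warning("sequences share less than ", min_overlap_bp,
            " bp of alignable overlap")
    return(empty)
  }
  a <- strsplit(h$query_aln, "")[[1]]
  b <- strsplit(h$reference_aln, "")[[1]]
  L <- length(a)
  gap_col <- a == "-" | b == "-"
  if (!any(gap_col)) return(empty)
  # group consecutive gap columns
  grp <- cumsum(c(TRUE, diff(which(gap_col)) > 1))
  groups <- split(which(gap_col), grp)
  events <- list()
  for (cols in groups) {
    gapped_in_a <- all(a[cols] == "-")
    gapped_in_b <- all(b[cols] == "-")
    if (!(gapped_in_a || gapped_in_b)) next   # mixed gap group, not a run event
    full <- if (gapped_in_a) b else a
    base <- unique(full[cols])
    if (length(base) != 1L || !base %in% c("A", "C", "G", "T")) next
    # expand over the flanking matched run of the same base
    lo <- min(cols); hi <- max(cols)
    while (lo > 1L && a[lo - 1L] == base && b[lo - 1L] == base) lo <- lo - 1L
    while (hi < L && a[hi + 1L] == base && b[hi + 1L] == base) hi <- hi + 1L
    run_a <- sum(a[lo:hi] == base)
    run_b <- sum(b[lo:hi] == base)
    if (min(run_a, run_b) < 2L || run_a == run_b) next
    # 0-based offset of the run start in the ungapped sequence_a
    offset <- h$query_start + sum(a[seq_len(lo - 1L)] != "-")
    events[[length(events) + 1L]] <- data.frame(
      base = base, run_length_a = run_a, run_length_b = run_b,
      offset = as.integer(offset), stringsAsFactors = FALSE)
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out[order(out$offset), , drop = FALSE]
}

#' No-match sequences near flagged clusters
#'
#' Among sequences that received no taxonomic assignment, finds those
#' within a small mismatch radius of any member of a flagged cluster
#' (sequences similar to, but below the identity threshold of, a flagged
#' species — e.g. error variants or chimera fragments).
#'
#' @param no_match_sequences named character vector of unassigned ASV
#'   sequences.
#' @param flagged_clusters named list; each element a named character
#'   vector of the cluster's member sequences (clusters are typically the
#'   ASVs sharing one flagged species).
#' @param max_mismatches inclusion radius (default 4, just beyond the 97%
#'   assignment radius on a 145 bp amplicon).
#' @param min_overlap_bp minimum alignable overlap.
#' @return named list (one element per cluster) of data.frames: asv_id,
#'   nearest_member, mismatches. Clusters with no neighbors get zero rows.
#' @export
near_threshold_neighbors <- function(no_match_sequences, flagged_clusters,
                                     max_mismatches = 4L,
                                     min_overlap_bp = 140L) {
  empty <- data.frame(asv_id = character(0), nearest_member = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (!length(flagged_clusters)) return(list())
  out <- lapply(flagged_clusters, function(members) {
    if (!length(no_match_sequences)) return(empty)
    rows <- list()
    for (qi in seq_along(no_match_sequences)) {
      best_mm <- NA_integer_; best_member <- NA_character_
      for (mi in order(names(members))) {
        h <- overlap_align(no_match_sequences[[qi]], members[[mi]],
                           min_overlap_bp)
        if (h$coverage_failed) next
        if (is.na(best_mm) || h$mismatches < best_mm) {
          best_mm <- h$mismatches; best_member <- names(members)[mi]
        }
      }
      if (!is.na(best_mm) && best_mm <= max_mismatches)
        rows[[length(rows) + 1L]] <- data.frame(
          asv_id = names(no_match_sequences)[qi],
          nearest_member = best_member, mismatches = best_mm,
          stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$asv_id), , drop = FALSE]
  })
  out
}
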