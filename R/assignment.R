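#' Rank reference matches for a query sequence
#'
#' Aligns a query against every record of a reference library, keeps for
#' each species only its best-identity record, discards hits whose usable
#' overlap is below the minimum (140 bp by default; matches discarded this
#' way typically rest on a single short reference record), and sorts the
#' rest by identity descending with lexicographic species order as a
#' deterministic tie-break.
#'
#' @param query query nucleotide string.
#' @param refs reference library data.frame (see [read_reference_fasta()]).
#' @param thresholds a [screening_thresholds()] object.
#' @return data.frame of hits: ref_id, species, genus, family, order,
#'   identity_pct, overlap_bp, mismatches, coverage_frac — one row per
#'   species, best first. Zero rows for an empty library or when all hits
#'   fail coverage.
#' @export
rank_matches <- function(query, refs, thresholds = screening_thresholds()) {
  if (is.null(refs) || nrow(refs) == 0L)
    return(.empty_hits())
  hits <- lapply(seq_len(nrow(refs)), function(i) {
    h <- overlap_align(query, refs$sequence[i], thresholds$min_overlap_bp)
    data.frame(ref_id = refs$ref_id[i], species = refs$species[i],
               genus = refs$genus[i], family = refs$family[i],
               order = refs$order[i],
               identity_pct = h$identity_pct, overlap_bp = h$overlap_bp,
               mismatches = h$mismatches, coverage_frac = h$coverage_frac,
               coverage_failed = h$coverage_failed,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[!hits$coverage_failed, , drop = FALSE]
  if (nrow(hits) == 0L) return(.empty_hits())
  # per-species best record: max identity, then fewest mismatches, then ref_id
  hits <- hits[order(hits$species, -hits$identity_pct, hits$mismatches,
                     hits$ref_id), , drop = FALSE]
  hits <- hits[!duplicated(hits$species), , drop = FALSE]
  hits <- hits[order(-hits$identity_pct, hits$species), , drop = FALSE]
  rownames(hits) <- NULL
  hits$coverage_failed <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(ref_id = character(0), species = character(0),
             genus = character(0), family = character(0),
             order = character(0), identity_pct = numeric(0),
             overlap_bp = integer(0), mismatches = integer(0),
             coverage_frac = numeric(0), stringsAsFactors = FALSE)
}

#' Adjudicate ranked matches into a taxonomic assignment
#'
#' Applies the identification decision rules: no hit at or above the
#' assignment identity threshold gives "no match"; a unique best-matching
#' species is assigned directly; when several species tie at the top
#' identity, a tie containing at least one locally occurring species is
#' resolved in favour of the local species (recorded via
#' `local_preference_applied`), and a tie among species none of which is
#' known locally is assigned at the lowest taxonomic rank the tied species
#' share (typically genus for congeneric ties). The confidence class is
#' "strict" when the winning hit has at most `strict_max_mismatches`
#' mismatches (at most 1 bp difference by default, i.e. >99% on a 145 bp
#' amplicon), otherwise "standard".
#'
#' @param hits output of [rank_matches()].
#' @param checklist locality checklist data.frame (species, distance_km);
#'   species at a distance of at most `nonlocal_distance_km` count as local.
#'   Species absent from the checklist are treated as non-local for tie
#'   resolution (never silently as local).
#' @param thresholds a [screening_thresholds()] object.
#' @param asv_id optional identifier carried into the result.
#' @return an `assignment_result` list: asv_id, assigned_rank
#'   (species/genus/family/order/no_match), assigned_name,
#'   best_identity_pct, mismatches, overlap_bp, confidence_class
#'   (strict/standard/none), tied_species, local_preference_applied.
#' @export
adjudicate <- function(hits, checklist, thresholds = screening_thresholds(),
                       asv_id = NA_character_) {
  no_match <- function() {
    structure(list(asv_id = asv_id, assigned_rank = "no_match",
                   assigned_name = "No match",
                   best_identity_pct = if (nrow(hits)) max(hits$identity_pct) else NA_real_,
                   mismatches = NA_integer_, overlap_bp = NA_integer_,
                   confidence_class = "none", tied_species = character(0),
                   local_preference_applied = FALSE),
              class = "assignment_result")
  }
  eligible <- hits[hits$identity_pct >= thresholds$assign_min_identity_pct, ,
                   drop = FALSE]
  if (nrow(eligible) == 0L) return(no_match())

  top_id <- eligible$identity_pct[1]
  tied <- eligible[abs(eligible$identity_pct - top_id) < 1e-9, , drop = FALSE]
  is_local <- .species_is_local(tied$species, checklist, thresholds)

  local_pref <- FALSE
  if (nrow(tied) == 1L) {
    winner <- tied[1, ]
    rank <- "species"; name <- winner$species
  } else if (any(is_local)) {
    # favour locally occurring species over equally good non-local ones
    local_pref <- TRUE
    locals <- tied[is_local, , drop = FALSE]
    if (nrow(locals) == 1L) {
      winner <- locals[1, ]
      rank <- "species"; name <- winner$species
    } else {
      sh <- .lowest_shared_rank(locals)
      if (is.null(sh)) return(no_match())
      winner <- locals[1, ]; rank <- sh$rank; name <- sh$name
    }
  } else {
    sh <- .lowest_shared_rank(tied)
    if (is.null(sh)) return(no_match())
    winner <- tied[1, ]; rank <- sh$rank; name <- sh$name
  }

  conf <- if (winner$mismatches <= thresholds$strict_max_mismatches)
    "strict" else "standard"
  structure(list(
    asv_id = asv_id, assigned_rank = rank, assigned_name = name,
    best_identity_pct = top_id, mismatches = as.integer(winner$mismatches),
    overlap_bp = as.integer(winner$overlap_bp), confidence_class = conf,
    tied_species = if (nrow(tied) > 1L) sort(tied$species) else character(0),
    local_preference_applied = local_pref), class = "assignment_result")
}

.species_is_local <- function(species, checklist, thresholds) {
  d <- checklist$distance_km[match(species, checklist$species)]
  !is.na(d) & d <= thresholds$nonlocal_distance_km
}

# lowest rank shared by all tied hits; NULL when even the order differs
.lowest_shared_rank <- function(tied) {
  for (rank in c("genus", "family", "order")) {
    vals <- unique(tied[[rank]])
    if (length(vals) == 1L && nzchar(vals)) return(list(rank = rank, name = vals))
  }
  NULL
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment: %s [%s] %s (%.2f%%, %s)\n",
              x$assigned_name, x$assigned_rank,
              if (length(x$tied_species)) paste0("tie{", paste(x$tied_species, collapse = ","), "} ") else "",
              x$best_identity_pct %||% NA_real_, x$confidence_class))
  invisible(x)
}

#' Assign taxonomy to every ASV of a dataset
#'
#' Runs [rank_matches()] and [adjudicate()] for each ASV. A second,
#' optional fallback library is consulted only for ASVs that the primary
#' library leaves without a match.
#'
#' @param dataset an `edna_dataset` from [load_dataset()] or
#'   [generate_dataset()].
#' @param fallback_refs optional second reference library data.frame.
#' @return data.frame, one row per ASV: asv_id, assigned_rank,
#'   assigned_name, best_identity_pct, mismatches, overlap_bp,
#'   confidence_class, tied_species (comma-joined),
#'   local_preference_applied.
#' @export
assign_taxonomy <- function(dataset, fallback_refs = NULL) {
  stopifnot(inherits(dataset, "edna_dataset"))
  th <- dataset$thresholds
  rows <- lapply(seq_len(nrow(dataset$asv)), function(i) {
    hits <- rank_matches(dataset$asv$sequence[i], dataset$refs, th)
    res <- adjudicate(hits, dataset$checklist, th, dataset$asv$asv_id[i])
    if (res$assigned_rank == "no_match" && !is.null(fallback_refs)) {
      hits2 <- rank_matches(dataset$asv$sequence[i], fallback_refs, th)
      res2 <- adjudicate(hits2, dataset$checklist, th, dataset$asv$asv_id[i])
      if (res2$assigned_rank != "no_match") res <- res2
    }
    as_assignment_row(res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_assignment_row <- function(res) {
  data.frame(asv_id = res$asv_id, assigned_rank = res$assigned_rank,
             assigned_name = res$assigned_name,
             best_identity_pct = res$best_identity_pct,
             mismatches = res$mismatches, overlap_bp = res$overlap_bp,
             confidence_class = res$confidence_class,
             tied_species = paste(res$tied_species, collapse = ","),
             local_preference_applied = res$local_preference_applied,
             stringsAsFactors = FALSE)
}
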