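#' Flag non-local species observations
#'
#' An (ASV, sample) occurrence is flagged when the ASV's assignment is at
#' species rank with strict confidence (at most 1 bp difference by
#' default) and the species' nearest known occurrence lies strictly more
#' than `nonlocal_distance_km` (200 km) from the study area. Occurrences
#' that would match a non-local species only at standard (not strict)
#' confidence, and genus-level assignments all of whose tied species are
#' non-local, are reported separately as near-threshold rather than
#' flagged. Species absent from the checklist are listed as "unknown
#' locality" and never silently treated as local.
#'
#' @param assignments assignment table from [assign_taxonomy()].
#' @param profiles_filtered named list of filtered-stage profiles from
#'   [sample_profiles()].
#' @param checklist locality checklist data.frame.
#' @param thresholds a [screening_thresholds()] object.
#' @return list with data.frames `flags` (asv_id, species, sample_id,
#'   rra_pct, strict), `near_threshold` and `unknown_locality` (same
#'   columns plus `reason`).
#' @export
flag_nonlocal <- function(assignments, profiles_filtered, checklist,
                          thresholds = screening_thresholds()) {
  occ <- function(asv_ids) {
    rows <- lapply(profiles_filtered, function(p) {
      hit <- intersect(names(p$rra), asv_ids)
      if (!length(hit)) return(NULL)
      data.frame(asv_id = hit, sample_id = p$sample_id,
                 rra_pct = unname(p$rra[hit]), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(asv_id = character(0),
                                        sample_id = character(0),
                                        rra_pct = numeric(0))
    out
  }

  sp <- assignments[assignments$assigned_rank == "species", , drop = FALSE]
  d <- checklist$distance_km[match(sp$assigned_name, checklist$species)]
  unknown <- is.na(d)
  nonlocal <- !unknown & d > thresholds$nonlocal_distance_km
  strict <- sp$confidence_class == "strict"

  mk <- function(tab, reason = NULL) {
    if (nrow(tab) == 0L) {
      out <- data.frame(asv_id = character(0), species = character(0),
                        sample_id = character(0), rra_pct = numeric(0),
                        strict = logical(0), stringsAsFactors = FALSE)
      if (!is.null(reason)) out$reason <- character(0)
      return(out)
    }
    oc <- occ(tab$asv_id)
    out <- data.frame(asv_id = oc$asv_id,
                      species = tab$assigned_name[match(oc$asv_id, tab$asv_id)],
                      sample_id = oc$sample_id, rra_pct = oc$rra_pct,
                      strict = tab$confidence_class[match(oc$asv_id, tab$asv_id)] == "strict",
                      stringsAsFactors = FALSE)
    if (!is.null(reason)) out$reason <- reason
    out[order(out$asv_id, out$sample_id), , drop = FALSE]
  }

  flags <- mk(sp[nonlocal & strict, , drop = FALSE])
  near1 <- mk(sp[nonlocal & !strict, , drop = FALSE],
              reason = "standard_confidence")

  # genus-level ties among exclusively non-local species
  gn <- assignments[assignments$assigned_rank %in%
                      c("genus", "family", "order") &
                      nzchar(assignments$tied_species), , drop = FALSE]
  if (nrow(gn)) {
    all_nonlocal <- vapply(strsplit(gn$tied_species, ",", fixed = TRUE),
                           function(spp) {
                             dd <- checklist$distance_km[match(spp, checklist$species)]
                             all(!is.na(dd) & dd > thresholds$nonlocal_distance_km)
                           }, logical(1))
    gn <- gn[all_nonlocal, , drop = FALSE]
  }
  near2 <- if (nrow(gn)) {
    oc <- occ(gn$asv_id)
    if (nrow(oc)) data.frame(
      asv_id = oc$asv_id,
      species = gn$tied_species[match(oc$asv_id, gn$asv_id)],
      sample_id = oc$sample_id, rra_pct = oc$rra_pct,
      strict = gn$confidence_class[match(oc$asv_id, gn$asv_id)] == "strict",
      reason = "nonlocal_tie_above_species", stringsAsFactors = FALSE)
    else NULL
  } else NULL
  near <- rbind(near1, near2)
  near <- near[order(near$asv_id, near$sample_id), , drop = FALSE]

  unknown_tab <- mk(sp[unknown, , drop = FALSE], reason = "not_in_checklist")

  rownames(flags) <- rownames(near) <- rownames(unknown_tab) <- NULL
  list(flags = flags, near_threshold = near, unknown_locality = unknown_tab)
}

#' Occurrence matrix under a declared sample ordering
#'
#' Wide matrix of abundances with taxa (or ASVs) as rows and samples as
#' columns, ordered by field collection date or lab processing index, with
#' lexicographic sample_id as deterministic tie-break. Cells hold the
#' relative read abundance (percent); absent means 0.
#'
#' @param flags flag table (asv_id or species rows) from [flag_nonlocal()],
#'   or any long table with columns `sample_id`, `rra_pct` and a row key.
#' @param meta sample metadata (all samples to include as columns).
#' @param ordering_key "collection_date" or "processing_index".
#' @param row_key column of `flags` used for rows ("species" or "asv_id").
#' @return list with `matrix` (rows = taxa, cols = samples in order),
#'   `ordering_key`, and `column_order` (the key values, as character).
#' @export
build_occurrence_matrix <- function(flags, meta,
                                    ordering_key = c("collection_date",
                                                     "processing_index"),
                                    row_key = "species") {
  ordering_key <- match.arg(ordering_key)
  keyvals <- meta[[ordering_key]]
  if (anyNA(keyvals))
    stop("missing ", ordering_key, " for sample(s): ",
         paste(meta$sample_id[is.na(keyvals)], collapse = ", "))
  ord <- order(keyvals, meta$sample_id)
  samples <- meta$sample_id[ord]
  taxa <- sort(unique(flags[[row_key]]))
  m <- matrix(0, nrow = length(taxa), ncol = length(samples),
              dimnames = list(taxa, samples))
  if (nrow(flags)) {
    agg <- stats::aggregate(flags$rra_pct,
                            by = list(taxon = flags[[row_key]],
                                      sample = flags$sample_id), FUN = sum)
    keep <- agg$sample %in% samples
    m[cbind(agg$taxon[keep], agg$sample[keep])] <- agg$x[keep]
  }
  list(matrix = m, ordering_key = ordering_key,
       column_order = as.character(keyvals[ord]))
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties. A constant vector has no
#' defined rank correlation and yields `NA`.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return rho in \[-1, 1\], or `NA` for constant input.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Depth and richness correlates of non-local abundance
#'
#' Tests whether samples' non-local content tracks their sequencing effort:
#' Spearman correlations of the per-sample total non-local relative read
#' abundance (over filtered profiles) against (i) the total raw read count
#' and (ii) the number of distinct ASVs, both computed on pre-filter data
#' including "no match" and sub-threshold ASVs. Samples with no non-local
#' content contribute zeroes.
#'
#' @param dataset an `edna_dataset` (raw counts are taken from it;
#'   negative controls excluded).
#' @param flags flag table from [flag_nonlocal()].
#' @return list with `rho_total_reads`, `rho_n_asvs`, and the per-sample
#'   table used.
#' @export
depth_and_richness_correlates <- function(dataset, flags) {
  meta <- dataset$meta[!dataset$meta$is_negative_control, , drop = FALSE]
  if (nrow(meta) < 3L)
    return(list(rho_total_reads = NA_real_, rho_n_asvs = NA_real_,
                per_sample = NULL))
  counts <- dataset$counts[, meta$sample_id, drop = FALSE]
  tab <- data.frame(
    sample_id = meta$sample_id,
    total_reads = colSums(counts),
    n_asvs = colSums(counts > 0),
    nonlocal_rra_pct = vapply(meta$sample_id, function(s)
      sum(flags$rra_pct[flags$sample_id == s]), numeric(1)),
    stringsAsFactors = FALSE)
  list(rho_total_reads = rank_correlation(tab$total_reads, tab$nonlocal_rra_pct),
       rho_n_asvs = rank_correlation(tab$n_asvs, tab$nonlocal_rra_pct),
       per_sample = tab)
}

#' Concentration of occurrences along a sample ordering
#'
#' Quantifies whether a taxon's occurrences cluster in a sample ordering
#' (e.g. lab processing order, where clustering suggests a point-source
#' contamination event). The statistic is the mean absolute pairwise
#' difference of the occupied positions; the p-value is the fraction of
#' random position sets (uniform draws without replacement) whose
#' statistic is at most the observed one. This is a package-specific
#' summary: the underlying study design compares orderings visually, and
#' the permutation test makes that comparison quantitative.
#'
#' @param positions integer positions (1-based ranks in the ordering) of
#'   the occurrences.
#' @param n_samples number of samples in the ordering.
#' @param n_permutations Monte-Carlo draws for the null (default 10000).
#' @param seed integer seed; required for reproducibility.
#' @return list with `statistic` and `p_value`; both `NA` with fewer than
#'   two occurrences.
#' @export
#' @examples
#' ordering_concentration(c(10, 11, 12), 94, 1000, seed = 1)
ordering_concentration <- function(positions, n_samples,
                                   n_permutations = 10000L, seed) {
  if (length(positions) < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_))
  stopifnot(!missing(seed), all(positions >= 1), all(positions <= n_samples),
            !anyDuplicated(positions))
  stat <- function(p) mean(abs(outer(p, p, "-"))[lower.tri(diag(length(p)))])
  obs <- stat(positions)
  k <- length(positions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i)
    stat(sample.int(n_samples, k)), numeric(1))
  list(statistic = obs, p_value = mean(null <= obs + 1e-12))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Concordance between technical replicates
#'
#' Compares two merged-stage profiles of the same underlying sample:
#' Jaccard similarity of the presence sets, the same restricted to taxa at
#' or above an abundance threshold (abundant taxa are expected to agree,
#' rare ones often appear in only one replicate), and the list of
#' discordant taxa with their abundances.
#'
#' @param profile_a,profile_b merged-stage `sample_profile`s.
#' @param abundance_threshold percent RRA defining "abundant" (default 1).
#' @return list with `jaccard_all`, `jaccard_above_threshold`,
#'   `discordant` (data.frame taxon, rra_pct, present_in).
#' @export
replicate_concordance <- function(profile_a, profile_b,
                                  abundance_threshold = 1.0) {
  a <- names(profile_a$rra); b <- names(profile_b$rra)
  jac <- function(x, y) {
    u <- union(x, y)
    if (!length(u)) return(1.0)
    length(intersect(x, y)) / length(u)
  }
  ab <- names(profile_a$rra[profile_a$rra >= abundance_threshold])
  bb <- names(profile_b$rra[profile_b$rra >= abundance_threshold])
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  disc <- rbind(
    if (length(only_a)) data.frame(taxon = only_a,
                                   rra_pct = unname(profile_a$rra[only_a]),
                                   present_in = profile_a$sample_id),
    if (length(only_b)) data.frame(taxon = only_b,
                                   rra_pct = unname(profile_b$rra[only_b]),
                                   present_in = profile_b$sample_id))
  if (is.null(disc))
    disc <- data.frame(taxon = character(0), rra_pct = numeric(0),
                       present_in = character(0))
  disc <- disc[order(disc$taxon), , drop = FALSE]
  rownames(disc) <- NULL
  list(jaccard_all = jac(a, b), jaccard_above_threshold = jac(ab, bb),
       discordant = disc)
}
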