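#' Compute relative read abundances for one sample
#'
#' Converts read counts to percentages summing to 100 within the sample.
#' An all-zero sample yields an empty profile with a warning rather than
#' an error.
#'
#' @param counts named non-negative integer vector (names = asv_id), or a
#'   single column of a counts matrix.
#' @param sample_id identifier stored in the profile.
#' @return a `sample_profile`: list with `sample_id`, `total_reads`,
#'   `rra` (named numeric, percent), `stage` ("raw") and `empty`.
#' @export
#' @examples
#' compute_rra(c(A = 9990, B = 10), "s1")$rra  # A 99.9, B 0.1
compute_rra <- function(counts, sample_id = "sample") {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) {
    warning("sample '", sample_id, "' has zero reads; empty profile")
    rra <- numeric(0)
  } else {
    rra <- 100 * counts[counts > 0] / total
  }
  structure(list(sample_id = sample_id, total_reads = as.integer(total),
                 rra = rra, stage = "raw", empty = total == 0),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("sample_profile '%s' [%s]: %d entries, %d reads\n",
              x$sample_id, x$stage, length(x$rra), x$total_reads))
  invisible(x)
}

#' Apply the abundance / no-match filter and renormalize
#'
#' Removes, in a single pass over the raw abundances, every entry whose
#' relative read abundance is strictly below the threshold (0.1% by
#' default; entries at exactly the threshold survive) or whose taxonomic
#' assignment is "no match", then rescales the survivors so they again sum
#' to 100%. Applying the filter to its own output changes nothing.
#'
#' @param profile a raw-stage `sample_profile` from [compute_rra()].
#' @param assignments assignment table from [assign_taxonomy()]; every ASV
#'   in the profile must appear in it.
#' @param thresholds a [screening_thresholds()] object.
#' @return a filtered-stage `sample_profile`; empty (with `empty = TRUE`)
#'   when nothing survives.
#' @export
filter_and_renormalize <- function(profile, assignments,
                                   thresholds = screening_thresholds()) {
  stopifnot(inherits(profile, "sample_profile"))
  if (profile$empty || length(profile$rra) == 0L)
    return(.restage(profile, "filtered", empty = TRUE))
  idx <- match(names(profile$rra), assignments$asv_id)
  if (anyNA(idx))
    stop("no assignment for ASV(s): ",
         paste(names(profile$rra)[is.na(idx)], collapse = ", "))
  no_match <- assignments$assigned_rank[idx] == "no_match"
  keep <- profile$rra >= thresholds$rra_min_pct & !no_match
  rra <- profile$rra[keep]
  if (length(rra) == 0L) {
    warning("sample '", profile$sample_id, "': nothing survives the filter")
    return(.restage(profile, "filtered", rra = numeric(0), empty = TRUE))
  }
  .restage(profile, "filtered", rra = 100 * rra / sum(rra))
}

.restage <- function(profile, stage, rra = profile$rra, empty = profile$empty) {
  profile$stage <- stage
  profile$rra <- rra
  profile$empty <- empty
  profile
}

#' Merge abundances that share a taxonomic assignment
#'
#' Sums filtered abundances per exact assignment (rank plus name), so two
#' ASVs both assigned to the same species pool their reads while a
#' genus-level assignment in the same genus stays a separate key. Totals
#' are conserved exactly.
#'
#' @param profile a filtered-stage `sample_profile`.
#' @param assignments assignment table from [assign_taxonomy()].
#' @return a merged-stage `sample_profile` keyed by `rank:name`.
#' @export
merge_by_identity <- function(profile, assignments) {
  stopifnot(inherits(profile, "sample_profile"))
  if (profile$empty || length(profile$rra) == 0L)
    return(.restage(profile, "merged"))
  idx <- match(names(profile$rra), assignments$asv_id)
  if (anyNA(idx))
    stop("no assignment for ASV(s): ",
         paste(names(profile$rra)[is.na(idx)], collapse = ", "))
  key <- paste(assignments$assigned_rank[idx], assignments$assigned_name[idx],
               sep = ":")
  merged <- vapply(split(profile$rra, key), sum, numeric(1))
  .restage(profile, "merged", rra = merged[sort(names(merged))])
}

#' Profiles for every sample of a dataset
#'
#' Convenience wrappers running [compute_rra()] (and optionally the filter
#' and merge stages) across all samples.
#'
#' @param dataset an `edna_dataset`.
#' @param assignments assignment table; required for stages beyond "raw".
#' @param stage one of "raw", "filtered", "merged".
#' @return named list of `sample_profile`s (one per sample).
#' @export
sample_profiles <- function(dataset, assignments = NULL, stage = "raw") {
  stopifnot(inherits(dataset, "edna_dataset"),
            stage %in% c("raw", "filtered", "merged"))
  profs <- lapply(colnames(dataset$counts), function(s) {
    cc <- setNames(dataset$counts[, s], rownames(dataset$counts))
    suppressWarnings(compute_rra(cc, s))
  })
  names(profs) <- colnames(dataset$counts)
  if (stage == "raw") return(profs)
  profs <- lapply(profs, function(p)
    suppressWarnings(filter_and_renormalize(p, assignments, dataset$thresholds)))
  if (stage == "filtered") return(profs)
  lapply(profs, merge_by_identity, assignments = assignments)
}

#' Long-format export of a list of profiles
#' @param profiles named list of `sample_profile`s.
#' @return data.frame sample_id, key, rra_pct (sorted for determinism).
#' @export
profiles_to_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    if (length(p$rra) == 0L) return(NULL)
    data.frame(sample_id = p$sample_id, key = names(p$rra),
               rra_pct = unname(p$rra), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(sample_id = character(0), key = character(0),
                      rra_pct = numeric(0), stringsAsFactors = FALSE))
  out <- out[order(out$sample_id, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Negative-control-informed count filtering
#'
#' Zeroes every ASV-by-sample cell whose read count is at most the maximum
#' count of that ASV across the dataset's negative controls. Off by
#' default in the pipeline (`negative_control_filter` config key): the
#' study design this package models reports control read counts but
#' applies no subtraction.
#'
#' @param dataset an `edna_dataset`.
#' @return the dataset with filtered counts (controls left untouched).
#' @export
apply_negative_control_filter <- function(dataset) {
  stopifnot(inherits(dataset, "edna_dataset"))
  nc <- dataset$meta$sample_id[dataset$meta$is_negative_control]
  if (!length(nc)) return(dataset)
  max_nc <- apply(dataset$counts[, nc, drop = FALSE], 1, max)
  smp <- dataset$meta$sample_id[!dataset$meta$is_negative_control]
  m <- dataset$counts[, smp, drop = FALSE]
  m[m <= max_nc] <- 0L   # max_nc recycles down columns: per-ASV comparison
  dataset$counts[, smp] <- m
  dataset
}

#' Per-category summary of non-local presence
#'
#' For each sample category (bird species or frass collector type): the
#' unweighted mean over its samples of the per-sample summed non-local
#' relative read abundance, and the number of distinct non-local species
#' observed (union over the category's samples). Negative controls are
#' excluded.
#'
#' @param flags flag table from [flag_nonlocal()].
#' @param meta sample metadata data.frame.
#' @return data.frame category, n_samples, n_nonlocal_species,
#'   mean_nonlocal_rra_pct.
#' @export
summarize_by_category <- function(flags, meta) {
  meta <- meta[!meta$is_negative_control, , drop = FALSE]
  if (nrow(meta) == 0L)
    return(data.frame(category = character(0), n_samples = integer(0),
                      n_nonlocal_species = integer(0),
                      mean_nonlocal_rra_pct = numeric(0)))
  per_sample <- vapply(meta$sample_id, function(s)
    sum(flags$rra_pct[flags$sample_id == s]), numeric(1))
  cats <- sort(unique(meta$category))
  out <- do.call(rbind, lapply(cats, function(cc) {
    ss <- meta$sample_id[meta$category == cc]
    sp <- unique(flags$species[flags$sample_id %in% ss])
    data.frame(category = cc, n_samples = length(ss),
               n_nonlocal_species = length(sp),
               mean_nonlocal_rra_pct = mean(per_sample[ss]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
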