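#' Screening thresholds
#'
#' Bundle of the decision thresholds used throughout the pipeline. Defaults
#' reproduce the study conditions this package models: matches with less
#' than 140 bp overlap (96% coverage of a 145 bp amplicon) are discarded,
#' assignments require at least 97% identity, non-local flags additionally
#' require a "strict" match (at most 1 bp difference, i.e. >99% on 145 bp),
#' ASVs below 0.1% relative read abundance are filtered, and a species is
#' non-local when its nearest known occurrence lies more than 200 km away.
#'
#' @param min_overlap_bp minimum usable query/reference overlap in bp.
#' @param min_coverage_frac advisory minimum overlap as a fraction of query
#'   length; the bp rule is operative, this is reported alongside.
#' @param assign_min_identity_pct minimum percent identity for any
#'   taxonomic assignment (inclusive).
#' @param strict_max_mismatches maximum mismatches for the "strict"
#'   confidence class required of non-local flags.
#' @param rra_min_pct relative read abundance filter threshold, percent;
#'   entries strictly below it are removed.
#' @param nonlocal_distance_km distance beyond which (strictly) a species
#'   counts as non-local.
#' @param min_total_reads optional minimum per-sample read total; samples
#'   below it are dropped before analysis. `NULL` disables the check.
#' @return an object of class `screening_thresholds` (a named list).
#' @export
#' @examples
#' screening_thresholds()
screening_thresholds <- function(min_overlap_bp = 140L,
                                 min_coverage_frac = 0.96,
                                 assign_min_identity_pct = 97.0,
                                 strict_max_mismatches = 1L,
                                 rra_min_pct = 0.1,
                                 nonlocal_distance_km = 200,
                                 min_total_reads = NULL) {
  th <- list(
    min_overlap_bp = as.integer(min_overlap_bp),
    min_coverage_frac = as.numeric(min_coverage_frac),
    assign_min_identity_pct = as.numeric(assign_min_identity_pct),
    strict_max_mismatches = as.integer(strict_max_mismatches),
    rra_min_pct = as.numeric(rra_min_pct),
    nonlocal_distance_km = as.numeric(nonlocal_distance_km),
    min_total_reads = if (is.null(min_total_reads)) NULL else as.integer(min_total_reads)
  )
  stopifnot(
    th$min_overlap_bp > 0, th$min_coverage_frac > 0,
    th$assign_min_identity_pct > 0, th$strict_max_mismatches >= 0,
    th$rra_min_pct > 0, th$nonlocal_distance_km > 0
  )
  # a strict-class hit must also clear the assignment threshold: 1 mismatch
  # on min_overlap_bp must not fall below assign_min_identity_pct
  strict_floor <- 100 * (th$min_overlap_bp - th$strict_max_mismatches) / th$min_overlap_bp
  if (strict_floor < th$assign_min_identity_pct)
    stop("strict confidence class would admit hits below the assignment threshold")
  class(th) <- "screening_thresholds"
  th
}

#' @export
print.screening_thresholds <- function(x, ...) {
  cat("Screening thresholds:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, if (is.null(v)) "off" else format(v)))
  }
  invisible(x)
}

#' Read or write a thresholds configuration file
#'
#' Flat YAML key-value files mirroring [screening_thresholds()].
#'
#' @param path file path.
#' @return `read_thresholds()` returns a `screening_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(screening_thresholds))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown threshold keys: ", paste(extra, collapse = ", "))
  do.call(screening_thresholds, cfg)
}

#' @rdname read_thresholds
#' @param thresholds a `screening_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}
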