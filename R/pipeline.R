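#' Run the full screening pipeline
#'
#' Orchestrates load, assignment, abundance filtering, non-local flagging,
#' occurrence-pattern analysis and (optionally) provenance tracing, and
#' writes the report files plus a run manifest (config hash, seed, input
#' checksums, per-stage record counts).
#'
#' @param config either a path to a YAML run configuration or an
#'   equivalent named list. Recognized keys: `asv_table`, `reference`,
#'   `metadata`, `checklist` (input paths; required unless `dataset` is
#'   given), `thresholds` (sub-list for [screening_thresholds()]),
#'   `suspect_sets` (named list of FASTA paths for provenance tracing),
#'   `n_permutations` (default 10000), `seed` (required), `out_dir`.
#' @param dataset optionally, an in-memory `edna_dataset` replacing the
#'   input paths (used by the synthetic workflow and tests).
#' @param quiet suppress stage log messages.
#' @return a `screen_report` (list of result tables; see [write_report()]),
#'   invisibly also written to `out_dir` when configured.
#' @export
run_screen <- function(config, dataset = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set a seed")
  seed <- as.integer(config$seed)
  n_perm <- as.integer(config$n_permutations %||% 10000L)
  log <- function(...) if (!quiet) message("[asvscreen] ", sprintf(...))

  th <- if (inherits(config$thresholds, "screening_thresholds"))
    config$thresholds
  else do.call(screening_thresholds, config$thresholds %||% list())

  if (is.null(dataset)) {
    for (key in c("asv_table", "reference", "metadata", "checklist"))
      if (is.null(config[[key]]))
        stop("config lacks required input path: ", key)
    log("loading inputs")
    dataset <- load_dataset(config$asv_table, config$reference,
                            config$metadata, config$checklist, th)
  } else {
    dataset$thresholds <- th
  }
  log("dataset: %d ASVs x %d samples", nrow(dataset$asv), ncol(dataset$counts))

  if (isTRUE(config$negative_control_filter)) {
    log("applying negative-control count filter")
    dataset <- apply_negative_control_filter(dataset)
  }

  log("assigning taxonomy against %d reference records", nrow(dataset$refs))
  assignments <- assign_taxonomy(dataset)

  log("computing abundance profiles")
  profiles_raw <- sample_profiles(dataset)
  profiles_filtered <- sample_profiles(dataset, assignments, "filtered")
  profiles_merged <- sample_profiles(dataset, assignments, "merged")

  log("flagging non-local observations")
  fl <- flag_nonlocal(assignments, profiles_filtered, dataset$checklist, th)

  log("occurrence patterns (%d flags)", nrow(fl$flags))
  meta_nc <- dataset$meta[!dataset$meta$is_negative_control, , drop = FALSE]
  occ <- list(
    collection_date = build_occurrence_matrix(fl$flags, meta_nc,
                                              "collection_date"),
    processing_index = build_occurrence_matrix(fl$flags, meta_nc,
                                               "processing_index"))
  correlates <- depth_and_richness_correlates(dataset, fl$flags)
  concentration <- .species_concentration(fl$flags, occ, n_perm, seed)
  category_summary <- summarize_by_category(fl$flags, dataset$meta)

  provenance <- NULL
  if (!is.null(config$suspect_sets)) {
    log("provenance tracing against %d suspect set(s)",
        length(config$suspect_sets))
    flagged_seqs <- dataset$asv$sequence[match(unique(fl$flags$asv_id),
                                               dataset$asv$asv_id)]
    names(flagged_seqs) <- unique(fl$flags$asv_id)
    if (length(flagged_seqs)) {
      sets <- lapply(config$suspect_sets, function(p) {
        if (is.character(p) && length(p) == 1L && file.exists(p)) {
          ss <- Biostrings::readDNAStringSet(p)
          setNames(as.character(ss), names(ss))
        } else unlist(p)
      })
      provenance <- cross_match(flagged_seqs, sets, th$min_overlap_bp)
    }
  }

  report <- structure(list(
    flags = fl$flags, near_threshold = fl$near_threshold,
    unknown_locality = fl$unknown_locality, assignments = assignments,
    profiles_filtered = profiles_to_table(profiles_filtered),
    profiles_merged = profiles_to_table(profiles_merged),
    occurrence = occ, correlates = correlates,
    concentration = concentration, category_summary = category_summary,
    provenance = provenance,
    summary = .report_summary(dataset, assignments, fl, correlates)
  ), class = "screen_report")

  if (!is.null(config$out_dir)) {
    log("writing report to %s", config$out_dir)
    paths <- write_report(report, config$out_dir)
    .write_manifest(config, dataset, report, seed, config$out_dir)
  }
  invisible(report)
}

# per-species occurrence concentration under both orderings
.species_concentration <- function(flags, occ, n_perm, seed) {
  species <- sort(unique(flags$species))
  rows <- lapply(seq_along(species), function(k) {
    sp <- species[k]
    out <- lapply(names(occ), function(ord) {
      m <- occ[[ord]]$matrix
      pos <- which(m[sp, ] > 0)
      r <- ordering_concentration(pos, ncol(m), n_perm,
                                  seed = seed + k)
      data.frame(species = sp, ordering = ord, n_occurrences = length(pos),
                 statistic = r$statistic, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(species = character(0), ordering = character(0),
                      n_occurrences = integer(0), statistic = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.report_summary <- function(dataset, assignments, fl, correlates) {
  meta_nc <- dataset$meta[!dataset$meta$is_negative_control, , drop = FALSE]
  counts <- dataset$counts[, meta_nc$sample_id, drop = FALSE]
  ranks <- table(factor(assignments$assigned_rank,
                        levels = c("species", "genus", "family", "order",
                                   "no_match")))
  affected <- length(unique(fl$flags$sample_id))
  kv <- c(
    n_samples = nrow(meta_nc),
    n_negative_controls = sum(dataset$meta$is_negative_control),
    n_asvs = nrow(dataset$asv),
    mean_reads_per_sample = round(mean(colSums(counts)), 1),
    n_assigned_species = unname(ranks["species"]),
    n_assigned_genus = unname(ranks["genus"]),
    n_assigned_family = unname(ranks["family"]),
    n_assigned_order = unname(ranks["order"]),
    n_no_match = unname(ranks["no_match"]),
    n_flagged_occurrences = nrow(fl$flags),
    n_flagged_asvs = length(unique(fl$flags$asv_id)),
    n_flagged_species = length(unique(fl$flags$species)),
    n_samples_with_flags = affected,
    n_near_threshold = nrow(fl$near_threshold),
    n_unknown_locality = nrow(fl$unknown_locality),
    rho_total_reads = round(correlates$rho_total_reads, 4),
    rho_n_asvs = round(correlates$rho_n_asvs, 4))
  data.frame(metric = names(kv), value = as.character(unname(kv)),
             stringsAsFactors = FALSE)
}

.write_manifest <- function(config, dataset, report, seed, out_dir) {
  cfg_plain <- config
  cfg_plain$thresholds <- unclass(
    if (inherits(config$thresholds, "screening_thresholds")) config$thresholds
    else do.call(screening_thresholds, config$thresholds %||% list()))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(cfg_plain, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  inputs <- unlist(config[c("asv_table", "reference", "metadata", "checklist")])
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  checksums <- if (length(inputs) && all(file.exists(inputs)))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    config_hash = cfg_hash, seed = seed, input_checksums = checksums,
    stage_counts = list(
      asvs = nrow(dataset$asv), samples = ncol(dataset$counts),
      reference_records = nrow(dataset$refs),
      assignments = nrow(report$assignments), flags = nrow(report$flags),
      near_threshold = nrow(report$near_threshold),
      unknown_locality = nrow(report$unknown_locality)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Generate a synthetic dataset from a configuration (CLI backend)
#'
#' Thin wrapper over [generate_dataset()] accepting a YAML configuration
#' path, used by the `simulate` subcommand of the command-line interface.
#'
#' @param config path to a YAML simulation configuration or a list;
#'   missing entries are filled from [default_sim_config()].
#' @param out_dir output directory (required).
#' @param seed integer seed (overrides a `seed` key in the config).
#' @return invisibly, the [generate_dataset()] result.
#' @export
simulate_dataset <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("a seed is required (config key 'seed' or argument)")
  config$seed <- NULL
  invisible(generate_dataset(config, out_dir = out_dir, seed = as.integer(seed)))
}
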