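#' Read an ASV table
#'
#' Tab-separated table with columns `asv_id`, `sequence`, then one column of
#' read counts per sample. Returns the ASV records and a rectangular counts
#' matrix (ASVs x samples); missing cells are zero.
#'
#' @param path path to the tab-separated ASV table.
#' @return list with `asv` (data.frame: asv_id, sequence) and `counts`
#'   (integer matrix, rownames = asv_id, colnames = sample_id).
#' @export
read_asv_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || !identical(names(tab)[1:2], c("asv_id", "sequence")))
    stop("ASV table must start with columns 'asv_id', 'sequence' plus sample columns: ", path)
  if (anyDuplicated(tab$asv_id))
    stop("duplicate asv_id in ASV table: ",
         paste(unique(tab$asv_id[duplicated(tab$asv_id)]), collapse = ", "))
  if (any(!nzchar(tab$sequence)))
    stop("empty sequence for asv_id: ",
         paste(tab$asv_id[!nzchar(tab$sequence)], collapse = ", "))
  samples <- names(tab)[-(1:2)]
  counts <- as.matrix(tab[, samples, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "integer")
  counts[is.na(counts)] <- 0L
  if (any(counts < 0))
    stop("negative read counts in ASV table")
  rownames(counts) <- tab$asv_id
  list(asv = data.frame(asv_id = tab$asv_id,
                        sequence = toupper(tab$sequence),
                        stringsAsFactors = FALSE),
       counts = counts)
}

#' Read a reference barcode library
#'
#' FASTA file whose headers carry the taxonomic lineage as
#' `ref_id;order;family;genus;Genus species` (semicolon-delimited ranks
#' after the identifier, species as a binomial).
#'
#' @param path FASTA path.
#' @return data.frame with ref_id, order, family, genus, species, sequence.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, ";", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 5L
  if (any(bad))
    stop("reference FASTA header lacks the 5 fields ",
         "'ref_id;order;family;genus;species': ",
         paste(headers[bad], collapse = " | "))
  m <- do.call(rbind, parts)
  refs <- data.frame(ref_id = trimws(m[, 1]), order = trimws(m[, 2]),
                     family = trimws(m[, 3]), genus = trimws(m[, 4]),
                     species = trimws(m[, 5]),
                     sequence = unname(toupper(as.character(seqs))),
                     stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  if (anyDuplicated(refs$ref_id))
    stop("duplicate ref_id in reference library")
  if (any(!nzchar(refs$species)))
    stop("species missing for reference record(s): ",
         paste(refs$ref_id[!nzchar(refs$species)], collapse = ", "))
  refs
}

#' Write a reference library to FASTA
#' @param refs data.frame as from [read_reference_fasta()].
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(refs, path) {
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- paste(refs$ref_id, refs$order, refs$family, refs$genus,
                       refs$species, sep = ";")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated file with header row: `sample_id`, `category`,
#' `collection_date` (ISO-8601), `processing_index`, `batch`,
#' `replicate_group` (may be empty), `is_negative_control` (TRUE/FALSE).
#'
#' @param path metadata path.
#' @return data.frame with typed columns; `collection_date` is `Date`.
#' @export
read_sample_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("sample_id", "category", "collection_date", "processing_index",
            "batch", "is_negative_control")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!"replicate_group" %in% names(meta)) meta$replicate_group <- NA_character_
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  meta$collection_date <- as.Date(meta$collection_date)  # ISO-8601
  meta$processing_index <- as.integer(meta$processing_index)
  meta$is_negative_control <- as.logical(meta$is_negative_control)
  meta$replicate_group[is.na(meta$replicate_group) |
                         meta$replicate_group == ""] <- NA_character_
  dup <- unsplit(lapply(split(meta$processing_index, meta$batch), duplicated),
                 meta$batch)
  if (any(dup))
    stop("processing_index not unique within batch for sample(s): ",
         paste(meta$sample_id[dup], collapse = ", "))
  meta[c("sample_id", "category", "collection_date", "processing_index",
         "batch", "replicate_group", "is_negative_control")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a species locality checklist
#'
#' Tab-separated file with header `species`, `distance_km`, `note`;
#' `distance_km` is the distance from the study area to the species'
#' nearest known occurrence. Species names must be pre-normalized binomials
#' (genus + epithet); synonym reconciliation is the caller's responsibility.
#'
#' @param path checklist path.
#' @return data.frame species, distance_km, note.
#' @export
read_checklist <- function(path) {
  chk <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "distance_km")
  if (!all(need %in% names(chk)))
    stop("checklist lacks column(s): ",
         paste(setdiff(need, names(chk)), collapse = ", "))
  if (!"note" %in% names(chk)) chk$note <- ""
  chk$distance_km <- as.numeric(chk$distance_km)
  if (anyNA(chk$distance_km) || any(chk$distance_km < 0))
    stop("checklist distances must be non-negative numbers")
  if (anyDuplicated(chk$species))
    stop("duplicate species in checklist")
  chk[c("species", "distance_km", "note")]
}

#' Load and cross-validate a complete screening dataset
#'
#' Reads all inputs and verifies they are mutually consistent: every sample
#' column in the ASV table must have metadata, ASV identifiers must be
#' unique, and counts are rectangularized (missing cells contribute zero
#' reads). If `thresholds$min_total_reads` is set, samples below it are
#' dropped with a message.
#'
#' @param asv_table_path,reference_fasta_path,metadata_path,checklist_path
#'   input file paths (see the respective readers for formats).
#' @param thresholds a [screening_thresholds()] object.
#' @return an object of class `edna_dataset`: list with `asv`, `counts`,
#'   `refs`, `meta`, `checklist`, `thresholds`.
#' @export
load_dataset <- function(asv_table_path, reference_fasta_path, metadata_path,
                         checklist_path, thresholds = screening_thresholds()) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  for (p in c(asv_table_path, reference_fasta_path, metadata_path, checklist_path))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  at <- read_asv_table(asv_table_path)
  refs <- read_reference_fasta(reference_fasta_path)
  meta <- read_sample_metadata(metadata_path)
  chk <- read_checklist(checklist_path)

  orphan <- setdiff(colnames(at$counts), meta$sample_id)
  if (length(orphan))
    stop("sample(s) in ASV table missing from metadata: ",
         paste(orphan, collapse = ", "))
  # keep only samples present in the table, in metadata order
  meta <- meta[meta$sample_id %in% colnames(at$counts), , drop = FALSE]
  counts <- at$counts[, meta$sample_id, drop = FALSE]

  if (!is.null(thresholds$min_total_reads)) {
    tot <- colSums(counts)
    low <- tot < thresholds$min_total_reads & !meta$is_negative_control
    if (any(low)) {
      message("dropping ", sum(low), " sample(s) below min_total_reads: ",
              paste(meta$sample_id[low], collapse = ", "))
      meta <- meta[!low, , drop = FALSE]
      counts <- counts[, meta$sample_id, drop = FALSE]
    }
  }

  ds <- list(asv = at$asv, counts = counts, refs = refs, meta = meta,
             checklist = chk, thresholds = thresholds)
  class(ds) <- "edna_dataset"
  ds
}

#' @export
print.edna_dataset <- function(x, ...) {
  cat(sprintf(paste0("edna_dataset: %d ASVs x %d samples, %d reference ",
                     "records, %d checklist species\n"),
              nrow(x$asv), ncol(x$counts), nrow(x$refs), nrow(x$checklist)))
  invisible(x)
}

#' Write an ASV table
#' @param asv data.frame asv_id, sequence.
#' @param counts integer matrix (ASVs x samples).
#' @param path output path.
#' @export
write_asv_table <- function(asv, counts, path) {
  stopifnot(identical(asv$asv_id, rownames(counts)))
  out <- cbind(asv[c("asv_id", "sequence")],
               as.data.frame(counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed float formatting shared by all report writers (byte-stable output)
.fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a screening report to disk
#'
#' Writes the flag table, near-threshold and unknown-locality side lists,
#' the assignment table, occurrence matrices under both sample orderings,
#' the provenance table (when present) and a summary, all as tab-separated
#' files with fixed column order and fixed float formatting so that
#' identical reports produce byte-identical files.
#'
#' @param report a `screen_report` as returned by [run_screen()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "screen_report"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wr <- function(df, name, num_cols = character(0), digits = 4) {
    for (cc in intersect(num_cols, names(df))) df[[cc]] <- .fmt_num(df[[cc]], digits)
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths[[length(paths) + 1L]] <<- p
  }
  wr(report$flags, "flags.tsv", "rra_pct")
  wr(report$near_threshold, "near_threshold.tsv", "rra_pct")
  wr(report$unknown_locality, "unknown_locality.tsv", "rra_pct")
  wr(report$assignments, "assignments.tsv",
     c("best_identity_pct"), digits = 2)
  wr(report$profiles_filtered, "profiles_filtered.tsv", "rra_pct")
  wr(report$profiles_merged, "profiles_merged.tsv", "rra_pct")
  wr(report$category_summary, "category_summary.tsv",
     c("mean_nonlocal_rra_pct"))
  for (ord in names(report$occurrence)) {
    om <- report$occurrence[[ord]]
    df <- data.frame(taxon = rownames(om$matrix),
                     apply(om$matrix, 2, .fmt_num),
                     check.names = FALSE, stringsAsFactors = FALSE)
    wr(df, paste0("occurrence_by_", ord, ".tsv"))
  }
  if (!is.null(report$provenance))
    wr(report$provenance, "provenance.tsv", "identity_pct", digits = 2)
  wr(report$summary, "summary.tsv")
  invisible(paths)
}
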