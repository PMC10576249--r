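# Synthetic data generation: complete datasets (reference library, locality
# checklist, sample metadata, ASV counts) with ground-truth origin labels,
# emulating the statistical structure the screening pipeline assumes:
# log-normal community composition sampled multinomially at depths around
# 28,000 reads/sample, contaminant injection structured in lab-processing
# order or field-collection time, low-level background carryover, and
# substitution / homopolymer / chimera sequencing artefacts.

.AMPLICON_WINDOW <- c(201L, 345L)   # 145 bp amplicon within a 658 bp barcode
.BARCODE_LEN <- 658L

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

.amplicon <- function(seq, window = .AMPLICON_WINDOW) {
  substr(seq, window[1], window[2])
}

#' Generate a synthetic reference library and locality checklist
#'
#' Full-length (658 bp) barcodes for a pool of local and foreign
#' (non-local) species, including a configurable number of congeneric
#' pairs whose members are near each other in sequence space (one local,
#' one foreign per pair, exercising the tie-resolution rules). Species are
#' mutually separated by at least `divergence$between_min` p-distance
#' within the amplicon window (the barcode-gap structure the decision
#' rules rely on); a few species carry a second reference record differing
#' by 1 bp (within-species haplotype variation). Checklist distances place
#' local species at most 200 km away and foreign species strictly beyond.
#'
#' @param n_local_species,n_foreign_species pool sizes (each >= 1).
#' @param n_congeneric_pairs number of local/foreign congeneric pairs
#'   (at most `min(n_local_species, n_foreign_species)`).
#' @param divergence list with `within_max` (fraction, second-record
#'   haplotype divergence ceiling) and `between_min` (minimum
#'   interspecies p-distance in the amplicon window).
#' @param n_haplotype_records how many species receive a 1-bp-variant
#'   second reference record.
#' @param seed integer seed; output is byte-identical per seed.
#' @return list with `refs` (reference data.frame), `checklist`,
#'   `species_pool` (species, genus, local) and `amplicon_window`.
#' @export
generate_reference_library <- function(n_local_species = 20L,
                                       n_foreign_species = 10L,
                                       n_congeneric_pairs = 2L,
                                       divergence = list(within_max = 0.01,
                                                         between_min = 0.02),
                                       n_haplotype_records = 3L,
                                       seed = 1L) {
  stopifnot(n_local_species >= 1L, n_foreign_species >= 1L,
            n_congeneric_pairs >= 0L,
            n_congeneric_pairs <= min(n_local_species, n_foreign_species))
  if (divergence$between_min <= 0 || divergence$between_min > 0.5 ||
      divergence$within_max < 0 || divergence$within_max >= divergence$between_min)
    stop("infeasible divergence constraints")
  .with_seed(seed, {
    win <- .AMPLICON_WINDOW
    win_len <- win[2] - win[1] + 1L
    n <- n_local_species + n_foreign_species
    local <- c(rep(TRUE, n_local_species), rep(FALSE, n_foreign_species))
    genus <- sprintf("Genus%02d", seq_len(n))
    # congeneric pairs: local i shares a genus with foreign partner
    for (k in seq_len(n_congeneric_pairs))
      genus[n_local_species + k] <- genus[k]
    families <- c("Erebidae", "Geometridae", "Noctuidae", "Tortricidae",
                  "Lycaenidae", "Nolidae", "Pieridae", "Notodontidae",
                  "Lasiocampidae")
    family <- families[(match(genus, unique(genus)) - 1L) %% length(families) + 1L]
    species <- paste(genus, sprintf("sp%02d", seq_len(n)))

    k_win <- ceiling(divergence$between_min * win_len) + 1L
    k_out <- ceiling(divergence$between_min * (.BARCODE_LEN - win_len))
    seqs <- character(n)
    for (attempt in seq_len(100L)) {
      for (i in seq_len(n)) {
        partner <- if (i > n_local_species &&
                       (i - n_local_species) <= n_congeneric_pairs)
          i - n_local_species else NA_integer_
        if (is.na(partner)) {
          seqs[i] <- .random_seq(.BARCODE_LEN)
        } else {
          pos_in <- sample(seq(win[1], win[2]), k_win)
          pos_out <- sample(setdiff(seq_len(.BARCODE_LEN), seq(win[1], win[2])),
                            k_out)
          seqs[i] <- .mutate_positions(seqs[partner], c(pos_in, pos_out))
        }
      }
      amps <- vapply(seqs, .amplicon, character(1))
      pd <- p_distance_matrix(setNames(amps, species), min_overlap_bp = 1L)
      diag(pd) <- Inf
      if (min(pd) >= divergence$between_min) break
      if (attempt == 100L)
        stop("infeasible divergence constraints: could not separate species")
    }

    refs <- data.frame(ref_id = sprintf("REF%03d", seq_len(n)),
                       order = "Lepidoptera", family = family, genus = genus,
                       species = species, sequence = seqs,
                       stringsAsFactors = FALSE)
    # second records: 1 bp haplotype variants inside the window
    n_hap <- min(n_haplotype_records, n)
    if (n_hap > 0 && divergence$within_max * win_len >= 1) {
      hap <- lapply(seq_len(n_hap), function(i) {
        pos <- sample(seq(win[1], win[2]), 1L)
        data.frame(ref_id = sprintf("REF%03dh", i), order = "Lepidoptera",
                   family = family[i], genus = genus[i], species = species[i],
                   sequence = .mutate_positions(seqs[i], pos),
                   stringsAsFactors = FALSE)
      })
      refs <- rbind(refs, do.call(rbind, hap))
    }
    rownames(refs) <- NULL
    checklist <- data.frame(
      species = species,
      distance_km = round(ifelse(local, runif(n, 0, 180),
                                 runif(n, 250, 2500)), 1),
      note = ifelse(local, "synthetic local", "synthetic non-local"),
      stringsAsFactors = FALSE)
    list(refs = refs, checklist = checklist,
         species_pool = data.frame(species = species, genus = genus,
                                   local = local, stringsAsFactors = FALSE),
         amplicon_window = win)
  })
}

#' Generate synthetic sample metadata
#'
#' Samples across bird/frass categories with collection dates uniform in
#' the field season, a lab processing order drawn independently of
#' collection date, batch labels and optional technical replicate pairs;
#' negative controls carry no collection date constraints and no reads.
#'
#' @param category_sizes named integer vector of samples per category.
#' @param date_range character vector of two ISO dates (field season).
#' @param n_negative_controls number of negative controls appended.
#' @param n_replicate_pairs number of technical replicate pairs (extra
#'   samples duplicating the first samples' category and date).
#' @param batch batch label.
#' @param seed integer seed.
#' @return metadata data.frame (see [read_sample_metadata()]).
#' @export
generate_sample_metadata <- function(category_sizes = c(crested_tit = 9L,
                                                        willow_tit = 24L,
                                                        blue_tit = 16L,
                                                        great_tit = 24L,
                                                        frass_sheet = 21L),
                                     date_range = c("2017-05-14", "2017-07-17"),
                                     n_negative_controls = 2L,
                                     n_replicate_pairs = 0L,
                                     batch = "batch1", seed = 1L) {
  .with_seed(seed, {
    category <- rep(names(category_sizes), category_sizes)
    n <- length(category)
    dates <- as.Date(date_range[1]) +
      sample.int(as.integer(as.Date(date_range[2]) - as.Date(date_range[1])) + 1L,
                 n, replace = TRUE) - 1L
    meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                       category = category, collection_date = dates,
                       batch = batch, replicate_group = NA_character_,
                       is_negative_control = FALSE, stringsAsFactors = FALSE)
    if (n_replicate_pairs > 0L) {
      stopifnot(n_replicate_pairs <= n)
      reps <- meta[seq_len(n_replicate_pairs), , drop = FALSE]
      grp <- sprintf("rep%02d", seq_len(n_replicate_pairs))
      meta$replicate_group[seq_len(n_replicate_pairs)] <- grp
      reps$replicate_group <- grp
      reps$sample_id <- sprintf("S%03dr", seq_len(n_replicate_pairs))
      meta <- rbind(meta, reps)
    }
    if (n_negative_controls > 0L) {
      nc <- data.frame(sample_id = sprintf("NC%02d", seq_len(n_negative_controls)),
                       category = "negative_control",
                       collection_date = as.Date(date_range[1]),
                       batch = batch, replicate_group = NA_character_,
                       is_negative_control = TRUE, stringsAsFactors = FALSE)
      meta <- rbind(meta, nc)
    }
    meta$processing_index <- sample.int(nrow(meta))
    meta[c("sample_id", "category", "collection_date", "processing_index",
           "batch", "replicate_group", "is_negative_control")]
  })
}

#' Generate true (contamination-free) community read counts
#'
#' Per-sample species compositions drawn log-normally over a random subset
#' of the local species pool, then read counts sampled multinomially at a
#' per-sample depth drawn around `depth$mean` (default 28,000 reads,
#' matching typical amplicon batch depths). Each species' ASV is the
#' amplicon window of its primary reference barcode; foreign species never
#' appear. Replicate-pair members share their composition (they subsample
#' the same material).
#'
#' @param meta metadata data.frame.
#' @param library output of [generate_reference_library()].
#' @param depth list: `mean`, `sd`, `min` for the per-sample read total.
#' @param composition list: `richness_range` (min/max species per sample),
#'   `sdlog` (log-normal abundance spread).
#' @param seed integer seed.
#' @return list with `asv` (data.frame asv_id, sequence, species),
#'   `counts` (integer matrix), `truth` (sample_id, asv_id, origin,
#'   parent).
#' @export
generate_true_communities <- function(meta, library,
                                      depth = list(mean = 28000, sd = 7000,
                                                   min = 1000),
                                      composition = list(richness_range = c(4L, 12L),
                                                         sdlog = 1.2),
                                      seed = 1L) {
  .with_seed(seed, {
    pool <- library$species_pool
    local_species <- pool$species[pool$local]
    stopifnot(length(local_species) >= composition$richness_range[1])
    # one ASV per species, stable ids by species pool order
    asv_id_of <- setNames(sprintf("ASV%03d", seq_len(nrow(pool))), pool$species)
    primary <- library$refs[!duplicated(library$refs$species), , drop = FALSE]
    seq_of <- setNames(vapply(primary$sequence, .amplicon, character(1),
                              window = library$amplicon_window),
                       primary$species)

    counts_env <- new.env(parent = emptyenv())
    add_reads <- function(sample_id, species, reads) {
      key <- paste(sample_id, species, sep = "\r")
      counts_env[[key]] <- (counts_env[[key]] %||% 0L) + as.integer(reads)
    }
    comp_of <- list()
    for (i in seq_len(nrow(meta))) {
      if (meta$is_negative_control[i]) next
      grp <- meta$replicate_group[i]
      if (!is.na(grp) && !is.null(comp_of[[grp]])) {
        comp <- comp_of[[grp]]
      } else {
        k <- sample(seq(composition$richness_range[1],
                        composition$richness_range[2]), 1L)
        k <- min(k, length(local_species))
        spp <- sample(local_species, k)
        w <- rlnorm(k, meanlog = 0, sdlog = composition$sdlog)
        comp <- setNames(w / sum(w), spp)
        if (!is.na(grp)) comp_of[[grp]] <- comp
      }
      total <- max(depth$min, round(rnorm(1, depth$mean, depth$sd)))
      reads <- as.integer(rmultinom(1, total, comp))
      for (j in seq_along(comp))
        if (reads[j] > 0) add_reads(meta$sample_id[i], names(comp)[j], reads[j])
    }

    keys <- ls(counts_env)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    sample_id <- vapply(parts, `[`, character(1), 1)
    species <- vapply(parts, `[`, character(1), 2)
    used_species <- sort(unique(species))
    asv <- data.frame(asv_id = unname(asv_id_of[used_species]),
                      sequence = unname(seq_of[used_species]),
                      species = used_species, stringsAsFactors = FALSE)
    asv <- asv[order(asv$asv_id), , drop = FALSE]
    counts <- matrix(0L, nrow(asv), nrow(meta),
                     dimnames = list(asv$asv_id, meta$sample_id))
    for (i in seq_along(keys))
      counts[asv_id_of[[species[i]]], sample_id[i]] <-
        as.integer(counts_env[[keys[i]]])
    truth <- data.frame(sample_id = sample_id,
                        asv_id = unname(asv_id_of[species]),
                        origin = "true_diet", parent = NA_character_,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$sample_id, truth$asv_id), , drop = FALSE]
    rownames(truth) <- NULL
    list(asv = asv, counts = counts, truth = truth, asv_id_of = asv_id_of,
         seq_of = seq_of)
  })
}

#' Define a contamination scenario
#'
#' @param mode "lab_point_source" (injection into a lab-processing-order
#'   window), "field_environmental" (injection into a collection-date
#'   window) or "background_carryover" (low-level reads everywhere).
#' @param contaminant_species species names drawn from the foreign pool.
#' @param target_window processing-index interval (lab mode) or date
#'   interval (field mode); ignored for background mode.
#' @param rra_level percent range from which each injection's target
#'   relative abundance is drawn (background mode: a single expected
#'   value, below the 0.1% filter by design). Must lie in (0, 60].
#' @param per_sample_probability probability that an eligible sample
#'   receives the contaminant.
#' @return a `contamination_scenario` list.
#' @export
contamination_scenario <- function(mode = c("lab_point_source",
                                            "field_environmental",
                                            "background_carryover"),
                                   contaminant_species,
                                   target_window = NULL,
                                   rra_level = c(0.5, 20),
                                   per_sample_probability = 0.7) {
  mode <- match.arg(mode)
  stopifnot(length(contaminant_species) >= 1,
            all(rra_level > 0), all(rra_level <= 60),
            per_sample_probability > 0, per_sample_probability <= 1)
  if (mode != "background_carryover" && is.null(target_window))
    stop("target_window required for ", mode)
  structure(list(mode = mode, contaminant_species = contaminant_species,
                 target_window = target_window, rra_level = rra_level,
                 per_sample_probability = per_sample_probability),
            class = "contamination_scenario")
}

#' Inject contaminant reads according to scenarios
#'
#' Lab point-source scenarios add contaminant reads only to samples whose
#' processing index falls in the target window; field scenarios only to
#' samples collected within the date window; background carryover adds
#' Poisson trace reads everywhere at an expected relative abundance below
#' the filter threshold. Injected read counts are chosen so the realized
#' post-injection relative abundance approximates the drawn `rra_level`.
#'
#' @param community output of [generate_true_communities()].
#' @param meta metadata data.frame.
#' @param library output of [generate_reference_library()].
#' @param scenarios list of [contamination_scenario()] objects.
#' @param seed integer seed.
#' @return `community` with updated `asv`, `counts` and `truth`.
#' @export
inject_contamination <- function(community, meta, library, scenarios,
                                 seed = 1L) {
  if (!length(scenarios)) return(community)
  .with_seed(seed, {
    counts <- community$counts
    asv <- community$asv
    truth <- community$truth
    asv_id_of <- community$asv_id_of
    seq_of <- community$seq_of
    eligible <- meta[!meta$is_negative_control, , drop = FALSE]
    for (sc in scenarios) {
      stopifnot(inherits(sc, "contamination_scenario"))
      targets <- switch(sc$mode,
        lab_point_source = eligible$sample_id[
          eligible$processing_index >= sc$target_window[1] &
          eligible$processing_index <= sc$target_window[2]],
        field_environmental = eligible$sample_id[
          eligible$collection_date >= as.Date(sc$target_window[1]) &
          eligible$collection_date <= as.Date(sc$target_window[2])],
        background_carryover = eligible$sample_id)
      if (!length(targets))
        stop("scenario window selects zero samples")
      for (spp in sc$contaminant_species) {
        if (!spp %in% names(asv_id_of)) stop("unknown contaminant species: ", spp)
        aid <- asv_id_of[[spp]]
        for (s in targets) {
          if (runif(1) > sc$per_sample_probability) next
          total <- sum(counts[, s])
          if (total == 0) next
          if (sc$mode == "background_carryover") {
            lam <- total * sc$rra_level[1] / 100
            reads <- stats::rpois(1, lam)
          } else {
            r <- runif(1, sc$rra_level[1], sc$rra_level[length(sc$rra_level)])
            reads <- max(1L, round(total * r / 100 / (1 - r / 100)))
          }
          if (reads == 0) next
          if (!aid %in% rownames(counts)) {
            counts <- rbind(counts, matrix(0L, 1, ncol(counts),
                                           dimnames = list(aid, colnames(counts))))
            asv <- rbind(asv, data.frame(asv_id = aid, sequence = seq_of[[spp]],
                                         species = spp, stringsAsFactors = FALSE))
          }
          counts[aid, s] <- counts[aid, s] + as.integer(reads)
          truth <- rbind(truth, data.frame(sample_id = s, asv_id = aid,
                                           origin = "contaminant",
                                           parent = NA_character_,
                                           stringsAsFactors = FALSE))
        }
      }
    }
    ord <- order(rownames(counts))
    counts <- counts[ord, , drop = FALSE]
    asv <- asv[order(asv$asv_id), , drop = FALSE]
    truth <- unique(truth[order(truth$sample_id, truth$asv_id), , drop = FALSE])
    rownames(asv) <- rownames(truth) <- NULL
    community$counts <- counts
    community$asv <- asv
    community$truth <- truth
    community
  })
}

# prefix of a at a 0-based breakpoint joined with the suffix of b
make_chimera <- function(a, b, breakpoint) {
  stopifnot(breakpoint > 0, breakpoint < nchar(a), nchar(a) == nchar(b))
  paste0(substr(a, 1, breakpoint), substr(b, breakpoint + 1, nchar(b)))
}

.runs_of <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  data.frame(base = r$values, length = r$lengths,
             start = ends - r$lengths + 1L, stringsAsFactors = FALSE)
}

#' Apply sequencing-error artefacts to a synthetic dataset
#'
#' Splits error-variant ASVs off their parents: substitution variants (one
#' random substituted position; a `sub_rate` fraction of each parent's
#' reads), homopolymer run-shortening variants (each run of >= 6 identical
#' bases is, with probability `homopolymer_del_prob`, shortened by one
#' base in a variant carrying a fixed fraction of the parent reads — the
#' semiconductor-sequencer artefact), and chimeric recombinants joining
#' the prefix and suffix of two co-occurring parents at a uniform
#' breakpoint (`chimera_rate` chance per sample). All rates 0 leave the
#' dataset untouched.
#'
#' @param community output of [generate_true_communities()] /
#'   [inject_contamination()].
#' @param sub_rate per-read substitution-variant rate in \[0, 0.1\].
#' @param homopolymer_del_prob per-run shortening probability in \[0, 1\].
#' @param chimera_rate per-sample chimera probability in \[0, 0.1\].
#' @param seed integer seed.
#' @return `community` with updated `asv`, `counts`, `truth`.
#' @export
apply_sequencing_noise <- function(community, sub_rate = 0,
                                   homopolymer_del_prob = 0,
                                   chimera_rate = 0, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.1,
            homopolymer_del_prob >= 0, homopolymer_del_prob <= 1,
            chimera_rate >= 0, chimera_rate <= 0.1)
  if (sub_rate == 0 && homopolymer_del_prob == 0 && chimera_rate == 0)
    return(community)
  .with_seed(seed, {
    counts <- community$counts
    asv <- community$asv
    truth <- community$truth
    hp_read_frac <- 0.2   # parent-read fraction moved to a run-shortened variant
    next_var <- 1L
    add_variant <- function(parent_id, var_seq, origin, per_sample_reads) {
      vid <- sprintf("ASVv%03d", next_var)
      next_var <<- next_var + 1L
      counts <<- rbind(counts, matrix(0L, 1, ncol(counts),
                                      dimnames = list(vid, colnames(counts))))
      asv <<- rbind(asv, data.frame(asv_id = vid, sequence = var_seq,
                                    species = NA_character_,
                                    stringsAsFactors = FALSE))
      for (s in names(per_sample_reads)) {
        mv <- per_sample_reads[[s]]
        if (mv <= 0) next
        counts[vid, s] <<- mv
        counts[parent_id, s] <<- counts[parent_id, s] - mv
        truth <<- rbind(truth, data.frame(sample_id = s, asv_id = vid,
                                          origin = origin, parent = parent_id,
                                          stringsAsFactors = FALSE))
      }
      vid
    }
    parents <- asv$asv_id
    for (pid in parents) {
      pseq <- asv$sequence[asv$asv_id == pid]
      present <- colnames(counts)[counts[pid, ] > 0]
      if (!length(present)) next
      if (sub_rate > 0) {
        pos <- sample.int(nchar(pseq), 1L)
        vseq <- .mutate_positions(pseq, pos)
        mv <- setNames(vapply(present, function(s)
          rbinom(1, counts[pid, s], sub_rate), numeric(1)), present)
        if (any(mv > 0)) add_variant(pid, vseq, "error_variant", mv)
      }
      if (homopolymer_del_prob > 0) {
        runs <- .runs_of(pseq)
        runs <- runs[runs$length >= 6L, , drop = FALSE]
        for (ri in seq_len(nrow(runs))) {
          if (runif(1) > homopolymer_del_prob) next
          vseq <- paste0(substr(pseq, 1, runs$start[ri]),
                         substr(pseq, runs$start[ri] + 2, nchar(pseq)))
          mv <- setNames(vapply(present, function(s)
            max(1L, as.integer(round(hp_read_frac * counts[pid, s]))),
            integer(1)), present)
          add_variant(pid, vseq, "error_variant", mv)
        }
      }
    }
    if (chimera_rate > 0) {
      for (s in colnames(counts)) {
        if (runif(1) > chimera_rate) next
        pres <- rownames(counts)[counts[, s] > 0]
        pres <- intersect(pres, parents)
        if (length(pres) < 2L) next
        ord <- pres[order(-counts[pres, s], pres)]
        a_id <- ord[1]; b_id <- ord[2]
        a <- asv$sequence[asv$asv_id == a_id]
        b <- asv$sequence[asv$asv_id == b_id]
        bp <- sample(seq(30L, nchar(a) - 30L), 1L)
        cseq <- make_chimera(a, b, bp)
        mv <- setNames(max(1L, as.integer(round(0.002 * sum(counts[, s])))), s)
        add_variant(a_id, cseq, "chimera", mv)
        # record both parents on the chimera truth row
        truth$parent[nrow(truth)] <- paste(a_id, b_id, sep = "|")
      }
    }
    # drop all-zero variant rows (possible when reads were fully reclaimed)
    nz <- rowSums(counts) > 0
    counts <- counts[nz, , drop = FALSE]
    asv <- asv[asv$asv_id %in% rownames(counts), , drop = FALSE]
    ord <- order(asv$asv_id)
    asv <- asv[ord, , drop = FALSE]
    counts <- counts[asv$asv_id, , drop = FALSE]
    truth <- truth[truth$asv_id %in% asv$asv_id, , drop = FALSE]
    truth <- truth[order(truth$sample_id, truth$asv_id), , drop = FALSE]
    rownames(asv) <- rownames(truth) <- NULL
    community$counts <- counts
    community$asv <- asv
    community$truth <- truth
    community
  })
}

#' Default simulation configuration
#'
#' The generator's defaults emulate the study conditions this package
#' models: 94 field samples across five categories plus negative controls,
#' a mean sequencing depth near 28,000 reads, a 30-species reference pool
#' with two congeneric local/foreign pairs, and one lab point-source
#' scenario contaminating the middle of the processing order with five
#' foreign species at 0.5-20% relative abundance.
#'
#' @return nested configuration list accepted by [generate_dataset()].
#' @export
default_sim_config <- function() {
  list(
    library = list(n_local_species = 20L, n_foreign_species = 10L,
                   n_congeneric_pairs = 2L,
                   divergence = list(within_max = 0.01, between_min = 0.02),
                   n_haplotype_records = 3L),
    metadata = list(category_sizes = c(crested_tit = 9L, willow_tit = 24L,
                                       blue_tit = 16L, great_tit = 24L,
                                       frass_sheet = 21L),
                    date_range = c("2017-05-14", "2017-07-17"),
                    n_negative_controls = 2L, n_replicate_pairs = 0L,
                    batch = "batch1"),
    depth = list(mean = 28000, sd = 7000, min = 1000),
    composition = list(richness_range = c(4L, 12L), sdlog = 1.2),
    scenarios = list(list(mode = "lab_point_source",
                          contaminant_species = "auto",
                          target_window = "auto",
                          rra_level = c(0.5, 20),
                          per_sample_probability = 0.7)),
    noise = list(sub_rate = 0, homopolymer_del_prob = 0, chimera_rate = 0)
  )
}

#' Generate a complete synthetic dataset
#'
#' One call producing a runnable input set (optionally written to disk in
#' the package's file dialects, plus the ground-truth table and the
#' generating configuration) from a nested configuration. Scenario fields
#' set to `"auto"` are resolved against the generated library and
#' metadata: contaminant species become the first foreign species, a lab
#' window becomes the middle third of processing indices, a field window
#' the middle third of the season.
#'
#' @param config configuration list; missing entries are filled from
#'   [default_sim_config()].
#' @param out_dir optional output directory; when given, all files are
#'   written there (asv_table.tsv, reference.fasta, metadata.tsv,
#'   checklist.tsv, thresholds.yaml, truth.tsv, sim_config.yaml).
#' @param seed integer master seed; every random draw derives from it.
#' @param thresholds [screening_thresholds()] carried into the dataset.
#' @return list with `dataset` (an `edna_dataset`), `truth`, `library`,
#'   and `paths` (when written).
#' @export
generate_dataset <- function(config = list(), out_dir = NULL, seed = 1L,
                             thresholds = screening_thresholds()) {
  cfg <- utils::modifyList(default_sim_config(), config)
  # modifyList merges lists recursively, which would quietly resurrect the
  # default scenario when the caller asks for none: take scenarios verbatim
  if ("scenarios" %in% names(config)) cfg$scenarios <- config$scenarios
  lib <- do.call(generate_reference_library, c(cfg$library, list(seed = seed)))
  meta <- do.call(generate_sample_metadata, c(cfg$metadata, list(seed = seed + 1L)))
  comm <- generate_true_communities(meta, lib, depth = cfg$depth,
                                    composition = cfg$composition,
                                    seed = seed + 2L)
  scenarios <- lapply(cfg$scenarios, .resolve_scenario, lib = lib, meta = meta)
  comm <- inject_contamination(comm, meta, lib, scenarios, seed = seed + 3L)
  comm <- apply_sequencing_noise(comm, sub_rate = cfg$noise$sub_rate,
                                 homopolymer_del_prob = cfg$noise$homopolymer_del_prob,
                                 chimera_rate = cfg$noise$chimera_rate,
                                 seed = seed + 4L)
  ds <- list(asv = comm$asv[c("asv_id", "sequence")], counts = comm$counts,
             refs = lib$refs, meta = meta, checklist = lib$checklist,
             thresholds = thresholds)
  class(ds) <- "edna_dataset"
  out <- list(dataset = ds, truth = comm$truth, library = lib,
              scenarios = scenarios)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)
    paths <- c(
      asv_table = file.path(out_dir, "asv_table.tsv"),
      reference = file.path(out_dir, "reference.fasta"),
      metadata = file.path(out_dir, "metadata.tsv"),
      checklist = file.path(out_dir, "checklist.tsv"),
      thresholds = file.path(out_dir, "thresholds.yaml"),
      truth = file.path(out_dir, "truth.tsv"),
      config = file.path(out_dir, "sim_config.yaml"))
    write_asv_table(ds$asv, ds$counts, paths[["asv_table"]])
    write_reference_fasta(ds$refs, paths[["reference"]])
    meta_out <- ds$meta
    meta_out$collection_date <- format(meta_out$collection_date, "%Y-%m-%d")
    .write_tsv(meta_out, paths[["metadata"]])
    .write_tsv(ds$checklist, paths[["checklist"]])
    write_thresholds(thresholds, paths[["thresholds"]])
    .write_tsv(comm$truth, paths[["truth"]])
    yaml::write_yaml(c(cfg, list(seed = seed)), paths[["config"]])
    out$paths <- paths
  }
  out
}

.resolve_scenario <- function(sc, lib, meta) {
  if (inherits(sc, "contamination_scenario")) return(sc)
  foreign <- lib$species_pool$species[!lib$species_pool$local]
  if (identical(sc$contaminant_species, "auto"))
    sc$contaminant_species <- head(foreign, 5L)
  if (identical(sc$target_window, "auto")) {
    if (sc$mode == "lab_point_source") {
      idx <- sort(meta$processing_index[!meta$is_negative_control])
      sc$target_window <- c(idx[ceiling(length(idx) / 3)],
                            idx[ceiling(2 * length(idx) / 3)])
    } else if (sc$mode == "field_environmental") {
      dd <- sort(meta$collection_date[!meta$is_negative_control])
      sc$target_window <- as.character(c(dd[ceiling(length(dd) / 3)],
                                         dd[ceiling(2 * length(dd) / 3)]))
    } else {
      sc$target_window <- NULL
    }
  }
  do.call(contamination_scenario, sc)
}
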