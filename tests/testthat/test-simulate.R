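test_that("reference library generation is deterministic and respects divergence", {
  lib1 <- generate_reference_library(n_local_species = 8L,
                                     n_foreign_species = 5L,
                                     n_congeneric_pairs = 2L, seed = 71)
  lib2 <- generate_reference_library(n_local_species = 8L,
                                     n_foreign_species = 5L,
                                     n_congeneric_pairs = 2L, seed = 71)
  expect_identical(lib1, lib2)
  # interspecies amplicon p-distances at or above the configured minimum
  primary <- lib1$refs[!duplicated(lib1$refs$species), ]
  amps <- setNames(substr(primary$sequence, lib1$amplicon_window[1],
                          lib1$amplicon_window[2]), primary$species)
  pd <- p_distance_matrix(amps)
  diag(pd) <- Inf
  expect_gte(min(pd), 0.02)
  # exactly two genera hold two species each (the congeneric pairs)
  tab <- table(lib1$species_pool$genus)
  expect_equal(sum(tab == 2), 2L)
  # checklist separates local from foreign by the 200 km rule
  loc <- lib1$checklist$distance_km[lib1$species_pool$local]
  frn <- lib1$checklist$distance_km[!lib1$species_pool$local]
  expect_true(all(loc <= 200) && all(frn > 200))
  expect_error(generate_reference_library(divergence = list(within_max = 0.05,
                                                            between_min = 0.02)),
               "divergence")
})

test_that("true communities hit the target depth and contain no foreign species", {
  lib <- generate_reference_library(n_local_species = 12L,
                                    n_foreign_species = 5L, seed = 72)
  meta <- generate_sample_metadata(category_sizes = c(bird = 50L),
                                   n_negative_controls = 2L, seed = 72)
  comm <- generate_true_communities(meta, lib,
                                    depth = list(mean = 28000, sd = 7000,
                                                 min = 1000), seed = 72)
  totals <- colSums(comm$counts[, !grepl("^NC", colnames(comm$counts))])
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 28000), 3 * se)
  # truth-only tables contain local species exclusively
  foreign_ids <- comm$asv_id_of[lib$species_pool$species[!lib$species_pool$local]]
  expect_false(any(foreign_ids %in% rownames(comm$counts)))
  expect_true(all(comm$truth$origin == "true_diet"))
  # negative controls carry no reads
  expect_equal(sum(comm$counts[, grepl("^NC", colnames(comm$counts))]), 0L)
})

test_that("a single-species composition gives one ASV at 100%", {
  lib <- generate_reference_library(n_local_species = 1L,
                                    n_foreign_species = 1L,
                                    n_congeneric_pairs = 0L,
                                    n_haplotype_records = 0L, seed = 73)
  meta <- generate_sample_metadata(category_sizes = c(bird = 3L),
                                   n_negative_controls = 0L, seed = 73)
  comm <- generate_true_communities(meta, lib,
                                    composition = list(richness_range = c(1L, 1L),
                                                       sdlog = 1), seed = 73)
  p <- compute_rra(setNames(comm$counts[, 1], rownames(comm$counts)),
                   colnames(comm$counts)[1])
  expect_equal(unname(p$rra), 100.0)
})

test_that("lab injections stay inside the processing window", {
  lib <- generate_reference_library(n_local_species = 10L,
                                    n_foreign_species = 4L, seed = 74)
  meta <- generate_sample_metadata(category_sizes = c(bird = 30L),
                                   n_negative_controls = 1L, seed = 74)
  comm <- generate_true_communities(meta, lib, seed = 74)
  frn <- lib$species_pool$species[!lib$species_pool$local]
  sc <- contamination_scenario("lab_point_source", frn[1:2],
                               target_window = c(10L, 20L),
                               rra_level = c(1, 5),
                               per_sample_probability = 1)
  out <- inject_contamination(comm, meta, lib, list(sc), seed = 74)
  inj <- out$truth[out$truth$origin == "contaminant", ]
  expect_gt(nrow(inj), 0)
  idx <- meta$processing_index[match(inj$sample_id, meta$sample_id)]
  expect_true(all(idx >= 10 & idx <= 20))
  # a window with no samples errors
  sc_bad <- contamination_scenario("lab_point_source", frn[1],
                                   target_window = c(900L, 950L))
  expect_error(inject_contamination(comm, meta, lib, list(sc_bad), seed = 1),
               "zero samples")
  # empty scenario list leaves the dataset unchanged
  expect_identical(inject_contamination(comm, meta, lib, list(), seed = 1),
                   comm)
})

test_that("field injections stay inside the date window", {
  lib <- generate_reference_library(n_local_species = 10L,
                                    n_foreign_species = 4L, seed = 75)
  meta <- generate_sample_metadata(category_sizes = c(bird = 30L), seed = 75)
  comm <- generate_true_communities(meta, lib, seed = 75)
  frn <- lib$species_pool$species[!lib$species_pool$local]
  win <- c("2017-06-01", "2017-06-20")
  sc <- contamination_scenario("field_environmental", frn[1],
                               target_window = win,
                               per_sample_probability = 1)
  out <- inject_contamination(comm, meta, lib, list(sc), seed = 75)
  inj <- out$truth[out$truth$origin == "contaminant", ]
  dd <- meta$collection_date[match(inj$sample_id, meta$sample_id)]
  expect_true(all(dd >= as.Date(win[1]) & dd <= as.Date(win[2])))
})

test_that("background carryover mostly falls below the abundance filter", {
  lib <- generate_reference_library(n_local_species = 10L,
                                    n_foreign_species = 4L, seed = 76)
  meta <- generate_sample_metadata(category_sizes = c(bird = 40L), seed = 76)
  comm <- generate_true_communities(meta, lib, seed = 76)
  frn <- lib$species_pool$species[!lib$species_pool$local]
  sc <- contamination_scenario("background_carryover", frn[1],
                               rra_level = 0.05, per_sample_probability = 1)
  out <- inject_contamination(comm, meta, lib, list(sc), seed = 76)
  inj <- out$truth[out$truth$origin == "contaminant", ]
  rra <- vapply(seq_len(nrow(inj)), function(i) {
    cc <- out$counts[, inj$sample_id[i]]
    100 * cc[inj$asv_id[i]] / sum(cc)
  }, numeric(1))
  expect_gte(mean(rra < 0.1), 0.9)
})

test_that("sequencing noise produces detectable variants and chimeras", {
  lib <- generate_reference_library(n_local_species = 6L,
                                    n_foreign_species = 2L,
                                    n_haplotype_records = 0L, seed = 77)
  meta <- generate_sample_metadata(category_sizes = c(bird = 10L), seed = 77)
  comm <- generate_true_communities(meta, lib, seed = 77)
  # zero rates: identity
  expect_identical(apply_sequencing_noise(comm, 0, 0, 0, seed = 1), comm)
  # force a homopolymer run into a parent and require its 1-shorter variant
  pid <- comm$asv$asv_id[1]
  seq0 <- comm$asv$sequence[1]
  seq7 <- paste0(substr(seq0, 1, 60), "TTTTTTT", substr(seq0, 68, nchar(seq0)))
  comm$asv$sequence[1] <- seq7
  noisy <- apply_sequencing_noise(comm, 0, homopolymer_del_prob = 1, 0,
                                  seed = 77)
  vars <- noisy$truth[noisy$truth$origin == "error_variant" &
                        noisy$truth$parent == pid, ]
  expect_gt(nrow(vars), 0)
  vseq <- noisy$asv$sequence[match(vars$asv_id[1], noisy$asv$asv_id)]
  ev <- homopolymer_discrepancies(seq7, vseq)
  expect_true(any(ev$run_length_a - ev$run_length_b == 1))
  # chimera joins prefix and suffix at the breakpoint
  a <- strrep("A", 145); b <- strrep("C", 145)
  expect_equal(asvscreen:::make_chimera(a, b, 70),
               paste0(strrep("A", 70), strrep("C", 75)))
  noisy2 <- apply_sequencing_noise(comm, 0, 0, chimera_rate = 0.1, seed = 78)
  chi <- noisy2$truth[noisy2$truth$origin == "chimera", ]
  expect_gt(nrow(chi), 0)
  expect_true(all(grepl("\\|", chi$parent)))
})

test_that("generate_dataset writes a loadable, seed-stable file set", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- list(metadata = list(category_sizes = c(bird = 8L, frass = 4L),
                              n_negative_controls = 1L))
  g1 <- generate_dataset(cfg, out_dir = d1, seed = 79)
  g2 <- generate_dataset(cfg, out_dir = d2, seed = 79)
  for (f in names(g1$paths)) {
    expect_identical(readLines(g1$paths[[f]]), readLines(g2$paths[[f]]),
                     info = f)
  }
  ds <- load_dataset(g1$paths[["asv_table"]], g1$paths[["reference"]],
                     g1$paths[["metadata"]], g1$paths[["checklist"]],
                     read_thresholds(g1$paths[["thresholds"]]))
  expect_s3_class(ds, "edna_dataset")
  # every read-bearing contaminant/diet cell has exactly one truth row
  truth <- read.delim(g1$paths[["truth"]])
  expect_equal(anyDuplicated(paste(truth$sample_id, truth$asv_id)), 0L)
})
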