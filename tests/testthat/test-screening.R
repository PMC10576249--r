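th <- screening_thresholds()

mk_profiles <- function(...) {
  lst <- list(...)
  out <- lapply(names(lst), function(s)
    structure(list(sample_id = s, total_reads = 10000L, rra = lst[[s]],
                   stage = "filtered", empty = length(lst[[s]]) == 0),
              class = "sample_profile"))
  names(out) <- names(lst)
  out
}

mk_assignments <- function(asv_id, name, rank = "species",
                           conf = "strict", tied = "") {
  data.frame(asv_id = asv_id, assigned_rank = rank, assigned_name = name,
             best_identity_pct = 100, mismatches = 0L, overlap_bp = 145L,
             confidence_class = conf, tied_species = tied,
             local_preference_applied = FALSE, stringsAsFactors = FALSE)
}

test_that("non-local flagging follows distance, rank and confidence rules", {
  chk <- make_checklist(c("Far sp", "Near sp", "Edge sp"), c(250, 150, 200))
  asg <- rbind(mk_assignments("a1", "Far sp"),
               mk_assignments("a2", "Near sp"),
               mk_assignments("a3", "Edge sp"),
               mk_assignments("a4", "Far sp", conf = "standard"),
               mk_assignments("a5", "Ghost sp"))
  profs <- mk_profiles(s1 = c(a1 = 5.0, a2 = 60.0, a3 = 20.0, a4 = 10.0,
                              a5 = 5.0))
  fl <- flag_nonlocal(asg, profs, chk, th)
  expect_equal(fl$flags$asv_id, "a1")           # 250 km, strict -> flagged
  expect_equal(fl$flags$rra_pct, 5.0)
  # 150 km and exactly 200 km are local
  expect_false(any(c("a2", "a3") %in% fl$flags$asv_id))
  # standard confidence to a non-local species -> near-threshold only
  expect_true("a4" %in% fl$near_threshold$asv_id)
  expect_false("a4" %in% fl$flags$asv_id)
  # species missing from the checklist -> unknown locality side list
  expect_true("a5" %in% fl$unknown_locality$asv_id)
})

test_that("genus-level ties among non-local species are near-threshold, not flagged", {
  chk <- make_checklist(c("GenA sp1", "GenA sp2"), c(300, 400))
  asg <- mk_assignments("g1", "GenA", rank = "genus",
                        tied = "GenA sp1,GenA sp2")
  profs <- mk_profiles(s1 = c(g1 = 12.0))
  fl <- flag_nonlocal(asg, profs, chk, th)
  expect_equal(nrow(fl$flags), 0L)
  expect_equal(fl$near_threshold$asv_id, "g1")
  expect_equal(fl$near_threshold$reason, "nonlocal_tie_above_species")
})

test_that("the flag set is invariant to sample and ASV input order", {
  chk <- make_checklist(c("Far sp", "Loc sp"), c(900, 10))
  asg <- rbind(mk_assignments(c("a1", "a2"), c("Far sp", "Loc sp")))
  profs <- mk_profiles(s1 = c(a1 = 5, a2 = 95), s2 = c(a2 = 50, a1 = 50))
  f1 <- flag_nonlocal(asg, profs, chk, th)$flags
  f2 <- flag_nonlocal(asg[2:1, ], rev(profs), chk, th)$flags
  expect_equal(f1, f2)
})

test_that("lowering the non-local distance threshold only adds flags", {
  set.seed(51)
  species <- sprintf("Sp%02d", 1:8)
  chk <- make_checklist(species, runif(8, 0, 1000))
  asg <- mk_assignments(sprintf("a%02d", 1:8), species)
  profs <- mk_profiles(s1 = setNames(rep(12.5, 8), sprintf("a%02d", 1:8)))
  f200 <- flag_nonlocal(asg, profs, chk, th)$flags
  f100 <- flag_nonlocal(asg, profs, chk,
                        screening_thresholds(nonlocal_distance_km = 100))$flags
  expect_true(all(paste(f200$asv_id, f200$sample_id) %in%
                    paste(f100$asv_id, f100$sample_id)))
})

test_that("occurrence matrices respect the declared ordering and tie-breaks", {
  meta <- data.frame(
    sample_id = c("sB", "sA", "sC"),
    category = "bird",
    collection_date = as.Date(c("2017-06-02", "2017-06-02", "2017-06-01")),
    processing_index = c(3L, 1L, 2L), batch = "b",
    replicate_group = NA_character_, is_negative_control = FALSE,
    stringsAsFactors = FALSE)
  flags <- data.frame(asv_id = "x", species = "Far sp",
                      sample_id = c("sB", "sC"), rra_pct = c(4, 2),
                      strict = TRUE, stringsAsFactors = FALSE)
  om <- build_occurrence_matrix(flags, meta, "collection_date")
  # date order, lexicographic among the tied dates
  expect_equal(colnames(om$matrix), c("sC", "sA", "sB"))
  expect_equal(unname(om$matrix["Far sp", ]), c(2, 0, 4))
  om2 <- build_occurrence_matrix(flags, meta, "processing_index")
  expect_equal(colnames(om2$matrix), c("sA", "sC", "sB"))
  meta$processing_index[2] <- NA
  expect_error(build_occurrence_matrix(flags, meta, "processing_index"), "sA")
})

test_that("rank correlation matches the average-rank oracle, NA on constants", {
  expect_equal(rank_correlation(1:3, c(2, 4, 9)), 1.0)
  expect_equal(rank_correlation(1:3, c(9, 4, 2)), -1.0)
  expect_true(is.na(rank_correlation(c(1, 1, 1), c(1, 2, 3))))
  set.seed(52)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + rnorm(n)
    expect_equal(rank_correlation(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("depth/richness correlates respond to planted structure", {
  set.seed(53)
  n <- 40
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n), category = "bird",
                     collection_date = as.Date("2017-06-01") + 1:n,
                     processing_index = 1:n, batch = "b",
                     replicate_group = NA_character_,
                     is_negative_control = FALSE, stringsAsFactors = FALSE)
  depth <- sample(5000:50000, n)
  counts <- rbind(A = as.integer(depth * 0.9), B = as.integer(depth * 0.1))
  colnames(counts) <- meta$sample_id
  ds <- structure(list(asv = data.frame(asv_id = c("A", "B"),
                                        sequence = c("ACGT", "GGCC")),
                       counts = counts, meta = meta), class = "edna_dataset")
  # contamination proportional to depth -> strong positive rho
  flags <- data.frame(asv_id = "B", species = "Far sp",
                      sample_id = meta$sample_id,
                      rra_pct = depth / max(depth) * 10, strict = TRUE,
                      stringsAsFactors = FALSE)
  r <- depth_and_richness_correlates(ds, flags)
  expect_gt(r$rho_total_reads, 0.9)
  # all-zero non-local totals -> undefined correlation
  r0 <- depth_and_richness_correlates(ds, flags[0, ])
  expect_true(is.na(r0$rho_total_reads))
})

test_that("ordering concentration statistic and null behave as designed", {
  r <- ordering_concentration(c(10, 11, 12), 94, 2000, seed = 1)
  expect_equal(r$statistic, 4 / 3, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
  r2 <- ordering_concentration(c(1, 47, 94), 94, 2000, seed = 1)
  expect_equal(r2$statistic, 62.0)
  expect_gt(r2$p_value, 0.5)
  r3 <- ordering_concentration(c(5), 94, 100, seed = 1)
  expect_true(is.na(r3$statistic) && is.na(r3$p_value))
})

test_that("concentration p-values are approximately uniform under the null", {
  set.seed(54)
  n <- 60; k <- 5
  pvals <- vapply(1:200, function(i) {
    pos <- sample.int(n, k)
    ordering_concentration(pos, n, 400, seed = 1000 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("replicate concordance separates abundant from rare taxa", {
  pa <- structure(list(sample_id = "r1", total_reads = 1000L,
                       rra = c(`species:X` = 60, `species:Y` = 39.54,
                               `species:Z` = 0.46),
                       stage = "merged", empty = FALSE),
                  class = "sample_profile")
  pb <- structure(list(sample_id = "r2", total_reads = 1000L,
                       rra = c(`species:X` = 55, `species:Y` = 45),
                       stage = "merged", empty = FALSE),
                  class = "sample_profile")
  rc <- replicate_concordance(pa, pb)
  expect_equal(rc$jaccard_all, 2 / 3)
  expect_equal(rc$jaccard_above_threshold, 1.0)  # rare 0.46% taxon excluded
  expect_equal(rc$discordant$taxon, "species:Z")
  expect_equal(rc$discordant$rra_pct, 0.46)
  expect_equal(replicate_concordance(pa, pa)$jaccard_all, 1.0)
  empty <- structure(list(sample_id = "e", total_reads = 0L,
                          rra = setNames(numeric(0), character(0)),
                          stage = "merged", empty = TRUE),
                     class = "sample_profile")
  rc2 <- replicate_concordance(pa, empty)
  expect_equal(rc2$jaccard_all, 0.0)
  expect_equal(nrow(rc2$discordant), 3L)
})
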