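mk_assign <- function(asv_id, rank = "species", name = NULL) {
  data.frame(asv_id = asv_id, assigned_rank = rank,
             assigned_name = if (is.null(name)) paste0("Sp ", asv_id) else name,
             confidence_class = ifelse(rank == "no_match", "none", "strict"),
             stringsAsFactors = FALSE)
}

test_that("relative read abundances sum to 100 and handle empty samples", {
  p <- compute_rra(c(A = 150L), "s")
  expect_equal(unname(p$rra), 100.0)
  p <- compute_rra(c(A = 9990L, B = 10L), "s")
  expect_equal(unname(p$rra), c(99.9, 0.1))
  expect_warning(p0 <- compute_rra(c(A = 0L, B = 0L), "s"), "zero reads")
  expect_true(p0$empty)
  expect_length(p0$rra, 0)
})

test_that("the abundance filter removes sub-threshold and no-match entries in one pass", {
  asg <- rbind(mk_assign(c("A", "B", "C")), mk_assign("NM", rank = "no_match"))
  # {A:89.91, B:10.0, C:0.09} -> C removed, renormalized to 4 dp
  p <- structure(list(sample_id = "s", total_reads = 10000L,
                      rra = c(A = 89.91, B = 10.0, C = 0.09),
                      stage = "raw", empty = FALSE), class = "sample_profile")
  f <- filter_and_renormalize(p, asg)
  expect_equal(round(unname(f$rra), 4), c(89.991, 10.009))
  expect_equal(sum(f$rra), 100, tolerance = 1e-9)

  # no-match removed regardless of abundance
  p <- structure(list(sample_id = "s", total_reads = 1000L,
                      rra = c(A = 95.0, NM = 5.0), stage = "raw",
                      empty = FALSE), class = "sample_profile")
  f <- filter_and_renormalize(p, asg)
  expect_equal(unname(f$rra), 100.0)
  expect_named(f$rra, "A")

  # an entry at exactly 0.1 survives the strict < comparison
  p <- compute_rra(c(A = 9990L, B = 10L), "s")
  f <- filter_and_renormalize(p, mk_assign(c("A", "B")))
  expect_true("B" %in% names(f$rra))
})

test_that("the filter is idempotent and conserves the 100% total", {
  set.seed(41)
  asg <- rbind(mk_assign(sprintf("A%02d", 1:12)),
               mk_assign(sprintf("N%02d", 1:3), rank = "no_match"))
  for (i in 1:100) {
    k <- sample(3:12, 1)
    ids <- c(sample(sprintf("A%02d", 1:12), k),
             sample(sprintf("N%02d", 1:3), sample(0:3, 1)))
    counts <- setNames(rpois(length(ids), lambda = sample(c(2, 500, 30000), 1)),
                       ids)
    p <- suppressWarnings(compute_rra(counts, "s"))
    f1 <- suppressWarnings(filter_and_renormalize(p, asg))
    if (length(f1$rra)) {
      expect_equal(sum(f1$rra), 100, tolerance = 1e-9)
      f2 <- filter_and_renormalize(f1, asg)
      expect_equal(f2$rra, f1$rra)
    }
  }
})

test_that("removing a zero-count ASV never changes abundances", {
  counts <- c(A = 500L, B = 250L, Z = 0L)
  p1 <- compute_rra(counts, "s")
  p2 <- compute_rra(counts[c("A", "B")], "s")
  expect_equal(p1$rra, p2$rra)
})

test_that("merging by identity pools equal assignments and conserves totals", {
  asg <- rbind(mk_assign(c("A1", "A2"), name = "Lymantria dispar"),
               mk_assign("B", name = "Other sp"),
               mk_assign("G", rank = "genus", name = "Lymantria"))
  p <- structure(list(sample_id = "s", total_reads = 1000L,
                      rra = c(A1 = 3.0, A2 = 2.0, B = 90.0, G = 5.0),
                      stage = "filtered", empty = FALSE),
                 class = "sample_profile")
  m <- merge_by_identity(p, asg)
  expect_equal(unname(m$rra["species:Lymantria dispar"]), 5.0)
  # genus-level key stays distinct from the congeneric species key
  expect_true("genus:Lymantria" %in% names(m$rra))
  expect_equal(sum(m$rra), sum(p$rra))
  # all-distinct identities pass through unchanged
  p2 <- structure(list(sample_id = "s", total_reads = 10L,
                       rra = c(A1 = 60.0, B = 40.0), stage = "filtered",
                       empty = FALSE), class = "sample_profile")
  m2 <- merge_by_identity(p2, asg)
  expect_equal(sort(unname(m2$rra)), c(40, 60))
})

test_that("negative-control filtering zeroes cells at or below control counts", {
  counts <- matrix(c(10L, 3L, 0L,   # s1
                     2L, 50L, 1L,   # s2
                     3L, 0L, 0L),   # nc1: max control counts 3, 0, 0
                   nrow = 3, dimnames = list(c("a", "b", "c"),
                                             c("s1", "s2", "nc1")))
  meta <- data.frame(sample_id = c("s1", "s2", "nc1"), category = "x",
                     collection_date = as.Date("2017-06-01"),
                     processing_index = 1:3, batch = "b",
                     replicate_group = NA_character_,
                     is_negative_control = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  ds <- structure(list(asv = data.frame(asv_id = c("a", "b", "c"),
                                        sequence = "ACGT"),
                       counts = counts, meta = meta), class = "edna_dataset")
  out <- apply_negative_control_filter(ds)
  expect_equal(unname(out$counts[, "s1"]), c(10L, 3L, 0L))
  expect_equal(unname(out$counts[, "s2"]), c(0L, 50L, 1L))  # a: 2 <= 3 zeroed
  expect_equal(unname(out$counts[, "nc1"]), c(3L, 0L, 0L))  # controls untouched
  # no controls: identity
  ds2 <- ds; ds2$meta$is_negative_control <- FALSE
  expect_identical(apply_negative_control_filter(ds2)$counts, ds2$counts)
})

test_that("category summaries average per-sample non-local totals", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "nc"),
                     category = c("tit", "tit", "flycatcher", "nc"),
                     is_negative_control = c(FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  flags <- data.frame(asv_id = c("x", "x", "y"), species = c("S1", "S1", "S2"),
                      sample_id = c("s1", "s2", "s1"),
                      rra_pct = c(10, 20, 0), strict = TRUE,
                      stringsAsFactors = FALSE)
  s <- summarize_by_category(flags, meta)
  expect_equal(s$mean_nonlocal_rra_pct[s$category == "tit"], 15.0)
  expect_equal(s$n_nonlocal_species[s$category == "tit"], 2L)
  expect_equal(s$mean_nonlocal_rra_pct[s$category == "flycatcher"], 0.0)
  expect_equal(s$n_nonlocal_species[s$category == "flycatcher"], 0L)
  expect_false("nc" %in% s$category)
  # planted totals match direct recomputation
  direct <- mean(c(sum(flags$rra_pct[flags$sample_id == "s1"]),
                   sum(flags$rra_pct[flags$sample_id == "s2"])))
  expect_equal(s$mean_nonlocal_rra_pct[s$category == "tit"], direct)
})
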