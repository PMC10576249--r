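# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

substitute_at <- function(seq, pos, base = NULL) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- if (is.null(base)) alt[1] else base
  }
  paste(chars, collapse = "")
}

# Brute-force fitting-alignment oracle: the shorter sequence is consumed in
# full, the longer one has free end gaps; cost = substitutions + gaps,
# minimized with the number of matches maximized among co-optimal solutions.
# Works on an encoded objective val = -1000*cost + matches (maximized; valid
# while matches < 1000), filled cell by cell with plain loops; completely
# independent of the package's C++ implementation.
oracle_align <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  acgt <- c("A", "C", "G", "T")
  V <- matrix(0, n + 1, m + 1)
  V[, 1] <- -1000 * (0:n)
  for (i in 1:n) {
    for (j in 1:m) {
      hit <- A[i] == B[j] && A[i] %in% acgt
      diag <- V[i, j] + if (hit) 1 else -1000
      up <- V[i, j + 1] - 1000
      left <- V[i + 1, j] - 1000
      V[i + 1, j + 1] <- max(diag, up, left)
    }
  }
  best <- max(V[n + 1, ])
  matches <- best %% 1000
  cost <- (matches - best) / 1000
  overlap <- matches + cost
  list(matches = matches, overlap_bp = overlap, mismatches = cost,
       identity_pct = if (overlap > 0) 100 * matches / overlap else NA_real_)
}

# average ranks computed from scratch (sort-based), then the product-moment
# formula applied to them: the definitional route to Spearman's rho.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (val in unique(v)) {
      idx <- which(v == val)
      positions <- which(sort(v) == val)
      r[idx] <- mean(positions)
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# hit-table builder for adjudication tests
make_hits <- function(species, identity, mismatches = NULL,
                      genus = NULL, family = "FamA", order = "Lepidoptera",
                      overlap = 145L) {
  k <- length(species)
  if (is.null(mismatches))
    mismatches <- round(overlap * (1 - identity / 100))
  if (is.null(genus)) genus <- vapply(strsplit(species, " "), `[`, "", 1)
  h <- data.frame(ref_id = sprintf("R%02d", seq_len(k)), species = species,
                  genus = genus, family = rep_len(family, k),
                  order = rep_len(order, k), identity_pct = identity,
                  overlap_bp = overlap, mismatches = as.integer(mismatches),
                  coverage_frac = 1, stringsAsFactors = FALSE)
  h[base::order(-h$identity_pct, h$species), , drop = FALSE]
}

make_checklist <- function(species, distance_km) {
  data.frame(species = species, distance_km = distance_km, note = "",
             stringsAsFactors = FALSE)
}

# small ready-made dataset files for io tests
write_toy_dataset <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asv <- data.frame(asv_id = c("a1", "a2", "a3"),
                    sequence = c(strrep("ACGT", 10), strrep("GATC", 10),
                                 strrep("TTAA", 10)),
                    s1 = c(100L, 50L, 0L), s2 = c(0L, 10L, 5L))
  write.table(asv, file.path(dir, "asv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c(">r1;Lepidoptera;Erebidae;Lymantria;Lymantria dispar",
               strrep("ACGT", 10),
               ">r2;Lepidoptera;Noctuidae;Xestia;Xestia agathina",
               strrep("GATC", 10)),
             file.path(dir, "refs.fasta"))
  meta <- data.frame(sample_id = c("s1", "s2"), category = c("bird", "bird"),
                     collection_date = c("2017-06-01", "2017-06-02"),
                     processing_index = 1:2, batch = "b1",
                     replicate_group = c("", ""),
                     is_negative_control = c(FALSE, FALSE))
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  chk <- data.frame(species = c("Lymantria dispar", "Xestia agathina"),
                    distance_km = c(1500, 10), note = "")
  write.table(chk, file.path(dir, "chk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(asv = file.path(dir, "asv.tsv"), refs = file.path(dir, "refs.fasta"),
       meta = file.path(dir, "meta.tsv"), chk = file.path(dir, "chk.tsv"))
}
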