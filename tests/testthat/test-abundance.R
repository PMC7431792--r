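test_that("per-ORF normalization reproduces hand-computed values", {
  expect_equal(normalize_per_orf(332, 166, 2.0), 1.0)
  expect_equal(normalize_per_orf(0, 166, 23.40), 0)
  expect_equal(normalize_per_orf(234, 166, 23.40), 234 / (166 * 23.40))
  expect_equal(normalize_per_orf(234, 166, 23.40), 0.06024, tolerance = 1e-4)
  expect_error(normalize_per_orf(10, 0, 1), class = "fragrec_input_error")
  expect_error(normalize_per_orf(10, 166, 0), class = "fragrec_input_error")
})

test_that("per-length normalization is exact and linear", {
  expect_equal(normalize_per_length(137, 137.012, 1.0), 137 / 137.012)
  expect_equal(normalize_per_length(137, 137.012, 1.0), 0.99991, tolerance = 1e-4)
  expect_equal(normalize_per_length(0, 50, 3), 0)
  expect_equal(normalize_per_length(10, 50, 1) / normalize_per_length(10, 50, 2), 2)
  # both normalizers are linear in hits and inversely linear in database size
  set.seed(4)
  h <- sample.int(1000, 20); g <- runif(20, 0.1, 50)
  expect_equal(normalize_per_orf(2 * h, 166, g), 2 * normalize_per_orf(h, 166, g))
  expect_equal(normalize_per_length(h, 137, 2 * g),
               normalize_per_length(h, 137, g) / 2)
})

test_that("phage ranking is deterministic, permutation-invariant and scale-invariant", {
  rows <- abundance_row(phage_id = c("pC", "pA", "pB", "pD"),
                        metagenome_id = "m1", n_hits = c(40, 40, 100, 7),
                        n_orfs = c(100, 100, 200, 50), db_gb = 2)
  r1 <- rank_phages(rows)
  expect_equal(r1$phage_id, c("pB", "pA", "pC", "pD"))  # tie pA/pC -> id order
  expect_equal(r1$rank, 1:4)
  set.seed(9)
  for (i in 1:5) {
    perm <- rows[sample.int(nrow(rows)), ]
    expect_equal(rank_phages(perm), r1)
  }
  scaled <- rows; scaled$normalized <- scaled$normalized * 17
  expect_equal(rank_phages(scaled)$phage_id, r1$phage_id)
  expect_equal(nrow(rank_phages(rows[1, ])), 1L)
})

test_that("rows computed with different normalizers refuse to rank together", {
  a <- abundance_row("p1", "m1", 10, n_orfs = 100, db_gb = 1)
  b <- abundance_row("p2", "m1", 10, genome_len_bp = 50000, db_gb = 1,
                     normalizer = "per_length")
  expect_error(rank_phages(rbind(a, b)), class = "fragrec_input_error")
})

test_that("coverage counts distinct metagenomes per ORF and habitat on a hand fixture", {
  orfs <- data.frame(index = 1:3, genome_id = "g",
                     start = c(1L, 301L, 601L), end = c(300L, 600L, 900L),
                     strand = "+", span = 300L, stop_pos = c(300L, 600L, 900L),
                     protein = "X", caller = "x", stringsAsFactors = FALSE)
  rec <- data.frame(
    read_id = paste0("r", 1:5),
    source_metagenome = c("f1", "f1", "f2", "mar1", "f2"),
    orf_index = c(1L, 1L, 1L, 2L, 3L),
    genome_start = c(10L, 50L, 100L, 320L, 610L),
    genome_end = c(100L, 140L, 190L, 410L, 700L),
    strand = "+", pct_identity = 90, evalue = 1e-9, bitscore = 50,
    stringsAsFactors = FALSE)
  habs <- data.frame(metagenome_id = c("f1", "f2", "mar1"),
                     habitat = c("freshwater", "freshwater", "marine"),
                     stringsAsFactors = FALSE)
  cs <- coverage_summary(rec, orfs, habs, k = 2)
  expect_equal(cs$per_orf$freshwater, c(2L, 0L, 1L))  # distinct metagenomes
  expect_equal(cs$per_orf$marine, c(0L, 1L, 0L))
  fresh <- cs$summary[cs$summary$habitat == "freshwater", ]
  expect_equal(fresh$n_orfs_ge1, 2L)
  expect_equal(fresh$n_orfs_ge2, 1L)
  expect_equal(fresh$n_orfs_gek, 1L)
  marine <- cs$summary[cs$summary$habitat == "marine", ]
  expect_equal(marine$n_orfs_ge1, 1L)
  expect_equal(marine$n_orfs_ge2, 0L)
  # unknown metagenome labels are an error
  bad <- rec; bad$source_metagenome[1] <- "mystery"
  expect_error(coverage_summary(bad, orfs, habs), class = "fragrec_input_error")
})

test_that("coverage thresholds are monotone in k and handle edge cases", {
  orfs <- data.frame(index = 1:3, genome_id = "g",
                     start = c(1L, 301L, 601L), end = c(300L, 600L, 900L),
                     strand = "+", span = 300L, stop_pos = c(300L, 600L, 900L),
                     protein = "X", caller = "x", stringsAsFactors = FALSE)
  habs <- data.frame(metagenome_id = c("f1", "f2"), habitat = "freshwater",
                     stringsAsFactors = FALSE)
  none <- coverage_summary(fragrec:::empty_recruitment_table(), orfs, habs)
  expect_true(all(none$summary[, c("n_orfs_ge1", "n_orfs_ge2", "n_orfs_gek")] == 0))
  # every ORF hit by every metagenome
  rec <- expand.grid(source_metagenome = c("f1", "f2"), orf_index = 1:3,
                     stringsAsFactors = FALSE)
  rec$read_id <- paste0("r", seq_len(nrow(rec)))
  rec$genome_start <- orfs$start[rec$orf_index]
  rec$genome_end <- orfs$start[rec$orf_index] + 30L
  rec$strand <- "+"; rec$pct_identity <- 99; rec$evalue <- 1e-20; rec$bitscore <- 80
  all_cov <- coverage_summary(rec, orfs, habs)
  expect_equal(all_cov$summary$n_orfs_ge1, 3L)
  expect_equal(all_cov$summary$n_orfs_ge2, 3L)
  ks <- vapply(1:4, function(k)
    coverage_summary(rec, orfs, habs, k = k)$summary$n_orfs_gek, integer(1))
  expect_true(all(diff(ks) <= 0))
})
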