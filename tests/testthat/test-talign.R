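test_that("six-frame translation matches manual codon lookup", {
  fr <- six_frame_translate("ATGAAATAG")
  expect_equal(fr$peptide[fr$frame == 1], "MK*")
  expect_equal(fr$peptide[fr$frame == -1], "LFH")  # revcomp CTATTTCAT
  expect_equal(nchar(fr$peptide), c(3L, 2L, 2L, 3L, 2L, 2L))
  fr2 <- six_frame_translate("AT")
  expect_true(all(fr2$peptide == ""))
})

test_that("local alignment reproduces matrix-diagonal scores and rejects noise", {
  a <- local_align("MKL", "MKL")
  expect_equal(a$score, 5L + 5L + 4L)  # BLOSUM62 diagonal M,K,L
  expect_equal(a$pct_identity, 100)
  b <- local_align("AAAA", "WWWW")
  expect_equal(b$score, 0L)
  expect_error(local_align("", "MKL"), class = "fragrec_input_error")
})

test_that("the DP equals a brute-force substring-enumeration oracle", {
  set.seed(101)
  for (rep in 1:200) {
    q <- random_peptide(sample(2:8, 1))
    s <- random_peptide(sample(2:8, 1))
    expect_equal(local_align(q, s)$score, oracle_local_score(q, s),
                 info = paste(q, s))
  }
})

test_that("the DP agrees with an independent aligner on longer peptides", {
  set.seed(102)
  mat <- blosum62()
  for (rep in 1:40) {
    q <- random_peptide(sample(10:60, 1))
    s <- random_peptide(sample(30:150, 1))
    # embed a shared motif in half the cases so positive scores occur
    if (rep %% 2 == 0) {
      motif <- random_peptide(12)
      q <- paste0(substr(q, 1, 5), motif, substr(q, 6, nchar(q)))
      s <- paste0(substr(s, 1, 20), motif, substr(s, 21, nchar(s)))
    }
    mine <- local_align(q, s)$score
    ref <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(mine, max(0, ref), info = paste(q, s))
  }
})

test_that("E-values follow the Karlin-Altschul formula and its scaling laws", {
  expect_equal(evalue(80, 100, 1e6), 0.041 * 100 * 1e6 * exp(-0.267 * 80))
  expect_equal(evalue(80, 100, 1e6), 2.2e-3, tolerance = 0.02)
  expect_equal(evalue(80, 100, 2e6) / evalue(80, 100, 1e6), 2)
  expect_equal(evalue(80, 200, 1e6) / evalue(80, 100, 1e6), 2)
  S <- seq(20, 200, by = 20)
  expect_true(all(diff(evalue(S, 100, 1e6)) < 0))
  expect_true(all(diff(bitscore(S)) > 0))
  expect_error(evalue(80, 0, 1e6), class = "fragrec_input_error")
})

test_that("reads copied from coding regions always self-match at 100% identity", {
  g <- simulate_phage_genome("self", length_bp = 10000, seed = 55)
  o <- call_orfs(g)
  db <- orf_proteins(o)
  big <- o[o$span > 400 & o$end <= genome_length(g), ]
  reads <- data.frame(
    id = paste0("r", seq_len(nrow(big))),
    seq = vapply(seq_len(nrow(big)), function(i)
      extract_interval(g, big$start[i] + 3, big$start[i] + 152, big$strand[i]),
      character(1)),
    stringsAsFactors = FALSE)
  hits <- search_translated(reads, db)
  top <- hits[hits$rank == 1, ]
  expect_setequal(top$read_id, reads$id)
  expect_true(all(top$pct_identity == 100))
})

test_that("seeded and exhaustive searches return identical hit sets", {
  set.seed(103)
  for (rep in 1:200) {
    prot <- random_peptide(sample(40:120, 1))
    if (rep %% 2 == 0) {
      # homologous read excised from the protein's coding sequence
      nt <- reverse_translate(prot)
      p0 <- sample.int(nchar(nt) - 90, 1)
      rd <- substr(nt, p0, p0 + 89)
    } else {
      rd <- random_dna(90)
    }
    reads <- data.frame(id = "r1", seq = rd, stringsAsFactors = FALSE)
    db <- data.frame(subject_id = "p1", peptide = prot, stringsAsFactors = FALSE)
    h1 <- search_translated(reads, db, mode = "seeded")
    h2 <- search_translated(reads, db, mode = "exhaustive")
    expect_identical(h1, h2)
  }
})

test_that("search output is a deterministic total order, byte-identical across runs", {
  g <- simulate_phage_genome("det", length_bp = 8000, seed = 77)
  o <- call_orfs(g)
  sim <- sample_reads(community_config(list(g), 1, n_reads = 200, seed = 5,
                                       background_fraction = 0.3))
  h1 <- search_translated(sim$reads, orf_proteins(o))
  h2 <- search_translated(sim$reads, orf_proteins(o))
  expect_identical(h1, h2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_hit_table(h1, p1); write_hit_table(h2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("reverse-complementing a read maps frame f hits to -f with equal scores", {
  g <- simulate_phage_genome("rc", length_bp = 8000, seed = 78)
  o <- call_orfs(g)
  db <- orf_proteins(o)
  sim <- sample_reads(community_config(list(g), 1, n_reads = 60, seed = 6,
                                       background_fraction = 0, read_len = 150))
  h <- search_translated(sim$reads, db)
  rc_reads <- sim$reads
  rc_reads$seq <- revcomp(rc_reads$seq)
  hrc <- search_translated(rc_reads, db)
  key <- function(d) {
    d <- d[order(d$read_id, d$subject_id, -d$raw_score),
           c("read_id", "subject_id", "raw_score")]
    rownames(d) <- NULL
    d
  }
  expect_equal(key(transform(h, frame = -frame))[, c("read_id", "subject_id")],
               key(hrc)[, c("read_id", "subject_id")])
  m <- merge(h, hrc, by = c("read_id", "subject_id"))
  m <- m[m$frame.x == -m$frame.y, ]
  expect_true(all(m$raw_score.x == m$raw_score.y))
})

test_that("an empty read collection searches to an empty hit table", {
  db <- data.frame(subject_id = "p", peptide = "MKLV", stringsAsFactors = FALSE)
  h <- search_translated(data.frame(id = character(), seq = character()), db)
  expect_equal(nrow(h), 0L)
  expect_error(search_translated(data.frame(id = "r", seq = "ACGT"),
                                 data.frame(subject_id = character(),
                                            peptide = character())),
               class = "fragrec_input_error")
})
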