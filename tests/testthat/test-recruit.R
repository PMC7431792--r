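test_that("reads excised from focal coding regions all pass the screen", {
  g <- simulate_phage_genome("foc", length_bp = 10000, seed = 61)
  o <- call_orfs(g)
  big <- o[o$span > 400 & o$end <= genome_length(g), ]
  reads <- data.frame(
    id = paste0("r", seq_len(nrow(big))),
    seq = vapply(seq_len(nrow(big)), function(i)
      extract_interval(g, big$start[i], big$start[i] + 149, big$strand[i]), ""),
    source_metagenome = "m1", stringsAsFactors = FALSE)
  cand <- screen_reads(reads, orf_proteins(o))
  expect_setequal(cand$id, reads$id)
  expect_equal(nrow(screen_reads(reads[0, ], orf_proteins(o))), 0L)
})

test_that("containment holds at every stage: recruited <= candidates <= reads", {
  com <- small_community()
  g <- com$refs[[1]]; o <- com$orfs[[1]]
  sim <- sample_reads(community_config(com$refs, c(.5, .3, .2), n_reads = 300,
                                       seed = 7, background_fraction = 0.3))
  prot <- orf_proteins(o)
  cand <- screen_reads(sim$reads, prot)
  decoys <- data.frame(subject_id = paste0("d", seq_len(nrow(com$orfs[[2]]))),
                       phage_id = "sc2", peptide = com$orfs[[2]]$protein,
                       stringsAsFactors = FALSE)
  db <- composite_db(g$id, prot, decoys)
  rec <- competitive_assign(cand, db, o)
  expect_true(all(cand$id %in% sim$reads$id))
  expect_true(all(rec$read_id %in% cand$id))
  expect_lte(nrow(rec), nrow(cand))
  expect_lte(nrow(cand), nrow(sim$reads))
})

test_that("with a focal-only database, stage 2 reduces to stage 1", {
  g <- simulate_phage_genome("only", length_bp = 8000, seed = 62)
  o <- call_orfs(g)
  sim <- sample_reads(community_config(list(g), 1, n_reads = 150, seed = 8,
                                       background_fraction = 0.4))
  prot <- orf_proteins(o)
  cand <- screen_reads(sim$reads, prot)
  rec <- competitive_assign(cand, composite_db(g$id, prot), o)
  expect_setequal(rec$read_id, cand$id)
})

test_that("adding decoys never enlarges the recruited set (monotone competition)", {
  com <- small_community(seed = 50)
  g <- com$refs[[1]]; o <- com$orfs[[1]]
  rel <- diverge_genome(g, o, 80, seed = 3)
  sim <- sample_reads(community_config(list(rel), 1, n_reads = 250, seed = 9,
                                       background_fraction = 0.2))
  prot <- orf_proteins(o)
  cand <- screen_reads(sim$reads, prot)
  rec0 <- competitive_assign(cand, composite_db(g$id, prot), o)
  # decoys: the relative's own proteome -- strong competitors
  sel <- o[o$index %in% attr(rel, "mutated_orfs"), ]
  dec1 <- data.frame(subject_id = paste0("dA", sel$index), phage_id = "decA",
                     peptide = vapply(seq_len(nrow(sel)), function(i)
                       translate_orf(rel, sel[i, ]), ""),
                     stringsAsFactors = FALSE)
  dec2 <- data.frame(subject_id = paste0("dB", seq_len(nrow(com$orfs[[3]]))),
                     phage_id = "decB", peptide = com$orfs[[3]]$protein,
                     stringsAsFactors = FALSE)
  rec1 <- competitive_assign(cand, composite_db(g$id, prot, dec1), o)
  rec2 <- competitive_assign(cand, composite_db(g$id, prot, rbind(dec1, dec2)), o)
  expect_true(all(rec1$read_id %in% rec0$read_id))
  expect_true(all(rec2$read_id %in% rec1$read_id))
})

test_that("a decoy that outscores the focal hit blocks recruitment; exact ties break by subject id", {
  prot <- random_peptide(80)
  nt <- reverse_translate(prot)
  reads <- data.frame(id = "r1", seq = substr(nt, 1, 120),
                      source_metagenome = "m", stringsAsFactors = FALSE)
  focal <- data.frame(subject_id = "ORF1",
                      peptide = paste0(substr(prot, 1, 20),
                                       random_peptide(nchar(prot) - 20)),
                      stringsAsFactors = FALSE)
  orfs <- data.frame(index = 1L, genome_id = "f", start = 1L,
                     end = nchar(focal$peptide) * 3L + 3L, strand = "+",
                     span = nchar(focal$peptide) * 3L + 3L,
                     stop_pos = nchar(focal$peptide) * 3L + 3L,
                     protein = focal$peptide, caller = "x",
                     stringsAsFactors = FALSE)
  cand <- screen_reads(reads, focal)
  expect_equal(nrow(cand), 1L)
  # decoy is the exact source protein: strictly better -> read not recruited
  dec <- data.frame(subject_id = "decoy1", phage_id = "other", peptide = prot,
                    stringsAsFactors = FALSE)
  rec <- competitive_assign(cand, composite_db("f", focal, dec), orfs)
  expect_equal(nrow(rec), 0L)

  # exact tie: identical protein under focal and decoy ids; "ORF1" < "Zdecoy"
  focal2 <- data.frame(subject_id = "ORF1", peptide = prot,
                       stringsAsFactors = FALSE)
  orfs2 <- orfs; orfs2$protein <- prot
  dec2 <- data.frame(subject_id = "Zdecoy", phage_id = "other", peptide = prot,
                     stringsAsFactors = FALSE)
  cand2 <- screen_reads(reads, focal2)
  rec2 <- competitive_assign(cand2, composite_db("f", focal2, dec2), orfs2)
  expect_equal(nrow(rec2), 1L)  # tie resolved toward the focal subject
  # and with a decoy id sorting before the focal id, the tie goes the other way
  dec3 <- data.frame(subject_id = "AAdecoy", phage_id = "other", peptide = prot,
                     stringsAsFactors = FALSE)
  rec3 <- competitive_assign(cand2, composite_db("f", focal2, dec3), orfs2)
  expect_equal(nrow(rec3), 0L)
})

test_that("composite databases require focal proteins and unique subject ids", {
  prot <- data.frame(subject_id = "ORF1", peptide = "MKLVAAE",
                     stringsAsFactors = FALSE)
  db <- composite_db("f", prot)
  attr(db, "focal_phage_id") <- "missing"
  expect_error(competitive_assign(data.frame(id = "r", seq = "ACGTACGTA"),
                                  db, NULL),
               class = "fragrec_input_error")
  dup <- data.frame(subject_id = "ORF1", phage_id = "o", peptide = "MML",
                    stringsAsFactors = FALSE)
  expect_error(composite_db("f", prot, dup), class = "fragrec_input_error")
})

test_that("protein-to-genome mapping arithmetic is exact on both strands", {
  orfs <- data.frame(index = c(1L, 2L), genome_id = "g",
                     start = c(101L, 200L), end = c(160L, 259L),
                     strand = c("+", "-"), span = c(60L, 60L),
                     stop_pos = c(160L, 200L),
                     protein = c(strrep("A", 19), strrep("A", 19)),
                     caller = "x", stringsAsFactors = FALSE)
  expect_equal(map_to_genome("ORF1", 1, 10, orfs)[, c("start", "end")],
               data.frame(start = 101L, end = 130L))
  expect_equal(map_to_genome("ORF2", 1, 10, orfs)[, c("start", "end")],
               data.frame(start = 230L, end = 259L))
  # a full-protein hit stays inside the ORF, excluding the stop codon
  expect_equal(map_to_genome("ORF1", 1, 19, orfs)[, c("start", "end")],
               data.frame(start = 101L, end = 157L))
  expect_error(map_to_genome("ORF1", 1, 20, orfs), class = "fragrec_input_error")
})

test_that("every recruitment interval lies within its ORF", {
  g <- simulate_phage_genome("inorf", length_bp = 10000, seed = 63)
  o <- call_orfs(g)
  sim <- sample_reads(community_config(list(g), 1, n_reads = 200, seed = 10,
                                       background_fraction = 0.2))
  cand <- screen_reads(sim$reads, orf_proteins(o))
  rec <- competitive_assign(cand, composite_db(g$id, orf_proteins(o)), o)
  expect_gt(nrow(rec), 0)
  for (i in seq_len(nrow(rec))) {
    orf <- o[o$index == rec$orf_index[i], ]
    expect_gte(rec$genome_start[i], orf$start)
    expect_lte(rec$genome_end[i], orf$end)
    expect_equal(rec$genome_end[i] - rec$genome_start[i] + 1L,
                 3L * ((rec$genome_end[i] - rec$genome_start[i] + 1L) %/% 3L))
  }
})

test_that("recruitment tables round-trip through TSV, including empty tables", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_recruitment_table(empty <- fragrec:::empty_recruitment_table(), p)
  back <- read_recruitment_table(p)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back), c("metagenome_id", "read_id", "genome_start",
                              "genome_end", "pct_identity", "evalue",
                              "bitscore", "orf_index"))
  g <- simulate_phage_genome("rt", length_bp = 8000, seed = 64)
  o <- call_orfs(g)
  sim <- sample_reads(community_config(list(g), 1, n_reads = 100, seed = 11,
                                       background_fraction = 0.2))
  cand <- screen_reads(sim$reads, orf_proteins(o))
  rec <- competitive_assign(cand, composite_db(g$id, orf_proteins(o)), o)
  write_recruitment_table(rec, p)
  back <- read_recruitment_table(p)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$genome_start, rec$genome_start)
  expect_equal(back$read_id, rec$read_id)
  expect_equal(back$pct_identity, rec$pct_identity, tolerance = 1e-12)
})

test_that("origin-spanning ORF hits appear once with unwrapped coordinates", {
  gene <- paste0("ATG", paste0(rep("CAT", 70), collapse = ""), "TAA")
  pad <- "TTAATAGTGATTAATAGTGA"
  base <- paste0(pad, gene, pad)
  L <- nchar(base)
  rot <- 40L
  g <- genome_record("ospan", paste0(substr(base, L - rot + 1L, L),
                                     substr(base, 1L, L - rot)),
                     circular = TRUE)
  o <- call_orfs(g)
  expect_gt(max(o$end), L)  # the gene wraps
  wor <- o[which.max(o$span), ]  # the constructed origin-spanning gene
  rd <- data.frame(id = "r1",
                   seq = extract_interval(g, wor$start + 3L, wor$start + 122L,
                                          wor$strand),
                   source_metagenome = "m", stringsAsFactors = FALSE)
  cand <- screen_reads(rd, orf_proteins(o))
  rec <- competitive_assign(cand, composite_db(g$id, orf_proteins(o)), o)
  expect_equal(nrow(rec), 1L)
  expect_lte(rec$genome_start, L)
  p <- withr::local_tempfile()
  write_recruitment_table(rec, p)
  expect_equal(nrow(read_recruitment_table(p)), 1L)
})
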