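test_that("a constructed 120-nt gene in stop-rich context yields exactly one ORF", {
  g <- single_orf_genome(n_codons = 38)  # ATG + 38 codons + TAA = 120 nt
  o <- call_orfs(g)
  expect_equal(nrow(o), 1L)
  expect_equal(o$span, 120L)
  expect_equal(o$strand, "+")
  expect_equal(nchar(o$protein), 39L)  # span/3 - 1, stop excluded
  expect_false(grepl("\\*", o$protein))
})

test_that("a poly-A genome yields no ORFs (no stop ever closes one)", {
  g <- genome_record("polyA", paste0(rep("A", 1000), collapse = ""))
  expect_equal(nrow(call_orfs(g)), 0L)
})

test_that("ORF calls mirror under reverse complement", {
  g <- single_orf_genome(n_codons = 38)
  o <- call_orfs(g)
  grc <- genome_record(g$id, revcomp(g$seq))
  orc <- call_orfs(grc)
  L <- genome_length(g)
  expect_equal(nrow(orc), 1L)
  expect_equal(orc$strand, "-")
  expect_equal(orc$start, L - o$end + 1L)
  expect_equal(orc$end, L - o$start + 1L)
  expect_equal(orc$protein, o$protein)
})

test_that("min_len filter is strictly greater-than", {
  # the fixture ORF spans exactly 120 nt: excluded at min_len 120, kept at 119
  g100 <- single_orf_genome(n_codons = 38)
  cfg <- orf_config(min_len_nt = 120)
  expect_equal(nrow(call_orfs(g100, cfg)), 0L)
  cfg2 <- orf_config(min_len_nt = 119)
  expect_equal(nrow(call_orfs(g100, cfg2)), 1L)
})

test_that("translate_orf matches manual codon lookup on both strands", {
  g <- genome_record("t", paste0("ATGAAATAG", paste0(rep("C", 100), collapse = "")))
  expect_equal(translate_orf(g, list(start = 1, end = 9, strand = "+")), "MK")
  grc <- genome_record("t", paste0(paste0(rep("C", 100), collapse = ""),
                                   revcomp("ATGAAATAG")))
  expect_equal(translate_orf(grc, list(start = 101, end = 109, strand = "-")), "MK")
  g1 <- genome_record("u", paste0("ATGTAA", paste0(rep("C", 100), collapse = "")))
  expect_equal(translate_orf(g1, list(start = 1, end = 6, strand = "+")), "M")
  # inconsistent coordinates surface as internal stops
  g2 <- genome_record("v", paste0("ATGTAAAAATAG", paste0(rep("C", 100), collapse = "")))
  expect_error(translate_orf(g2, list(start = 1, end = 12, strand = "+")),
               class = "fragrec_input_error")
})

test_that("stored proteins are coherent with their coordinates", {
  g <- simulate_phage_genome("coh", length_bp = 6000, seed = 21)
  o <- call_orfs(g)
  expect_gt(nrow(o), 3)
  for (i in seq_len(nrow(o)))
    expect_equal(translate_orf(g, o[i, ]), o$protein[i])
})

test_that("consensus keeps the longer call per shared stop/strand locus", {
  g <- simulate_phage_genome("cons", length_bp = 5000, seed = 8)
  a <- call_orfs(g)
  # caller B reports the same loci with later starts (shorter calls)
  b <- a
  trim <- a$span > 200
  b$start[trim & b$strand == "+"] <- b$start[trim & b$strand == "+"] + 30L
  b$end[trim & b$strand == "-"] <- b$end[trim & b$strand == "-"] - 30L
  b$span <- b$end - b$start + 1L
  b$protein <- vapply(seq_len(nrow(b)), function(i) translate_orf(g, b[i, ]), "")
  cons <- consensus_longer(a, b)
  expect_equal(nrow(cons), nrow(a))
  expect_equal(cons$start, a$start)
  expect_equal(cons$end, a$end)
})

test_that("consensus is idempotent, commutative, and unions single-caller loci", {
  g <- simulate_phage_genome("cc", length_bp = 5000, seed = 9)
  a <- call_orfs(g)
  expect_equal(consensus_longer(a, a)[names(a)], a[names(a)])
  half <- a[seq(1, nrow(a), by = 2), ]
  ab <- consensus_longer(a, half)
  ba <- consensus_longer(half, a)
  expect_equal(ab, ba)
  expect_equal(nrow(ab), nrow(a))  # loci only in `a` are kept
  g2 <- simulate_phage_genome("other", length_bp = 5000, seed = 10)
  expect_error(consensus_longer(a, call_orfs(g2)), class = "fragrec_input_error")
})

test_that("the documented start-choice example keeps the earlier start", {
  tmpl <- data.frame(index = 1L, genome_id = "g", start = 101L, end = 160L,
                     strand = "+", span = 60L, stop_pos = 160L,
                     protein = "X", caller = "a", stringsAsFactors = FALSE)
  b <- tmpl; b$start <- 110L; b$span <- 51L; b$caller <- "b"
  cons <- consensus_longer(tmpl, b)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 101L)
})

test_that("circular genomes find origin-spanning ORFs once, and calls rotate with the genome", {
  gene <- paste0("ATG", paste0(rep("GGA", 60), collapse = ""), "TAA")
  pad <- "TTAATAGTGATTAATAGTGA"
  base <- paste0(pad, gene, pad)
  # place the gene across the origin: rotate so it starts 50 nt before the end
  L <- nchar(base)
  rot <- 30L
  rotated <- paste0(substr(base, L - rot + 1L, L), substr(base, 1L, L - rot))
  g <- genome_record("circ", rotated, circular = TRUE)
  o <- call_orfs(g)
  # every locus appears exactly once
  expect_false(any(duplicated(paste(o$strand, o$stop_pos))))
  # the constructed gene is recovered as a single origin-spanning call
  tgt <- o[o$span == nchar(gene), ]
  expect_equal(nrow(tgt), 1L)
  expect_gt(tgt$end, L)           # unwrapped across the origin
  expect_lte(tgt$start, L)
  expect_equal(translate_orf(g, tgt[1, ]), tgt$protein[1])

  # rotation invariance: span multiset unchanged, coordinates shifted by rot
  g0 <- genome_record("circ", base, circular = TRUE)
  o0 <- call_orfs(g0)
  expect_equal(sort(o$span), sort(o0$span))
  tgt0 <- o0[o0$span == nchar(gene), ]
  expect_equal(((tgt0$start - 1L + rot) %% L) + 1L, tgt$start)
})

test_that("GFF3 export/import round-trips ORF calls for consensus use", {
  g <- simulate_phage_genome("io", length_bp = 5000, seed = 12)
  o <- call_orfs(g)
  o_lin <- o[o$end <= genome_length(g), ]  # GFF3 carries linear features
  p <- withr::local_tempfile(fileext = ".gff3")
  orfs_to_gff3(o_lin, p)
  back <- gff3_to_orfs(p, g)
  expect_equal(nrow(back), nrow(o_lin))
  expect_equal(back$start, o_lin$start)
  expect_equal(back$end, o_lin$end)
  expect_equal(back$strand, o_lin$strand)
  expect_equal(back$protein, o_lin$protein)
})
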