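# Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A genome with exactly one constructed gene (ATG + n_codons non-stop codons
# + TAA) embedded in stop-rich padding that cannot host ORFs > 100 bp.
single_orf_genome <- function(n_codons = 38, pad = "TTTTAATAGTGA",
                              id = "fix1", circular = FALSE) {
  core <- paste0("ATG", paste0(rep("GCT", n_codons), collapse = ""), "TAA")
  genome_record(id, paste0(pad, core, pad), circular = circular)
}

# Designed intrinsic terminator: ORF, 20-nt C spacer, 8-bp pure G/C stem,
# 3-nt loop, poly-T tail. Energy under the default model: 8 * (-3) + 4 = -20.
terminator_genome <- function(stem = "GGCCGCGC", loop = "TTT",
                              tail = "TTTTTTTT", spacer_len = 20) {
  orf_nt <- paste0("ATG", paste0(rep("GCA", 40), collapse = ""), "TAA")
  term <- paste0(stem, loop, revcomp(stem), tail)
  genome_record("termfix", paste0(
    paste0(rep("C", 30), collapse = ""), orf_nt,
    paste0(rep("C", spacer_len), collapse = ""), term,
    paste0(rep("GAC", 30), collapse = "")), circular = FALSE)
}

# Independent local-alignment oracle: maximum over all anchored substring
# pairs of a start-anchored global affine DP. Deliberately a different
# formulation from the package's single-pass Smith-Waterman.
oracle_local_score <- function(qa, sb, mat = blosum62(), go = 11, ge = 1) {
  a <- strsplit(qa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  m <- length(a); n <- length(b)
  best <- 0
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      mm <- m - i + 1L; nn <- n - k + 1L
      M <- matrix(-1e9, mm + 1L, nn + 1L); E <- M; F <- M
      M[1, 1] <- 0
      for (x in seq_len(mm)) {
        for (y in seq_len(nn)) {
          E[x + 1, y + 1] <- max(M[x + 1, y] - go - ge, E[x + 1, y] - ge)
          F[x + 1, y + 1] <- max(M[x, y + 1] - go - ge, F[x, y + 1] - ge)
          M[x + 1, y + 1] <- mat[a[i + x - 1], b[k + y - 1]] +
            max(M[x, y], E[x, y], F[x, y])
          if (M[x + 1, y + 1] > best) best <- M[x + 1, y + 1]
        }
      }
    }
  }
  best
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste0(sample(AA20, n, replace = TRUE),
                                     collapse = "")

# Reverse-translate a peptide with uniformly chosen synonymous codons.
reverse_translate <- function(pep) {
  code <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(code), unname(code))
  paste0(vapply(strsplit(pep, "")[[1]],
                function(a) sample(by_aa[[a]], 1L), character(1)),
         collapse = "")
}

# Small three-genome community shared by recruitment/abundance tests.
small_community <- function(seed = 42, length_bp = 8000) {
  refs <- lapply(1:3, function(i)
    simulate_phage_genome(paste0("sc", i), length_bp = length_bp,
                          seed = seed + i))
  orfs <- lapply(refs, call_orfs)
  list(refs = refs, orfs = orfs)
}
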