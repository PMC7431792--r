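# ORF prediction on (possibly circular) phage genomes and the two-caller
# consensus rule: gene finders mostly disagree on the start codon, so calls
# sharing a stop codon and strand are treated as one locus and the longer
# call wins. The built-in caller reports every maximal start-to-stop frame;
# external caller output can be imported from GFF3 and combined the same way.

#' ORF caller configuration
#'
#' @param min_len_nt minimum nucleotide span; ORFs must be strictly longer
#'   than this (default 100 bp, the conventional cutoff for phage genome
#'   maps).
#' @param genetic_code NCBI genetic code id (default "11",
#'   bacterial/archaeal/plant plastid).
#' @param start_codons allowed start codons (default ATG, GTG, TTG).
#' @return list of class `orf_config`.
#' @export
orf_config <- function(min_len_nt = 100L, genetic_code = "11",
                       start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(min_len_nt >= 3L, length(start_codons) >= 1L)
  structure(list(min_len_nt = as.integer(min_len_nt),
                 genetic_code = genetic_code,
                 start_codons = toupper(start_codons)),
            class = "orf_config")
}

genetic_code_table <- function(id = "11") {
  key <- paste0("gc_", id)
  if (is.null(.fragrec_env[[key]]))
    .fragrec_env[[key]] <- Biostrings::getGeneticCode(id)
  .fragrec_env[[key]]
}

# Translate an in-frame nucleotide string; codons containing ambiguity become
# "X", stops become "*". Trailing partial codons are dropped.
translate_nt <- function(nt, genetic_code = "11") {
  code <- genetic_code_table(genetic_code)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n)
  cod <- substring(nt, starts, starts + 2L)
  aa <- unname(code[cod])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# Scan one linear strand: all maximal start->stop ORFs in the 3 forward
# frames of `s`. Returns nt coordinates on `s` (start of start codon, end of
# stop codon).
scan_strand_orfs <- function(s, cfg) {
  n <- nchar(s)
  code <- genetic_code_table(cfg$genetic_code)
  stop_codons <- names(code)[code == "*"]
  out <- vector("list", 3L)
  for (f in 1:3) {
    nc <- (n - f + 1L) %/% 3L
    if (nc < 2L) next
    pos <- seq(f, by = 3L, length.out = nc)
    cod <- substring(s, pos, pos + 2L)
    stop_i <- which(cod %in% stop_codons)
    start_i <- which(cod %in% cfg$start_codons)
    if (!length(stop_i) || !length(start_i)) next
    # segment id for each start = number of stops at or before it + 1
    seg <- findInterval(start_i, stop_i) + 1L
    ok <- seg <= length(stop_i)           # starts after the last stop never close
    if (!any(ok)) next
    first_start <- tapply(start_i[ok], seg[ok], min)
    seg_id <- as.integer(names(first_start))
    os <- pos[unname(first_start)]
    oe <- pos[stop_i[seg_id]] + 2L
    out[[f]] <- data.frame(start = os, end = oe)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(start = integer(), end = integer()) else res
}

#' Predict ORFs on a genome
#'
#' Reports every maximal start-to-stop reading frame on both strands whose
#' nucleotide span exceeds `cfg$min_len_nt`. For circular genomes the
#' sequence is virtually extended across the origin by one full copy minus
#' one nucleotide, so origin-spanning ORFs are found exactly once; their
#' intervals keep `start` within the genome and an unwrapped `end` that may
#' exceed the genome length.
#'
#' @param genome a [genome_record()].
#' @param cfg an [orf_config()].
#' @return data.frame with columns `index`, `genome_id`, `start`, `end`,
#'   `strand`, `span`, `stop_pos` (genome coordinate anchoring the stop
#'   codon; the locus key used by [consensus_longer()]), `protein` (stop
#'   codon excluded) and `caller`; sorted by `start`.
#' @export
call_orfs <- function(genome, cfg = orf_config()) {
  stopifnot(inherits(genome, "genome_record"))
  L <- nchar(genome$seq)
  if (L < cfg$min_len_nt)
    stop_fragrec("genome shorter than min_len_nt", "fragrec_input_error")
  ext <- function(s) if (genome$circular) paste0(s, substr(s, 1L, L - 1L)) else s
  fwd_seq <- ext(genome$seq)
  rc <- revcomp(genome$seq)
  rev_seq <- ext(rc)

  reduce1 <- function(p) ((p - 1L) %% L) + 1L

  fwd <- scan_strand_orfs(fwd_seq, cfg)
  if (nrow(fwd)) {
    fwd$span <- fwd$end - fwd$start + 1L
    fwd <- fwd[fwd$span > cfg$min_len_nt & fwd$span <= L, , drop = FALSE]
  }
  rows <- list()
  if (nrow(fwd)) {
    s_red <- reduce1(fwd$start)
    e_red <- s_red + fwd$span - 1L
    df <- data.frame(start = s_red, end = e_red, strand = "+",
                     span = fwd$span, stop_pos = reduce1(e_red),
                     scan_start = fwd$start, scan_seq = "f",
                     stringsAsFactors = FALSE)
    rows[["f"]] <- df
  }
  rev <- scan_strand_orfs(rev_seq, cfg)
  if (nrow(rev)) {
    rev$span <- rev$end - rev$start + 1L
    rev <- rev[rev$span > cfg$min_len_nt & rev$span <= L, , drop = FALSE]
  }
  if (nrow(rev)) {
    s_red <- reduce1(rev$start)
    e_red <- s_red + rev$span - 1L           # rc coordinates, unwrapped
    g_start <- L - e_red + 1L
    wrap <- g_start < 1L
    g_start[wrap] <- g_start[wrap] + L
    df <- data.frame(start = g_start, end = g_start + rev$span - 1L,
                     strand = "-", span = rev$span,
                     stop_pos = g_start,     # stop codon sits at the low end
                     scan_start = rev$start, scan_seq = "r",
                     stringsAsFactors = FALSE)
    rows[["r"]] <- df
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(index = integer(), genome_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      span = integer(), stop_pos = integer(),
                      protein = character(), caller = character(),
                      stringsAsFactors = FALSE))
  }
  # De-duplicate circular copies: one locus per (strand, stop position),
  # keeping the longest (earliest-start) call.
  all <- all[order(-all$span, all$start), , drop = FALSE]
  all <- all[!duplicated(paste(all$strand, all$stop_pos)), , drop = FALSE]
  all <- all[order(all$start, all$end, all$strand), , drop = FALSE]

  # Translate from the scanned strand directly (already oriented 5'->3').
  prot <- character(nrow(all))
  for (i in seq_len(nrow(all))) {
    s <- if (all$scan_seq[i] == "f") fwd_seq else rev_seq
    nt <- substr(s, all$scan_start[i], all$scan_start[i] + all$span[i] - 1L)
    p <- translate_nt(nt, cfg$genetic_code)
    prot[i] <- sub("\\*$", "", p)
  }
  data.frame(index = seq_len(nrow(all)), genome_id = genome$id,
             start = all$start, end = all$end, strand = all$strand,
             span = all$span, stop_pos = all$stop_pos, protein = prot,
             caller = "fragrec", stringsAsFactors = FALSE)
}

#' Translate an ORF from its genome coordinates
#'
#' Minus-strand ORFs are translated from the reverse complement; the stop
#' codon is excluded. An internal stop indicates inconsistent coordinates and
#' is an error.
#'
#' @param genome a [genome_record()].
#' @param orf one row of a [call_orfs()] table (or any list with `start`,
#'   `end`, `strand`).
#' @return amino-acid string.
#' @export
translate_orf <- function(genome, orf) {
  nt <- extract_interval(genome, orf$start, orf$end, orf$strand)
  if (nchar(nt) %% 3L != 0L)
    stop_fragrec("ORF span not divisible by 3", "fragrec_input_error")
  p <- translate_nt(nt, "11")
  body <- sub("\\*$", "", p)
  if (grepl("\\*", body))
    stop_fragrec("internal stop codon: ORF coordinates are inconsistent",
                 "fragrec_input_error")
  body
}

#' Combine two ORF call sets, keeping the longer call per locus
#'
#' Calls are grouped into loci by (stop-codon position, strand); where both
#' callers report a locus the longer call is kept, and a locus reported by
#' only one caller is kept as-is. This mirrors consensus annotation with two
#' gene finders, which typically agree on the stop codon but differ in start
#' choice.
#'
#' @param calls_a,calls_b ORF tables as returned by [call_orfs()] (or
#'   imported via [gff3_to_orfs()]), from the same genome.
#' @return a consensus ORF table, re-indexed in start order.
#' @export
consensus_longer <- function(calls_a, calls_b) {
  ga <- unique(calls_a$genome_id); gb <- unique(calls_b$genome_id)
  if (length(ga) > 1L || length(gb) > 1L || (length(ga) && length(gb) && ga != gb))
    stop_fragrec("ORF call sets come from different genomes", "fragrec_input_error")
  all <- rbind(calls_a, calls_b)
  if (!nrow(all)) return(calls_a)
  ord <- order(-all$span, all$start, all$strand)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(paste(all$strand, all$stop_pos)), , drop = FALSE]
  all <- all[order(all$start, all$end, all$strand), , drop = FALSE]
  all$index <- seq_len(nrow(all))
  rownames(all) <- NULL
  all
}

#' Write an ORF proteome as FASTA
#'
#' Sequence ids are `ORF<n>` using the table's `index` column, the id
#' convention that recruitment subject ids resolve against.
#'
#' @param orfs ORF table from [call_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(orfs, path) {
  write_fasta(setNames(orfs$protein, paste0("ORF", orfs$index)), path)
}

#' Export ORF calls as GFF3 CDS features
#' @param orfs ORF table from [call_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
orfs_to_gff3 <- function(orfs, path) {
  write_gff3(data.frame(
    seqid = orfs$genome_id, type = "CDS", start = orfs$start, end = orfs$end,
    strand = orfs$strand, phase = "0",
    attributes = paste0("ID=ORF", orfs$index),
    stringsAsFactors = FALSE), path)
}

#' Import ORF calls from GFF3 (e.g. an external gene finder)
#'
#' CDS features are read, proteins re-translated from the genome, and the
#' locus key (`stop_pos`) recomputed, so imported calls can enter
#' [consensus_longer()] on equal footing with the built-in caller.
#'
#' @param path GFF3 path.
#' @param genome the [genome_record()] the features refer to.
#' @param caller label stored in the `caller` column.
#' @return an ORF table.
#' @export
gff3_to_orfs <- function(path, genome, caller = "imported") {
  g <- read_gff3(path)
  g <- g[g$type == "CDS", , drop = FALSE]
  L <- nchar(genome$seq)
  if (!nrow(g)) {
    return(data.frame(index = integer(), genome_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      span = integer(), stop_pos = integer(),
                      protein = character(), caller = character(),
                      stringsAsFactors = FALSE))
  }
  span <- g$end - g$start + 1L
  stop_pos <- ifelse(g$strand == "+", ((g$end - 1L) %% L) + 1L, g$start)
  out <- data.frame(index = seq_len(nrow(g)), genome_id = genome$id,
                    start = g$start, end = g$end, strand = g$strand,
                    span = span, stop_pos = as.integer(stop_pos),
                    protein = NA_character_, caller = caller,
                    stringsAsFactors = FALSE)
  out$protein <- vapply(seq_len(nrow(out)), function(i)
    translate_orf(genome, out[i, ]), character(1))
  out[order(out$start, out$end, out$strand), ]
}
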