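# Translated homology search: six-frame translation of nucleotide reads,
# affine-gap Smith-Waterman protein alignment against a protein database,
# Karlin-Altschul E-value/bit-score statistics and a deterministic hit
# ranking. The seeded mode filters subjects by exact 4-mer words and then
# runs the full DP on the candidates, so its hit set matches the exhaustive
# mode whenever a reportable alignment contains one exact word -- which at
# the default E-value cutoff it always does in practice.

#' Karlin-Altschul parameters for gapped protein search
#'
#' Defaults are the published gapped constants for BLOSUM62 with gap open 11
#' and gap extend 1: lambda = 0.267 per raw-score unit, K = 0.041. E-values
#' are `K * m * n * exp(-lambda * S)`; bit scores are
#' `(lambda * S - ln K) / ln 2`.
#'
#' @param lambda,K Karlin-Altschul scale and search-space constants.
#' @param gap_open,gap_extend affine gap costs (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @return list of class `ka_params`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041, gap_open = 11L,
                      gap_extend = 1L) {
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend >= 1)
  structure(list(lambda = lambda, K = K, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)), class = "ka_params")
}

#' The scoring matrix used for protein alignment
#'
#' BLOSUM62 (from Biostrings), with the stop row/column overridden to a
#' large negative score so that alignments never pair a stop codon; search
#' additionally splits translated frames at stops so extensions terminate
#' there. 'X' (ambiguous translation) keeps its BLOSUM62 scores.
#'
#' @return integer matrix with residue-name dimnames.
#' @export
blosum62 <- function() {
  if (is.null(.fragrec_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["*", ] <- -1000L
    m[, "*"] <- -1000L
    storage.mode(m) <- "integer"
    .fragrec_env$blosum62 <- m
  }
  .fragrec_env$blosum62
}

encode_peptide <- function(pep, alphabet = rownames(blosum62())) {
  x <- match(strsplit(pep, "")[[1]], alphabet)
  x[is.na(x)] <- match("X", alphabet)
  x - 1L
}

#' Six-frame translation
#'
#' Frames +1..+3 read the sequence at offsets 0..2; frames -1..-3 read the
#' reverse complement the same way. Stops are rendered "*"; trailing partial
#' codons are dropped; codons containing N translate to "X".
#'
#' @param nt nucleotide string.
#' @return data.frame with columns `frame` (+1, +2, +3, -1, -2, -3) and
#'   `peptide`.
#' @examples
#' six_frame_translate("ATGAAATAG")$peptide[1]  # "MK*"
#' @export
six_frame_translate <- function(nt) {
  nt <- toupper(nt)
  rc <- revcomp(nt)
  pep <- c(vapply(1:3, function(f) translate_nt(substring(nt, f)), character(1)),
           vapply(1:3, function(f) translate_nt(substring(rc, f)), character(1)))
  data.frame(frame = c(1L, 2L, 3L, -1L, -2L, -3L), peptide = pep,
             stringsAsFactors = FALSE)
}

#' Optimal local alignment of two peptides
#'
#' Affine-gap Smith-Waterman with the given scoring matrix; a gap of length
#' g costs `gap_open + g * gap_extend`. Percent identity is computed over
#' aligned residue pairs (gap columns excluded).
#'
#' @param query_pep,subject_pep peptide strings (non-empty).
#' @param matrix scoring matrix (default [blosum62()]).
#' @param params [ka_params()] supplying the gap costs.
#' @return list with `score`, `qstart`, `qend`, `sstart`, `send`,
#'   `pct_identity`, `matches`, `aln_cols`, `gaps`, `gapopens`. A pair with
#'   no positive-scoring alignment has `score = 0` and empty spans.
#' @export
local_align <- function(query_pep, subject_pep, matrix = blosum62(),
                        params = ka_params()) {
  if (!nzchar(query_pep) || !nzchar(subject_pep))
    stop_fragrec("peptides must be non-empty", "fragrec_input_error")
  r <- sw_pair_cpp(encode_peptide(query_pep, rownames(matrix)),
                   encode_peptide(subject_pep, rownames(matrix)),
                   matrix, params$gap_open, params$gap_extend)
  r$pct_identity <- if (r$paired > 0) 100 * r$matches / r$paired else NA_real_
  r$aln_cols <- r$cols
  r
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least S between a length-m query and a database of
#' n residues.
#'
#' @param S raw alignment score (> 0).
#' @param m query length in residues.
#' @param n database size in residues.
#' @param params [ka_params()].
#' @return E-value (vectorized over `S`).
#' @export
evalue <- function(S, m, n, params = ka_params()) {
  if (any(m <= 0) || any(n <= 0))
    stop_fragrec("search-space dimensions must be positive", "fragrec_input_error")
  params$K * m * n * exp(-params$lambda * S)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue
#' @return bit score (vectorized).
#' @export
bitscore <- function(S, params = ka_params()) {
  (params$lambda * S - log(params$K)) / log(2)
}

# Vectorized six-frame translation over a character vector of reads;
# returns data.frame(read_idx, frame, peptide). Biostrings does the heavy
# lifting so large read sets translate at C speed.
six_frame_translate_set <- function(seqs) {
  code <- genetic_code_table("11")
  rc <- revcomp(seqs)
  out <- vector("list", 6L)
  k <- 0L
  for (src in list(seqs, rc)) {
    for (f in 1:3) {
      k <- k + 1L
      sub <- substring(src, f)
      n <- (nchar(sub) %/% 3L) * 3L
      sub <- substr(sub, 1L, n)
      pep <- character(length(sub))
      nz <- which(n >= 3L)
      if (length(nz))
        pep[nz] <- as.character(Biostrings::translate(
          Biostrings::DNAStringSet(sub[nz]), genetic.code = code,
          if.fuzzy.codon = "X", no.init.codon = TRUE))
      out[[k]] <- data.frame(read_idx = seq_along(seqs),
                             frame = if (k <= 3L) k else -(k - 3L),
                             peptide = pep, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Split a peptide at stops; returns data.frame(offset, seg) where offset is
# the 0-based position of the segment within the peptide.
split_at_stops <- function(pep) {
  if (!grepl("*", pep, fixed = TRUE))
    return(data.frame(offset = 0L, seg = pep, stringsAsFactors = FALSE))
  parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nzchar(parts)
  data.frame(offset = offs[keep], seg = parts[keep], stringsAsFactors = FALSE)
}

#' Search translated reads against a protein database
#'
#' Each read is translated in six frames, frames are split at stop codons,
#' and each stop-free segment is locally aligned against the database. Hits
#' with E-value at or below `cutoff` are returned, one best alignment per
#' (read, frame, subject). Within a read, hits are ranked by bit score
#' (descending), then E-value (ascending), then subject id (ascending) -- a
#' total order, so repeated runs are byte-identical.
#'
#' The E-value query length m is the length of the stop-free segment actually
#' searched; the database size n defaults to the total residue count of the
#' protein database and can be overridden (`n_eff`) to model a larger search
#' space.
#'
#' @param reads data.frame with columns `id` and `seq` (a `source_metagenome`
#'   column, if present, is carried through).
#' @param protein_db data.frame with columns `subject_id` and `peptide`, or a
#'   named character vector of peptides.
#' @param cutoff maximum E-value (default 1e-5).
#' @param mode "seeded" (default) or "exhaustive"; both return the same hit
#'   set whenever reportable alignments contain an exact 4-mer word.
#' @param params [ka_params()].
#' @param n_eff effective database size in residues (default: total residues
#'   in `protein_db`).
#' @param word seed word size for the seeded mode (default 4).
#' @return data.frame of hits: `read_id`, `frame`, `subject_id`,
#'   `raw_score`, `bitscore`, `evalue`, `pct_identity`, `qstart`, `qend`
#'   (residue coordinates on the frame peptide), `sstart`, `send`,
#'   `aln_cols`, `matches`, `mismatches`, `gapopens`, `rank`.
#' @export
search_translated <- function(reads, protein_db, cutoff = 1e-5,
                              mode = c("seeded", "exhaustive"),
                              params = ka_params(), n_eff = NULL, word = 4L) {
  mode <- match.arg(mode)
  db <- as_protein_db(protein_db)
  if (!nrow(db)) stop_fragrec("protein database is empty", "fragrec_input_error")
  if (!nrow(reads)) return(empty_hit_table())
  mat <- blosum62()
  alpha <- paste0(rownames(mat), collapse = "")
  if (is.null(n_eff)) n_eff <- sum(nchar(db$peptide))

  # Build query units: one per stop-free segment of each frame peptide.
  fr <- six_frame_translate_set(reads$seq)
  fr <- fr[nzchar(fr$peptide), , drop = FALSE]
  if (!nrow(fr)) return(empty_hit_table())
  parts <- strsplit(fr$peptide, "*", fixed = TRUE)
  offs <- lapply(parts, function(p) cumsum(c(0L, nchar(p) + 1L))[seq_along(p)])
  qseg <- unlist(parts, use.names = FALSE)
  qoff <- unlist(offs, use.names = FALSE)
  qrow <- rep(seq_len(nrow(fr)), lengths(parts))
  keep <- nzchar(qseg)
  qseg <- qseg[keep]; qoff <- qoff[keep]; qrow <- qrow[keep]
  if (!length(qseg)) return(empty_hit_table())
  qread <- fr$read_idx[qrow]
  qframe <- fr$frame[qrow]

  raw <- translated_search_cpp(qseg, db$peptide, alpha, mat, params$gap_open,
                               params$gap_extend, params$lambda, params$K,
                               as.numeric(n_eff), cutoff,
                               mode == "seeded", as.integer(word))
  if (!nrow(raw)) return(empty_hit_table())
  hits <- data.frame(
    read_id = reads$id[qread[raw$qidx]],
    frame = qframe[raw$qidx],
    subject_id = db$subject_id[raw$sidx],
    raw_score = raw$raw_score, bitscore = raw$bitscore, evalue = raw$evalue,
    pct_identity = ifelse(raw$paired > 0, 100 * raw$matches / raw$paired, NA_real_),
    qstart = raw$qstart + qoff[raw$qidx], qend = raw$qend + qoff[raw$qidx],
    sstart = raw$sstart, send = raw$send, aln_cols = raw$cols,
    matches = raw$matches, mismatches = raw$paired - raw$matches,
    gapopens = raw$gapopens, stringsAsFactors = FALSE)

  # Best alignment per (read, frame, subject): multiple segments of one frame
  # may hit the same subject.
  ord <- order(match(hits$read_id, reads$id), hits$frame, hits$subject_id,
               -hits$raw_score, hits$evalue, hits$qstart)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$read_id, hits$frame, hits$subject_id)), ,
               drop = FALSE]

  # Deterministic ranking within each read.
  ord <- order(match(hits$read_id, reads$id), -hits$bitscore, hits$evalue,
               hits$subject_id, hits$frame)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$read_id,
                          FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

as_protein_db <- function(protein_db) {
  if (is.character(protein_db))
    protein_db <- data.frame(subject_id = names(protein_db),
                             peptide = unname(protein_db),
                             stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "peptide") %in% names(protein_db)))
  if (anyDuplicated(protein_db$subject_id))
    stop_fragrec("duplicate subject ids in protein database", "fragrec_input_error")
  protein_db
}

empty_hit_table <- function() {
  data.frame(read_id = character(), frame = integer(), subject_id = character(),
             raw_score = integer(), bitscore = numeric(), evalue = numeric(),
             pct_identity = numeric(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), aln_cols = integer(),
             matches = integer(), mismatches = integer(), gapopens = integer(),
             rank = integer(), stringsAsFactors = FALSE)
}

#' Write hits in 12-column tabular search format
#'
#' The canonical tabular columns: query, subject, %identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param hits hit table from [search_translated()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(query = hits$read_id, subject = hits$subject_id,
                    pident = sprintf("%.3f", hits$pct_identity),
                    length = hits$aln_cols, mismatches = hits$mismatches,
                    gapopens = hits$gapopens, qstart = hits$qstart,
                    qend = hits$qend, sstart = hits$sstart, send = hits$send,
                    evalue = format(hits$evalue, digits = 3),
                    bitscore = sprintf("%.1f", hits$bitscore))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
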