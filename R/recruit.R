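# Two-stage competitive fragment recruitment. Stage 1 screens reads against
# the focal phage proteome by translated search; stage 2 re-searches the
# candidates against a composite database (focal proteome + many decoy phage
# proteomes) and recruits a read only if its best hit belongs to the focal
# phage. Recruited reads are mapped back onto focal genome coordinates
# through the ORF the best hit landed on.

#' Build a composite phage protein database
#'
#' @param focal_phage_id id of the focal phage.
#' @param focal_proteins data.frame `subject_id`, `peptide` (or named
#'   character vector), e.g. from [call_orfs()] proteins named `ORF<n>`.
#' @param decoys optional data.frame with columns `subject_id`, `phage_id`,
#'   `peptide` holding proteins of competitor phages.
#' @return object of class `composite_db`: data.frame `subject_id`,
#'   `phage_id`, `peptide` with attribute `focal_phage_id`.
#' @export
composite_db <- function(focal_phage_id, focal_proteins, decoys = NULL) {
  fp <- as_protein_db(focal_proteins)
  fp$phage_id <- focal_phage_id
  db <- fp[, c("subject_id", "phage_id", "peptide")]
  if (!is.null(decoys) && nrow(decoys)) {
    stopifnot(all(c("subject_id", "phage_id", "peptide") %in% names(decoys)))
    db <- rbind(db, decoys[, c("subject_id", "phage_id", "peptide")])
  }
  if (anyDuplicated(db$subject_id))
    stop_fragrec("subject ids must be unique across the composite database",
                 "fragrec_input_error")
  structure(db, class = c("composite_db", "data.frame"),
            focal_phage_id = focal_phage_id)
}

#' ORF proteins as a searchable database
#'
#' @param orfs ORF table from [call_orfs()].
#' @return data.frame `subject_id` (`ORF<n>`), `peptide`.
#' @export
orf_proteins <- function(orfs) {
  data.frame(subject_id = paste0("ORF", orfs$index), peptide = orfs$protein,
             stringsAsFactors = FALSE)
}

#' Stage 1: screen reads against the focal proteome
#'
#' @param reads read table (`id`, `seq`, optionally `source_metagenome`).
#' @param focal_proteome protein db (`subject_id`, `peptide`) of the focal
#'   phage, e.g. [orf_proteins()].
#' @param cutoff E-value cutoff (default 1e-5).
#' @param mode,params passed to [search_translated()].
#' @return the subset of `reads` with at least one hit at `E <= cutoff`,
#'   with the stage-1 hit table attached as attribute `"hits"`.
#' @export
screen_reads <- function(reads, focal_proteome, cutoff = 1e-5,
                         mode = "seeded", params = ka_params()) {
  hits <- search_translated(reads, focal_proteome, cutoff = cutoff,
                            mode = mode, params = params)
  cand <- reads[reads$id %in% unique(hits$read_id), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "hits") <- hits
  cand
}

#' Stage 2: competitive best-hit assignment against the composite database
#'
#' All hits of each candidate read against the full composite database at
#' `E <= cutoff` are ranked (bit score descending, E-value ascending,
#' subject id ascending); the read is recruited iff the top-ranked hit's
#' phage is the focal phage. Recruited reads are mapped onto the focal
#' genome through the ORF their best hit subject corresponds to; percent
#' identity, E-value and bit score are reported from this stage-2 alignment.
#'
#' @param candidates read table from [screen_reads()].
#' @param db a [composite_db()]; must contain the focal phage's proteins
#'   with subject ids `ORF<n>` matching `orfs`.
#' @param orfs focal ORF table from [call_orfs()] (for genome mapping).
#' @param cutoff E-value cutoff (default 1e-5).
#' @param mode,params passed to [search_translated()].
#' @return recruitment table: `read_id`, `source_metagenome`, `orf_index`,
#'   `genome_start`, `genome_end`, `strand`, `pct_identity`, `evalue`,
#'   `bitscore`.
#' @export
competitive_assign <- function(candidates, db, orfs, cutoff = 1e-5,
                               mode = "seeded", params = ka_params()) {
  focal <- attr(db, "focal_phage_id")
  if (is.null(focal) || !any(db$phage_id == focal))
    stop_fragrec("composite database lacks focal phage proteins",
                 "fragrec_input_error")
  if (!nrow(candidates)) return(empty_recruitment_table())
  hits <- search_translated(candidates,
                            db[, c("subject_id", "peptide")],
                            cutoff = cutoff, mode = mode, params = params)
  if (!nrow(hits)) return(empty_recruitment_table())
  best <- hits[hits$rank == 1L, , drop = FALSE]
  best$phage_id <- db$phage_id[match(best$subject_id, db$subject_id)]
  rec <- best[best$phage_id == focal, , drop = FALSE]
  if (!nrow(rec)) return(empty_recruitment_table())

  src <- if ("source_metagenome" %in% names(candidates))
    candidates$source_metagenome[match(rec$read_id, candidates$id)]
  else rep(NA_character_, nrow(rec))

  iv <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
    map_to_genome(rec$subject_id[i], rec$sstart[i], rec$send[i], orfs)))
  out <- data.frame(read_id = rec$read_id, source_metagenome = src,
                    orf_index = iv$orf_index, genome_start = iv$start,
                    genome_end = iv$end, strand = iv$strand,
                    pct_identity = rec$pct_identity, evalue = rec$evalue,
                    bitscore = rec$bitscore, stringsAsFactors = FALSE)
  out <- out[order(out$genome_start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a protein-coordinate hit back onto the genome
#'
#' A hit covering amino acids `a1..a2` of ORF with genome interval
#' `[g1, g2]` maps to `[g1 + 3(a1-1), g1 + 3*a2 - 1]` on the plus strand and
#' mirror-image from `g2` downward on the minus strand; the mapped length is
#' `3 * (a2 - a1 + 1)` nt.
#'
#' @param subject_id focal subject id of the form `ORF<n>`.
#' @param a1,a2 aligned amino-acid span on the subject protein (1-based).
#' @param orfs focal ORF table.
#' @return data.frame with `orf_index`, `start`, `end`, `strand`.
#' @export
map_to_genome <- function(subject_id, a1, a2, orfs) {
  idx <- as.integer(sub("^ORF", "", subject_id))
  row <- orfs[orfs$index == idx, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_fragrec(sprintf("subject '%s' is not a focal ORF", subject_id),
                 "fragrec_input_error")
  if (a2 > nchar(row$protein) || a1 < 1L)
    stop_fragrec("aligned span exceeds the protein", "fragrec_input_error")
  if (row$strand == "+") {
    start <- row$start + 3L * (a1 - 1L)
    end <- row$start + 3L * a2 - 1L
  } else {
    end <- row$end - 3L * (a1 - 1L)
    start <- row$end - 3L * a2 + 1L
  }
  data.frame(orf_index = idx, start = start, end = end, strand = row$strand,
             stringsAsFactors = FALSE)
}

empty_recruitment_table <- function() {
  data.frame(read_id = character(), source_metagenome = character(),
             orf_index = integer(), genome_start = integer(),
             genome_end = integer(), strand = character(),
             pct_identity = numeric(), evalue = numeric(),
             bitscore = numeric(), stringsAsFactors = FALSE)
}

#' Write a recruitment table as TSV
#'
#' Columns: metagenome_id, read_id, genome_start, genome_end, pct_identity,
#' evalue, bitscore, orf_index; sorted by genome_start then read_id. This
#' table is the data behind a fragment-recruitment plot (one horizontal line
#' per recruited read). Origin-spanning records keep unwrapped coordinates
#' (end may exceed the genome length), so each read appears once.
#'
#' @param records recruitment table from [competitive_assign()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recruitment_table <- function(records, path) {
  out <- data.frame(metagenome_id = records$source_metagenome,
                    read_id = records$read_id,
                    genome_start = records$genome_start,
                    genome_end = records$genome_end,
                    pct_identity = records$pct_identity,
                    evalue = records$evalue, bitscore = records$bitscore,
                    orf_index = records$orf_index, stringsAsFactors = FALSE)
  out <- out[order(out$genome_start, out$read_id), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recruitment table written by [write_recruitment_table()]
#' @param path TSV path.
#' @return data.frame with the table's columns.
#' @export
read_recruitment_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
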