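# Normalized cross-metagenome abundance of recruited reads. Two normalizers
# are supported: recruited hits per predicted ORF per gigabase of metagenome
# (the default) and hits per kb of genome per gigabase. A "gigabyte" of
# metagenome means 1e9 bases of read sequence, which is reproducible and
# format-independent; callers that prefer compressed file size can pass that
# instead. Every output row is stamped with the normalizer used so tables
# from different normalizers can never be silently mixed.

#' Per-ORF normalized recruitment
#'
#' `N = n_hits / (n_orfs * db_gb)`: recruited reads per predicted ORF per
#' gigabyte of metagenome.
#'
#' @param n_hits recruited-read count (>= 0).
#' @param n_orfs number of predicted ORFs in the focal genome (>= 1).
#' @param db_gb metagenome size in gigabytes (> 0); by package convention,
#'   1e9 bases of read sequence.
#' @return normalized abundance (vectorized).
#' @examples
#' normalize_per_orf(332, 166, 2)  # 1
#' @export
normalize_per_orf <- function(n_hits, n_orfs, db_gb) {
  if (any(n_orfs < 1) || any(db_gb <= 0))
    stop_fragrec("n_orfs must be >= 1 and db_gb > 0", "fragrec_input_error")
  if (any(n_hits < 0)) stop_fragrec("negative hit count", "fragrec_input_error")
  n_hits / (n_orfs * db_gb)
}

#' Per-genome-length normalized recruitment
#'
#' `N = n_hits / (genome_len_kb * db_gb)`: recruited reads per kb of genome
#' per gigabyte of metagenome.
#'
#' @param n_hits recruited-read count (>= 0).
#' @param genome_len_kb genome length in kilobases (> 0).
#' @param db_gb metagenome size in gigabytes (> 0).
#' @return normalized abundance (vectorized).
#' @export
normalize_per_length <- function(n_hits, genome_len_kb, db_gb) {
  if (any(genome_len_kb <= 0) || any(db_gb <= 0))
    stop_fragrec("genome_len_kb and db_gb must be positive", "fragrec_input_error")
  if (any(n_hits < 0)) stop_fragrec("negative hit count", "fragrec_input_error")
  n_hits / (genome_len_kb * db_gb)
}

#' Build abundance rows for one or more phage/metagenome combinations
#'
#' @param phage_id,metagenome_id identifiers (recycled to a common length).
#' @param n_hits recruited-read counts.
#' @param n_orfs ORF counts (needed for `normalizer = "per_orf"`).
#' @param genome_len_bp genome lengths in bp (needed for `"per_length"`).
#' @param db_gb metagenome sizes in gigabytes.
#' @param normalizer `"per_orf"` (default) or `"per_length"`.
#' @return data.frame with identifying columns, the inputs, `normalizer`,
#'   and `normalized`.
#' @export
abundance_row <- function(phage_id, metagenome_id, n_hits, n_orfs = NA,
                          genome_len_bp = NA, db_gb,
                          normalizer = c("per_orf", "per_length")) {
  normalizer <- match.arg(normalizer)
  normalized <- if (normalizer == "per_orf")
    normalize_per_orf(n_hits, n_orfs, db_gb)
  else normalize_per_length(n_hits, genome_len_bp / 1000, db_gb)
  data.frame(phage_id = phage_id, metagenome_id = metagenome_id,
             n_hits = n_hits, n_orfs = n_orfs, genome_len_bp = genome_len_bp,
             db_size_gb = db_gb, normalizer = normalizer,
             normalized = normalized, stringsAsFactors = FALSE)
}

#' Rank phages within one metagenome by normalized abundance
#'
#' Descending by `normalized`; ties broken by phage id (ascending). The
#' result is invariant under permuting the input rows. Rows built with
#' different normalizers cannot be ranked together.
#'
#' @param rows abundance rows from [abundance_row()], one per phage, all for
#'   the same metagenome and normalizer.
#' @return the rows sorted by rank, with a `rank` column prepended.
#' @export
rank_phages <- function(rows) {
  if (length(unique(rows$normalizer)) > 1L)
    stop_fragrec("cannot rank rows computed with different normalizers",
                 "fragrec_input_error")
  if (length(unique(rows$metagenome_id)) > 1L)
    stop_fragrec("rank_phages expects a single metagenome", "fragrec_input_error")
  ord <- order(-rows$normalized, rows$phage_id)
  out <- rows[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Per-ORF coverage across metagenomes, split by habitat
#'
#' For every focal ORF, counts the distinct metagenomes (per habitat class)
#' contributing at least one recruited read overlapping the ORF, then
#' summarises how many ORFs are covered by at least 1, at least 2
#' ("multiple") and at least `k` ("extensive") metagenomes of each habitat.
#'
#' @param records recruitment table(s) from [competitive_assign()] (rbind
#'   several metagenomes' tables together).
#' @param orfs focal ORF table.
#' @param habitats data.frame `metagenome_id`, `habitat` (e.g. "freshwater",
#'   "marine"); every metagenome in `records` must be listed.
#' @param k threshold for "extensively mapped" (default 5).
#' @return list with `per_orf` (data.frame `orf_index` and one metagenome
#'   count column per habitat) and `summary` (data.frame `habitat`,
#'   `n_orfs_ge1`, `n_orfs_ge2`, `n_orfs_gek`, `k`).
#' @export
coverage_summary <- function(records, orfs, habitats, k = 5L) {
  unknown <- setdiff(unique(records$source_metagenome), habitats$metagenome_id)
  if (length(unknown))
    stop_fragrec(sprintf("metagenome without habitat label: %s",
                         paste(unknown, collapse = ", ")),
                 "fragrec_input_error")
  habs <- sort(unique(habitats$habitat))
  per <- data.frame(orf_index = orfs$index)
  for (h in habs) per[[h]] <- 0L
  if (nrow(records)) {
    records$habitat <- habitats$habitat[match(records$source_metagenome,
                                              habitats$metagenome_id)]
    for (oi in seq_len(nrow(orfs))) {
      o <- orfs[oi, ]
      ov <- records$genome_start <= o$end & records$genome_end >= o$start
      if (!any(ov)) next
      sub <- records[ov, , drop = FALSE]
      cnt <- tapply(sub$source_metagenome, sub$habitat,
                    function(x) length(unique(x)))
      for (h in intersect(names(cnt), habs))
        per[[h]][oi] <- as.integer(cnt[[h]])
    }
  }
  summ <- do.call(rbind, lapply(habs, function(h) data.frame(
    habitat = h, n_orfs_ge1 = sum(per[[h]] >= 1L),
    n_orfs_ge2 = sum(per[[h]] >= 2L), n_orfs_gek = sum(per[[h]] >= k),
    k = as.integer(k), stringsAsFactors = FALSE)))
  list(per_orf = per, summary = summ)
}

#' Write an abundance table as TSV
#' @param rows (ranked) abundance rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
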