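# Sequence and feature I/O plus the coordinate conventions used by every
# other module. Coordinates are 1-based and fully inclusive throughout, with
# the canonical internal form start <= end plus an explicit strand flag;
# published feature tables sometimes encode the minus strand as start > end,
# so interval() accepts either dialect and normalizes.

#' Construct a genome record
#'
#' @param id sequence identifier (no whitespace).
#' @param seq nucleotide string over A, C, G, T, N (case-insensitive).
#' @param circular is the genome circular (e.g. a circularly permuted phage
#'   genome)? Circular genomes are virtually unwrapped across the origin by
#'   downstream callers.
#' @param desc optional free-text description.
#' @return an object of class `genome_record` with fields `id`, `seq`
#'   (uppercased), `circular`, `desc`.
#' @examples
#' g <- genome_record("phage1", "acgtACGT", circular = TRUE)
#' nchar(g$seq)
#' @export
genome_record <- function(id, seq, circular = FALSE, desc = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop_fragrec("genome sequence must be non-empty", "fragrec_input_error")
  if (grepl("[^ACGTN]", seq))
    stop_fragrec(sprintf("sequence of '%s' contains characters outside {A,C,G,T,N}", id),
                 "fragrec_input_error")
  structure(list(id = id, seq = seq, circular = isTRUE(circular), desc = desc),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp%s, GC %.1f%%\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) " (circular)" else "", gc_content(x$seq)))
  invisible(x)
}

#' Genome length in bp
#' @param genome a `genome_record`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' Read a FASTA file
#'
#' Sequences are uppercased and unwrapped; the identifier is the header token
#' before the first whitespace, the remainder is kept as `desc`. An empty file
#' yields a zero-row data frame. A record line appearing before any ">" header
#' is a format error reported with its line number.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `desc`, `seq`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop_fragrec(sprintf("file not found: %s", path), "fragrec_input_error")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE))
  first_content <- which(keep)[1]
  if (!startsWith(lines[first_content], ">"))
    stop_fragrec(sprintf("malformed FASTA: line %d is not a '>' header", first_content),
                 "fragrec_format_error")
  hdr <- startsWith(lines, ">")
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  body <- lines[!hdr & keep]
  bgrp <- grp[!hdr & keep]
  seqs <- vapply(seq_along(headers), function(i)
    toupper(paste0(body[bgrp == i], collapse = "")), character(1))
  data.frame(id = id, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param records data.frame with `id` and `seq` (and optionally `desc`), a
#'   named character vector, or a single `genome_record`.
#' @param path output path.
#' @param width line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "genome_record"))
    records <- data.frame(id = records$id, desc = records$desc,
                          seq = records$seq, stringsAsFactors = FALSE)
  if (is.character(records))
    records <- data.frame(id = names(records), desc = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  if (is.null(records$desc)) records$desc <- ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste0(">", records$id[i], " ", records$desc[i]) else paste0(">", records$id[i])
    writeLines(hdr, con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read reads from FASTA or FASTQ
#'
#' Format is detected from the first character ("@" = FASTQ, ">" = FASTA);
#' FASTQ qualities are ignored. Every read is labelled with a source
#' metagenome, which downstream recruitment tables carry through.
#'
#' @param path path to the reads file.
#' @param source_metagenome label for the metagenome these reads came from
#'   (default: file name without extension).
#' @return data.frame with columns `id`, `seq`, `source_metagenome`.
#' @export
read_reads <- function(path, source_metagenome = NULL) {
  if (is.null(source_metagenome))
    source_metagenome <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(id = character(), seq = character(),
                      source_metagenome = character(), stringsAsFactors = FALSE))
  if (startsWith(lines[1], "@")) {
    if (length(lines) %% 4L != 0L)
      stop_fragrec("malformed FASTQ: line count not a multiple of 4", "fragrec_format_error")
    id <- sub("\\s.*$", "", sub("^@", "", lines[seq(1, length(lines), by = 4)]))
    seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  } else {
    fa <- read_fasta(path)
    id <- fa$id
    seqs <- fa$seq
  }
  data.frame(id = id, seq = seqs, source_metagenome = source_metagenome,
             stringsAsFactors = FALSE)
}

#' Construct genomic intervals
#'
#' Accepts either the canonical dialect (start <= end with an explicit strand)
#' or the table dialect in which a minus-oriented feature is printed with
#' start > end; start/end are swapped into canonical form. Vectorized.
#'
#' @param start,end 1-based inclusive endpoints.
#' @param strand "+" or "-" (recycled).
#' @return data.frame with columns `start`, `end`, `strand`, start <= end.
#' @examples
#' interval(26973, 26924, "+")  # printed-table dialect, normalized
#' @export
interval <- function(start, end, strand = "+") {
  stopifnot(all(strand %in% c("+", "-")))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L & end < 1L)) stop_fragrec("interval positions must be >= 1", "fragrec_input_error")
  swap <- start > end
  s <- ifelse(swap, end, start)
  e <- ifelse(swap, start, end)
  if (any(s < 1L)) stop_fragrec("interval positions must be >= 1", "fragrec_input_error")
  data.frame(start = s, end = e, strand = rep_len(strand, length(s)),
             stringsAsFactors = FALSE)
}

#' Interval length in bp
#'
#' `abs(end - start) + 1`: invariant under swapping the endpoints and under
#' strand flips, so it reproduces printed "Length (bp)" columns in either
#' coordinate dialect.
#'
#' @param start an interval data.frame (from [interval()]) or a start vector.
#' @param end end vector when `start` is numeric.
#' @return integer vector of lengths.
#' @examples
#' interval_length(26973, 26924)  # 50
#' @export
interval_length <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  as.integer(abs(as.numeric(end) - as.numeric(start)) + 1)
}

#' GC content of nucleotide sequences
#'
#' Percent `100 * (G + C) / (A + C + G + T)`; N (and other ambiguity codes)
#' are excluded from the denominator. A sequence with no unambiguous base has
#' undefined GC content and is an error.
#'
#' @param seq character vector of nucleotide sequences.
#' @return numeric vector of percentages in `[0, 100]`.
#' @examples
#' gc_content("GATC")  # 50
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop_fragrec("empty sequence", "fragrec_input_error")
  gc <- nchar(gsub("[^GC]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (any(acgt == 0L))
    stop_fragrec("GC content undefined: no unambiguous bases", "fragrec_input_error")
  100 * gc / acgt
}

#' AT content of nucleotide sequences
#'
#' Complement of [gc_content()] over unambiguous bases, so
#' `gc_content(s) + at_content(s) == 100` for N-free `s`.
#' @inheritParams gc_content
#' @return numeric vector of percentages.
#' @export
at_content <- function(seq) {
  seq <- toupper(seq)
  at <- nchar(gsub("[^AT]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  if (any(acgt == 0L))
    stop_fragrec("AT content undefined: no unambiguous bases", "fragrec_input_error")
  100 * at / acgt
}

#' Reverse complement
#' @param seq character vector of nucleotide sequences (A/C/G/T/N).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract an interval from a genome, unwrapping the circular origin
#'
#' For circular genomes `end` may exceed the genome length, meaning the
#' feature runs across the origin; the returned sequence wraps around. Strand
#' "-" returns the reverse complement.
#'
#' @param genome a `genome_record`.
#' @param start,end 1-based inclusive endpoints, `start` within the genome.
#' @param strand "+" or "-".
#' @return nucleotide string of length `end - start + 1`.
#' @export
extract_interval <- function(genome, start, end, strand = "+") {
  L <- nchar(genome$seq)
  if (start < 1L || start > L)
    stop_fragrec("interval start outside genome", "fragrec_input_error")
  if (end > L && !genome$circular)
    stop_fragrec("interval end beyond a linear genome", "fragrec_input_error")
  if (end - start + 1 > L)
    stop_fragrec("interval longer than the genome", "fragrec_input_error")
  s <- if (end <= L) substr(genome$seq, start, end)
  else paste0(substr(genome$seq, start, L), substr(genome$seq, 1L, end - L))
  if (strand == "-") revcomp(s) else s
}

# ---- GFF3 ----------------------------------------------------------------

#' Write features as GFF3
#'
#' 1-based inclusive coordinates, strand in column 7. For origin-spanning
#' features on circular genomes the unwrapped end (> genome length) is
#' written, which keeps start <= end.
#'
#' @param features data.frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `attributes`, and optionally `score`, `phase`.
#' @param path output path.
#' @param source value for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "fragrec") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    score <- if (is.null(features$score)) "." else
      ifelse(is.na(features$score), ".", format(features$score, trim = TRUE))
    phase <- if (is.null(features$phase)) "." else as.character(features$phase)
    writeLines(paste(features$seqid, source, features$type, features$start,
                     features$end, score, features$strand, phase,
                     features$attributes, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GFF3 file
#' @param path path to a GFF3 file.
#' @return data.frame with the nine GFF3 columns (`seqid`, `source`, `type`,
#'   `start`, `end`, `score`, `strand`, `phase`, `attributes`).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  if (!length(lines)) {
    out <- as.data.frame(setNames(rep(list(character()), 9), cols),
                         stringsAsFactors = FALSE)
    out$start <- integer(); out$end <- integer()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad))
    stop_fragrec(sprintf("malformed GFF3: line %d does not have 9 columns", bad[1]),
                 "fragrec_format_error")
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- cols
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

# Extract one key's value from a GFF3 attribute string.
gff3_attr <- function(attributes, key) {
  m <- regmatches(attributes, regexpr(paste0("(^|;)", key, "=[^;]*"), attributes))
  val <- rep(NA_character_, length(attributes))
  hit <- lengths(regmatches(attributes, gregexpr(paste0("(^|;)", key, "="), attributes))) > 0
  val[hit] <- sub(paste0("^;?", key, "="), "", m)
  val
}
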