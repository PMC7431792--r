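# Simplified rho-independent terminator screen: inverted repeats forming a
# stem-loop followed by a U-rich tract, scored with a transparent pair-sum
# energy model and filtered at a free-energy threshold (default -16 kcal/mol,
# the conventional screening threshold for phage genome annotation). The
# model is deliberately simple -- per-pair energies plus a loop penalty --
# so every reported energy is exactly reproducible from the configuration.

#' Terminator screen configuration
#'
#' @param energy_threshold report hairpins with energy at or below this
#'   (kcal/mol, must be negative; default -16).
#' @param stem_min,stem_max allowed stem lengths in bp (4..20).
#' @param loop_min,loop_max allowed loop lengths in nt (3..10).
#' @param max_orf_distance maximum gap (nt) to the nearest upstream ORF for
#'   the terminator to be annotated with it (default 200).
#' @param pair_energies named energies (kcal/mol) for allowed stem pairs;
#'   orientation-symmetric, defaults G:C = -3, A:T = -2, G:T = -1 (wobble).
#' @param loop_base,loop_slope loop penalty `loop_base + loop_slope *
#'   (loop_len - 3)` kcal/mol (defaults +4.0, +0.3).
#' @param require_poly_t require a run of at least `tail_min_t` T residues
#'   starting within `tail_window` nt downstream of the stem (default TRUE);
#'   suppresses random hairpins with no terminator-like U-tract.
#' @param tail_window,tail_min_t see `require_poly_t`.
#' @return list of class `terminator_config`.
#' @export
terminator_config <- function(energy_threshold = -16, stem_min = 4L,
                              stem_max = 20L, loop_min = 3L, loop_max = 10L,
                              max_orf_distance = 200L,
                              pair_energies = c("G:C" = -3, "A:T" = -2, "G:T" = -1),
                              loop_base = 4.0, loop_slope = 0.3,
                              require_poly_t = TRUE, tail_window = 5L,
                              tail_min_t = 4L) {
  if (energy_threshold >= 0)
    stop_fragrec("energy threshold must be negative", "fragrec_config_error")
  structure(list(energy_threshold = energy_threshold,
                 stem_min = as.integer(stem_min), stem_max = as.integer(stem_max),
                 loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
                 max_orf_distance = as.integer(max_orf_distance),
                 pair_energies = pair_energies, loop_base = loop_base,
                 loop_slope = loop_slope, require_poly_t = isTRUE(require_poly_t),
                 tail_window = as.integer(tail_window),
                 tail_min_t = as.integer(tail_min_t)),
            class = "terminator_config")
}

# 5x5 symmetric pair-energy matrix over A,C,G,T,other; NA = disallowed.
pair_energy_matrix <- function(cfg) {
  m <- matrix(NA_real_, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                              c("A", "C", "G", "T", "N")))
  for (nm in names(cfg$pair_energies)) {
    b <- strsplit(nm, ":", fixed = TRUE)[[1]]
    m[b[1], b[2]] <- cfg$pair_energies[[nm]]
    m[b[2], b[1]] <- cfg$pair_energies[[nm]]
  }
  m
}

#' Free energy of a stem-loop under the pair-sum model
#'
#' Energy = sum of per-pair energies + `loop_base + loop_slope * (loop_len -
#' 3)`. Pairs are orientation-symmetric ("G:C" and "C:G" are the same pair).
#'
#' @param stem_pairs character vector of stem pairs such as
#'   `c("G:C", "A:T")`, outermost first.
#' @param loop_len loop length in nt.
#' @param cfg a [terminator_config()].
#' @return energy in kcal/mol.
#' @examples
#' hairpin_energy(rep("G:C", 8), 3)  # -20
#' @export
hairpin_energy <- function(stem_pairs, loop_len, cfg = terminator_config()) {
  if (!length(stem_pairs))
    stop_fragrec("stem must contain at least one pair", "fragrec_input_error")
  canon <- function(p) {
    b <- strsplit(p, ":", fixed = TRUE)[[1]]
    c(paste(b, collapse = ":"), paste(rev(b), collapse = ":"))
  }
  e <- vapply(stem_pairs, function(p) {
    both <- canon(p)
    hit <- both[both %in% names(cfg$pair_energies)]
    if (!length(hit))
      stop_fragrec(sprintf("disallowed stem pair '%s'", p), "fragrec_input_error")
    cfg$pair_energies[[hit[1]]]
  }, numeric(1))
  sum(e) + cfg$loop_base + cfg$loop_slope * (loop_len - 3)
}

encode_dna <- function(s) {
  x <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  x[is.na(x)] <- 5L
  x - 1L
}

#' Find rho-independent terminator candidates
#'
#' Scans both strands for inverted repeats forming a stem-loop within the
#' configured bounds, optionally followed within a few nt by a poly-T tract
#' on the coding strand, with energy at or below the threshold. Overlapping
#' candidates are resolved by keeping the lowest energy (ties: leftmost
#' start, then "+" strand). Each call is annotated with the nearest upstream
#' ORF on the same strand within `max_orf_distance` nt, measuring the gap
#' from the ORF 3' end to the terminator 5' end.
#'
#' @param genome a [genome_record()].
#' @param orfs ORF table from [call_orfs()] (may be empty).
#' @param cfg a [terminator_config()].
#' @return data.frame with columns `terminator`, `start`, `end`, `length`,
#'   `strand`, `energy`, `stem_len`, `loop_len`, `upstream_orf`,
#'   `distance_nt`; genome coordinates, sorted by start.
#' @export
find_terminators <- function(genome, orfs = NULL, cfg = terminator_config()) {
  if (!is.null(orfs) && nrow(orfs) &&
      !all(orfs$genome_id == genome$id))
    stop_fragrec("ORFs come from a different genome", "fragrec_input_error")
  L <- nchar(genome$seq)
  pm <- pair_energy_matrix(cfg)
  scan1 <- function(s) scan_hairpins_cpp(encode_dna(s), pm, cfg$stem_min,
    cfg$stem_max, cfg$loop_min, cfg$loop_max, cfg$loop_base, cfg$loop_slope,
    cfg$energy_threshold, cfg$require_poly_t, cfg$tail_window, cfg$tail_min_t)
  fwd <- scan1(genome$seq)
  rev <- scan1(revcomp(genome$seq))
  cand <- data.frame(start = integer(), end = integer(), strand = character(),
                     energy = numeric(), stem_len = integer(),
                     loop_len = integer(), stringsAsFactors = FALSE)
  if (nrow(fwd))
    cand <- rbind(cand, data.frame(start = fwd$start, end = fwd$end,
      strand = "+", energy = fwd$energy, stem_len = fwd$stem_len,
      loop_len = fwd$loop_len, stringsAsFactors = FALSE))
  if (nrow(rev))
    cand <- rbind(cand, data.frame(start = L - rev$end + 1L,
      end = L - rev$start + 1L, strand = "-", energy = rev$energy,
      stem_len = rev$stem_len, loop_len = rev$loop_len,
      stringsAsFactors = FALSE))
  if (!nrow(cand)) return(empty_terminator_table())

  # Greedy non-overlap selection: lowest energy, then leftmost, then "+".
  cand <- cand[order(cand$energy, cand$start, cand$strand), , drop = FALSE]
  ks <- integer(0); ke <- integer(0)
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(ks) || all(cand$end[i] < ks | cand$start[i] > ke)) {
      sel <- c(sel, i)
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  cand <- cand[sel, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]

  # Upstream ORF annotation (same strand, gap within max_orf_distance).
  up <- rep(NA_integer_, nrow(cand)); dist <- rep(NA_integer_, nrow(cand))
  if (!is.null(orfs) && nrow(orfs)) {
    for (i in seq_len(nrow(cand))) {
      if (cand$strand[i] == "+") {
        same <- orfs[orfs$strand == "+", , drop = FALSE]
        gap <- cand$start[i] - same$end - 1L
      } else {
        same <- orfs[orfs$strand == "-", , drop = FALSE]
        gap <- same$start - cand$end[i] - 1L
      }
      ok <- which(gap >= 0L & gap <= cfg$max_orf_distance)
      if (length(ok)) {
        j <- ok[which.min(gap[ok])]
        up[i] <- same$index[j]
        dist[i] <- gap[j]
      }
    }
  }
  data.frame(terminator = paste0("Term", seq_len(nrow(cand))),
             start = cand$start, end = cand$end,
             length = cand$end - cand$start + 1L, strand = cand$strand,
             energy = cand$energy, stem_len = cand$stem_len,
             loop_len = cand$loop_len, upstream_orf = up, distance_nt = dist,
             stringsAsFactors = FALSE)
}

empty_terminator_table <- function() {
  data.frame(terminator = character(), start = integer(), end = integer(),
             length = integer(), strand = character(), energy = numeric(),
             stem_len = integer(), loop_len = integer(),
             upstream_orf = integer(), distance_nt = integer(),
             stringsAsFactors = FALSE)
}

#' Write a terminator table as TSV
#'
#' Columns follow the conventional annotation-table order: Terminator,
#' Start, End, Length, Strand, Energy, Upstream ORF, Distance.
#' @param terms table from [find_terminators()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_terminator_table <- function(terms, path) {
  out <- data.frame(Terminator = terms$terminator, Start = terms$start,
                    End = terms$end, `Length (bp)` = terms$length,
                    Strand = terms$strand, `Energy (kCal)` = terms$energy,
                    `Upstream ORF` = terms$upstream_orf,
                    `Distance to ORF` = terms$distance_nt,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export terminator calls as GFF3
#' @param terms table from [find_terminators()].
#' @param genome_id seqid for column 1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
terminators_to_gff3 <- function(terms, genome_id, path) {
  write_gff3(data.frame(
    seqid = genome_id, type = "terminator", start = terms$start,
    end = terms$end, score = terms$energy, strand = terms$strand,
    attributes = paste0("ID=", terms$terminator), stringsAsFactors = FALSE),
    path)
}
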