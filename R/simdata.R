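# Synthetic-community generator. Emulates the statistical structure the
# recruitment analysis assumes: a community of phage genomes with known
# relative abundances, controlled amino-acid-level divergence from a focal
# genome (substitutions only, so coordinates stay comparable to truth),
# fixed-length reads with substitution errors, and non-homologous background
# reads. Everything is deterministic under a single seed.

#' Simulate a gene-dense phage-like genome
#'
#' Concatenates protein-coding genes (ATG start, random non-stop codons, TAA
#' stop) on random strands, separated by short random intergenic spacers.
#' The construction guarantees a known set of long ORFs for downstream
#' callers to find.
#'
#' @param id genome identifier.
#' @param length_bp approximate target length (default 50000).
#' @param mean_gene_nt mean gene length in nt, start/stop included (default
#'   900; individual genes vary uniformly by +/- 40%).
#' @param intergenic_nt spacer length between genes (default 20).
#' @param seed integer seed.
#' @param circular mark the genome circular (default TRUE).
#' @return a [genome_record()].
#' @export
simulate_phage_genome <- function(id, length_bp = 50000L, mean_gene_nt = 900L,
                                  intergenic_nt = 20L, seed = 1L,
                                  circular = TRUE) {
  code <- genetic_code_table("11")
  sense <- names(code)[code != "*"]
  with_seed(seed, {
    parts <- character(0)
    total <- 0L
    while (total < length_bp) {
      ncod <- max(40L, round(stats::runif(1, 0.6, 1.4) * mean_gene_nt / 3))
      gene <- paste0("ATG",
                     paste0(sample(sense, ncod - 2L, replace = TRUE),
                            collapse = ""),
                     "TAA")
      if (stats::runif(1) < 0.5) gene <- revcomp(gene)
      spacer <- paste0(sample(c("A", "C", "G", "T"), intergenic_nt,
                              replace = TRUE), collapse = "")
      parts <- c(parts, gene, spacer)
      total <- total + nchar(gene) + intergenic_nt
    }
    genome_record(id, paste0(parts, collapse = ""), circular = circular)
  })
}

# Mean amino-acid identity of two proteomes given as parallel character
# vectors, measured by local alignment and weighted by protein length.
proteome_identity <- function(prot_a, prot_b) {
  stopifnot(length(prot_a) == length(prot_b), length(prot_a) > 0)
  ids <- numeric(length(prot_a)); wts <- nchar(prot_a)
  for (i in seq_along(prot_a)) {
    al <- local_align(prot_a[i], prot_b[i])
    ids[i] <- if (!is.na(al$pct_identity)) al$pct_identity else 0
  }
  sum(ids * wts) / sum(wts)
}

#' Diverge a genome to a target amino-acid identity
#'
#' Applies codon-aware point substitutions inside the given ORFs (start and
#' stop codons preserved; replacement codons always encode a different,
#' non-stop amino acid) until the mean amino-acid identity of the proteome
#' to the original, measured by local alignment, is within `tol` points of
#' `target_aa_identity`. Intergenic positions are substituted at the
#' realized coding nucleotide rate. No indels are introduced, so ORF
#' coordinates are preserved exactly.
#'
#' Overlapping ORFs are resolved by processing longer ORFs first and
#' skipping any ORF overlapping an already-mutated one.
#'
#' @param genome a [genome_record()].
#' @param orfs ORF table from [call_orfs()] on `genome`.
#' @param target_aa_identity target mean identity in percent (50..100).
#' @param seed integer seed.
#' @param tol acceptance window in identity points (default 2).
#' @param max_iter rate-adjustment iterations before giving up (default 10).
#' @return a [genome_record()] with id `<id>_id<target>`; attribute
#'   `mutated_orfs` lists the indices of the (non-overlapping) ORFs that
#'   were diverged and are guaranteed stop-free at the input coordinates.
#' @export
diverge_genome <- function(genome, orfs, target_aa_identity, seed = 1L,
                           tol = 2, max_iter = 10L) {
  if (target_aa_identity < 50 || target_aa_identity > 100)
    stop_fragrec("target identity must be in [50, 100]", "fragrec_input_error")
  new_id <- sprintf("%s_id%g", genome$id, target_aa_identity)
  L <- nchar(genome$seq)
  code <- genetic_code_table("11")
  codons <- names(code)
  by_aa <- split(codons, unname(code))

  # Non-overlapping ORF selection, longest first (real genes win over
  # spurious opposite-strand calls). Only selected ORFs are mutated -- and
  # only they are guaranteed stop-free afterwards; overlapping calls in
  # other frames may gain stops, as homologs of a diverged relative would.
  sel <- orfs[order(-orfs$span, orfs$start), , drop = FALSE]
  covered <- rep(FALSE, L)
  use <- logical(nrow(sel))
  posmod <- function(p) ((p - 1L) %% L) + 1L
  for (i in seq_len(nrow(sel))) {
    span_pos <- posmod(sel$start[i]:sel$end[i])
    if (!any(covered[span_pos])) {
      use[i] <- TRUE
      covered[span_pos] <- TRUE
    }
  }
  sel <- sel[use, , drop = FALSE]
  coding_mask <- covered
  if (target_aa_identity == 100) {
    out <- genome_record(new_id, genome$seq, genome$circular)
    attr(out, "mutated_orfs") <- sort(sel$index)
    return(out)
  }

  p <- 1 - target_aa_identity / 100
  for (iter in seq_len(max_iter)) {
    res <- with_seed(seed + iter - 1L, {
      s <- strsplit(genome$seq, "")[[1]]
      changed <- 0L; coding_bases <- 0L
      new_prot <- character(nrow(sel))
      for (oi in seq_len(nrow(sel))) {
        o <- sel[oi, ]
        nt <- extract_interval(genome, o$start, o$end, o$strand)
        ncod <- nchar(nt) %/% 3L
        starts <- seq(1L, by = 3L, length.out = ncod)
        cods <- substring(nt, starts, starts + 2L)
        coding_bases <- coding_bases + nchar(nt)
        if (ncod > 2L) {
          hit <- which(stats::runif(ncod - 2L) < p) + 1L
          for (ci in hit) {
            aa <- unname(code[cods[ci]])
            alt <- setdiff(names(by_aa), c(aa, "*"))
            pick_aa <- sample(alt, 1L)
            cands <- by_aa[[pick_aa]]
            newc <- cands[sample.int(length(cands), 1L)]
            changed <- changed + sum(strsplit(newc, "")[[1]] !=
                                       strsplit(cods[ci], "")[[1]])
            cods[ci] <- newc
          }
        }
        new_nt <- paste0(cods, collapse = "")
        new_prot[oi] <- sub("\\*$", "", translate_nt(new_nt))
        oriented <- if (o$strand == "-") revcomp(new_nt) else new_nt
        span_pos <- posmod(o$start:o$end)
        s[span_pos] <- strsplit(oriented, "")[[1]]
      }
      nt_rate <- if (coding_bases > 0) changed / coding_bases else 0
      inter <- which(!coding_mask)
      if (length(inter) && nt_rate > 0) {
        mut <- inter[stats::runif(length(inter)) < nt_rate]
        for (pidx in mut) {
          s[pidx] <- sample(setdiff(c("A", "C", "G", "T"), s[pidx]), 1L)
        }
      }
      list(seq = paste0(s, collapse = ""), new_prot = new_prot)
    })
    measured <- proteome_identity(sel$protein, res$new_prot)
    if (abs(measured - target_aa_identity) <= tol) {
      out <- genome_record(new_id, res$seq, genome$circular)
      attr(out, "mutated_orfs") <- sort(sel$index)
      return(out)
    }
    p <- min(0.95, max(0.005, p * (100 - target_aa_identity) /
                         max(100 - measured, 1e-6)))
  }
  stop_fragrec(sprintf(
    "could not reach %g%% identity within %d iterations (last measured %.1f%%)",
    target_aa_identity, max_iter, measured), "fragrec_sim_error")
}

#' Configuration for a synthetic read set
#'
#' @param genomes list of [genome_record()]s forming the community.
#' @param weights non-negative relative abundances, one per genome, summing
#'   to 1 (within 1e-9).
#' @param n_reads number of reads to generate.
#' @param read_len read length in nt (default 150).
#' @param error_rate per-base substitution error probability (default 0.01).
#' @param background_fraction fraction of reads drawn as i.i.d. uniform
#'   nucleotides, modelling non-homologous virome content (default 0.5).
#' @param seed integer seed.
#' @param metagenome_id source label stamped on every read (default "sim").
#' @return list of class `community_config`.
#' @export
community_config <- function(genomes, weights, n_reads, read_len = 150L,
                             error_rate = 0.01, background_fraction = 0.5,
                             seed = 1L, metagenome_id = "sim") {
  stopifnot(length(genomes) >= 1L, length(weights) == length(genomes))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop_fragrec("weights must be non-negative and sum to 1", "fragrec_config_error")
  if (background_fraction < 0 || background_fraction > 1)
    stop_fragrec("background_fraction must be in [0, 1]", "fragrec_config_error")
  structure(list(genomes = genomes, weights = weights,
                 n_reads = as.integer(n_reads), read_len = as.integer(read_len),
                 error_rate = error_rate,
                 background_fraction = background_fraction,
                 seed = as.integer(seed), metagenome_id = metagenome_id),
            class = "community_config")
}

#' Sample reads from a synthetic community
#'
#' Read origins are drawn from the community weights (or replaced by uniform
#' random background with probability `background_fraction`); positions are
#' uniform, wrapping across the origin of circular genomes; strands are
#' uniform; substitution errors are Bernoulli per base. Deterministic given
#' the config seed.
#'
#' @param cfg a [community_config()].
#' @return list with `reads` (data.frame `id`, `seq`, `source_metagenome`)
#'   and `truth` (data.frame `read_id`, `origin` -- genome id or
#'   "background" -- `pos`, `strand`).
#' @export
sample_reads <- function(cfg) {
  stopifnot(inherits(cfg, "community_config"))
  lens <- vapply(cfg$genomes, genome_length, integer(1))
  if (cfg$read_len > min(lens))
    stop_fragrec("read_len exceeds the shortest genome", "fragrec_input_error")
  n <- cfg$n_reads
  bases <- c("A", "C", "G", "T")
  if (n == 0L) {
    return(list(
      reads = data.frame(id = character(), seq = character(),
                         source_metagenome = character(),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = character(), origin = character(),
                         pos = integer(), strand = character(),
                         stringsAsFactors = FALSE)))
  }
  with_seed(cfg$seed, {
    ids <- sprintf("read%06d", seq_len(n))
    is_bg <- stats::runif(n) < cfg$background_fraction
    gi <- sample.int(length(cfg$genomes), n, replace = TRUE,
                     prob = cfg$weights)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    pos <- integer(n)
    seqs <- character(n)
    # Genomes padded across the origin (circular) for direct substring reads.
    ext <- lapply(cfg$genomes, function(g) {
      pad <- if (g$circular) substr(g$seq, 1L, cfg$read_len - 1L) else ""
      list(fwd = paste0(g$seq, pad),
           rev = revcomp(paste0(g$seq, pad)))
    })
    for (i in seq_len(n)) {
      if (is_bg[i]) {
        seqs[i] <- paste0(sample(bases, cfg$read_len, replace = TRUE),
                          collapse = "")
        pos[i] <- NA_integer_
        next
      }
      L <- lens[gi[i]]
      maxstart <- if (cfg$genomes[[gi[i]]]$circular) L else L - cfg$read_len + 1L
      p <- sample.int(maxstart, 1L)
      pos[i] <- p
      e <- ext[[gi[i]]]
      s <- if (strand[i] == "+") substr(e$fwd, p, p + cfg$read_len - 1L)
      else {
        extL <- nchar(e$fwd)
        substr(e$rev, extL - (p + cfg$read_len - 1L) + 1L, extL - p + 1L)
      }
      nerr <- stats::rbinom(1L, cfg$read_len, cfg$error_rate)
      if (nerr > 0L) {
        at <- sample.int(cfg$read_len, nerr)
        ch <- strsplit(s, "")[[1]]
        for (a in at) ch[a] <- sample(setdiff(bases, ch[a]), 1L)
        s <- paste0(ch, collapse = "")
      }
      seqs[i] <- s
    }
    origin <- ifelse(is_bg, "background",
                     vapply(cfg$genomes, function(g) g$id, character(1))[gi])
    strand[is_bg] <- NA_character_
    list(reads = data.frame(id = ids, seq = seqs,
                            source_metagenome = cfg$metagenome_id,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, origin = origin, pos = pos,
                            strand = strand, stringsAsFactors = FALSE))
  })
}

#' The standard synthetic community references
#'
#' Five simulated 50-kb phage genomes with log-spaced relative abundances
#' 16:8:4:2:1 -- the package's canonical end-to-end validation scenario.
#'
#' @param seed integer seed for genome construction.
#' @return list with `refs` (list of [genome_record()]) and `weights`.
#' @export
standard_community <- function(seed = 1L) {
  refs <- lapply(1:5, function(i)
    simulate_phage_genome(paste0("phage", LETTERS[i]), length_bp = 50000L,
                          seed = seed + i))
  list(refs = refs, weights = c(16, 8, 4, 2, 1) / 31)
}

#' End-to-end abundance recovery harness
#'
#' Builds a synthetic community of relatives of the reference genomes at a
#' controlled amino-acid identity, samples reads with errors and background,
#' then runs the full two-stage competitive recruitment with each reference
#' in turn as the focal phage, against a composite database containing that
#' reference's proteome plus divergent decoy proteomes of every reference.
#' Reports the Spearman rank correlation between the true community weights
#' and the per-ORF-normalized recruited-hit counts.
#'
#' @param refs list of at least 3 [genome_record()] references.
#' @param weights true relative abundances (distinct values required, else
#'   the rank correlation is undefined).
#' @param n_reads,read_len,error_rate,background_fraction read simulation
#'   parameters (defaults 20000, 150, 0.01, 0.5).
#' @param relative_identity amino-acid identity of the community genomes to
#'   their references, percent (default 85).
#' @param decoy_identity amino-acid identity of the decoy proteomes
#'   (default 60).
#' @param cutoff E-value cutoff for both stages (default 1e-5).
#' @param mode search mode, "seeded" or "exhaustive".
#' @param seed integer master seed; all stage RNGs derive from it.
#' @return list with `rho` (Spearman correlation) and `table` (per-phage
#'   data.frame: `phage_id`, `weight`, `n_true_reads`, `n_candidates`,
#'   `n_recruited`, `n_orfs`, `normalized`).
#' @export
recovery_harness <- function(refs, weights, n_reads = 20000L, read_len = 150L,
                             error_rate = 0.01, background_fraction = 0.5,
                             relative_identity = 85, decoy_identity = 60,
                             cutoff = 1e-5, mode = "seeded", seed = 1L) {
  if (length(refs) < 3L)
    stop_fragrec("recovery harness needs at least 3 phages", "fragrec_input_error")
  if (length(unique(weights)) == 1L)
    stop_fragrec("all weights equal: rank correlation undefined",
                 "fragrec_input_error")
  orfs_list <- lapply(refs, call_orfs)
  community <- lapply(seq_along(refs), function(i)
    diverge_genome(refs[[i]], orfs_list[[i]], relative_identity,
                   seed = seed + 100L + i))
  decoys <- do.call(rbind, lapply(seq_along(refs), function(i) {
    dg <- diverge_genome(refs[[i]], orfs_list[[i]], decoy_identity,
                         seed = seed + 500L + i)
    keep <- orfs_list[[i]][orfs_list[[i]]$index %in% attr(dg, "mutated_orfs"),
                           , drop = FALSE]
    prot <- vapply(seq_len(nrow(keep)), function(j)
      translate_orf(dg, keep[j, ]), character(1))
    data.frame(subject_id = paste0(dg$id, "_ORF", keep$index),
               phage_id = dg$id, peptide = prot, stringsAsFactors = FALSE)
  }))
  sim <- sample_reads(community_config(
    community, weights, n_reads = n_reads, read_len = read_len,
    error_rate = error_rate, background_fraction = background_fraction,
    seed = seed))
  db_gb <- sum(nchar(sim$reads$seq)) / 1e9

  rows <- lapply(seq_along(refs), function(i) {
    proteome <- orf_proteins(orfs_list[[i]])
    cand <- screen_reads(sim$reads, proteome, cutoff = cutoff, mode = mode)
    db <- composite_db(refs[[i]]$id, proteome, decoys = decoys)
    rec <- competitive_assign(cand, db, orfs_list[[i]], cutoff = cutoff,
                              mode = mode)
    data.frame(phage_id = refs[[i]]$id, weight = weights[i],
               n_true_reads = sum(sim$truth$origin == community[[i]]$id),
               n_candidates = nrow(cand), n_recruited = nrow(rec),
               n_orfs = nrow(orfs_list[[i]]),
               normalized = normalize_per_orf(nrow(rec),
                                              nrow(orfs_list[[i]]), db_gb),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(rho = stats::cor(tab$weight, tab$normalized, method = "spearman"),
       table = tab)
}
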