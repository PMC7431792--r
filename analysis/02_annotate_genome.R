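#!/usr/bin/env Rscript

# Step 2 -- annotate the focal genome. Calls ORFs on the first reference
# (the focal phage of the downstream recruitment), demonstrates the
# two-caller consensus rule on a start-shifted variant of the call set, and
# screens for rho-independent terminators at the -16 kcal/mol threshold.
# Writes results/annotation/{orfs.gff3,proteome.faa,terminators.tsv}.
#
# Usage: Rscript analysis/02_annotate_genome.R [seed]

suppressPackageStartupMessages(library(fragrec))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

focal_fa <- "results/sim/phageA.fa"
if (!file.exists(focal_fa))
  stop("run analysis/01_simulate_community.R first", call. = FALSE)
fa <- read_fasta(focal_fa)
genome <- genome_record(fa$id[1], fa$seq[1], circular = TRUE)

orfs <- call_orfs(genome)
message(genome$id, ": ", nrow(orfs), " ORFs > 100 bp (",
        sum(orfs$strand == "+"), " plus / ", sum(orfs$strand == "-"),
        " minus strand)")

# Consensus with a second caller that prefers later starts: the longer call
# per (stop, strand) locus is kept, so the consensus equals the original set.
alt <- orfs
shift <- alt$span > 300 & alt$strand == "+" &
  alt$start + 30L <= genome_length(genome)
alt$start[shift] <- alt$start[shift] + 30L
alt$span <- alt$end - alt$start + 1L
alt$protein <- vapply(seq_len(nrow(alt)), function(i)
  translate_orf(genome, alt[i, ]), character(1))
cons <- consensus_longer(orfs, alt)
message("Consensus with a start-shifted caller keeps ", nrow(cons),
        " loci (longer call per locus).")

orfs_to_gff3(cons, file.path(out, "orfs.gff3"))
write_proteome(cons, file.path(out, "proteome.faa"))

terms <- find_terminators(genome, cons)
write_terminator_table(terms, file.path(out, "terminators.tsv"))
message(nrow(terms), " rho-independent terminator candidates at <= -16 kcal/mol")
if (nrow(terms))
  print(terms[, c("terminator", "start", "end", "length", "strand", "energy",
                  "upstream_orf", "distance_nt")])
message("Wrote annotation under ", out)
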