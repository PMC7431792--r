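#!/usr/bin/env Rscript

# Step 1 -- build the study system. Simulates the standard five-phage
# community: five gene-dense 50-kb reference genomes, 85%-identity
# environmental relatives of each, 60%-identity decoy proteomes (the stand-in
# for a large composite phage protein database), and a 20,000-read synthetic
# metagenome (150-nt reads, 1% substitution error, 50% non-homologous
# background) with a ground-truth table. Everything is written under
# results/sim/ for the later steps.
#
# Usage: Rscript analysis/01_simulate_community.R [seed]

suppressPackageStartupMessages(library(fragrec))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- standard_community(seed = seed)
message("Simulated ", length(sc$refs), " reference genomes:")
for (g in sc$refs)
  message("  ", g$id, ": ", genome_length(g), " bp, GC ",
          round(gc_content(g$seq), 1), "%")

orfs_list <- lapply(sc$refs, call_orfs)
community <- decoys <- vector("list", length(sc$refs))
for (i in seq_along(sc$refs)) {
  community[[i]] <- diverge_genome(sc$refs[[i]], orfs_list[[i]], 85,
                                   seed = seed + 100L + i)
  decoys[[i]] <- diverge_genome(sc$refs[[i]], orfs_list[[i]], 60,
                                seed = seed + 500L + i)
  write_fasta(sc$refs[[i]], file.path(out, paste0(sc$refs[[i]]$id, ".fa")))
  orfs_to_gff3(orfs_list[[i]],
               file.path(out, paste0(sc$refs[[i]]$id, "_orfs.gff3")))
}
message("Community relatives at 85% aa identity; decoys at 60%.")

sim <- sample_reads(community_config(
  community, sc$weights, n_reads = 20000L, read_len = 150L,
  error_rate = 0.01, background_fraction = 0.5, seed = seed,
  metagenome_id = "simlake"))
write_fasta(setNames(sim$reads$seq, sim$reads$id),
            file.path(out, "reads.fa"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
counts <- table(sim$truth$origin)
message("Sampled ", nrow(sim$reads), " reads; origins:")
print(counts)
message("Wrote genomes, ORFs, reads and truth under ", out)
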