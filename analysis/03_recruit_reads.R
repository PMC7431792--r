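#!/usr/bin/env Rscript

# Step 3 -- two-stage competitive recruitment of the synthetic metagenome
# onto the focal phage. Stage 1 screens all reads against the focal proteome
# by six-frame translated search (E <= 1e-5); stage 2 re-searches candidates
# against the composite database (focal proteome + the five 60%-identity
# decoy proteomes) and recruits a read only when its best hit is a focal
# protein. Recruited reads are mapped onto focal genome coordinates.
# Writes results/recruitment/{recruitment.tsv,manifest.json}.
#
# Usage: Rscript analysis/03_recruit_reads.R [seed]

suppressPackageStartupMessages(library(fragrec))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

if (!file.exists("results/sim/reads.fa") ||
    !file.exists("results/annotation/proteome.faa"))
  stop("run analysis steps 01 and 02 first", call. = FALSE)

fa <- read_fasta("results/sim/phageA.fa")
genome <- genome_record(fa$id[1], fa$seq[1], circular = TRUE)
orfs <- gff3_to_orfs("results/annotation/orfs.gff3", genome)
reads <- read_reads("results/sim/reads.fa", source_metagenome = "simlake")

# Rebuild the decoy proteomes exactly as step 01 defined them.
sc <- standard_community(seed = seed)
orfs_list <- lapply(sc$refs, call_orfs)
decoys <- do.call(rbind, lapply(seq_along(sc$refs), function(i) {
  dg <- diverge_genome(sc$refs[[i]], orfs_list[[i]], 60, seed = seed + 500L + i)
  keep <- orfs_list[[i]][orfs_list[[i]]$index %in% attr(dg, "mutated_orfs"), ]
  data.frame(subject_id = paste0(dg$id, "_ORF", keep$index), phage_id = dg$id,
             peptide = vapply(seq_len(nrow(keep)), function(j)
               translate_orf(dg, keep[j, ]), character(1)),
             stringsAsFactors = FALSE)
}))

proteome <- orf_proteins(orfs)
message("Stage 1: screening ", nrow(reads), " reads against ",
        nrow(proteome), " focal proteins ...")
cand <- screen_reads(reads, proteome, cutoff = 1e-5)
message("  candidates: ", nrow(cand))

db <- composite_db(genome$id, proteome, decoys = decoys)
message("Stage 2: competitive best-hit assignment against ", nrow(db),
        " proteins from ", length(unique(db$phage_id)), " phages ...")
rec <- competitive_assign(cand, db, orfs, cutoff = 1e-5)
message("  recruited: ", nrow(rec), " (",
        round(100 * nrow(rec) / nrow(reads), 1), "% of reads)")

dir.create("results/recruitment", showWarnings = FALSE, recursive = TRUE)
write_recruitment_table(rec, "results/recruitment/recruitment.tsv")
jsonlite::write_json(
  list(seed = seed, reads_in = nrow(reads), candidates = nrow(cand),
       recruited = nrow(rec), n_orfs = nrow(orfs),
       db_proteins = nrow(db)),
  "results/recruitment/manifest.json", auto_unbox = TRUE, pretty = TRUE)
message("Wrote results/recruitment/recruitment.tsv")
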