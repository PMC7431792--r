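#!/usr/bin/env Rscript

# Step 4 -- abundance normalization and coverage summaries. Normalizes the
# recruited-read count per predicted ORF and per gigabase of metagenome
# (and, for comparison, per kb of genome), and summarises per-ORF coverage
# by habitat the way cross-metagenome ORF maps are reported.
# Writes results/abundance/{abundance.tsv,coverage.tsv}.
#
# Usage: Rscript analysis/04_abundance_summaries.R

suppressPackageStartupMessages(library(fragrec))

if (!file.exists("results/recruitment/recruitment.tsv"))
  stop("run analysis step 03 first", call. = FALSE)
rec <- read_recruitment_table("results/recruitment/recruitment.tsv")
fa <- read_fasta("results/sim/phageA.fa")
genome <- genome_record(fa$id[1], fa$seq[1], circular = TRUE)
orfs <- gff3_to_orfs("results/annotation/orfs.gff3", genome)
reads <- read_reads("results/sim/reads.fa")
db_gb <- sum(nchar(reads$seq)) / 1e9

dir.create("results/abundance", showWarnings = FALSE, recursive = TRUE)
rows <- rbind(
  abundance_row(genome$id, "simlake", nrow(rec), n_orfs = nrow(orfs),
                db_gb = db_gb),
  abundance_row(genome$id, "simlake", nrow(rec),
                genome_len_bp = genome_length(genome), db_gb = db_gb,
                normalizer = "per_length"))
write_abundance_table(rows, "results/abundance/abundance.tsv")
message("Normalized abundance of ", genome$id, " in simlake:")
print(rows[, c("normalizer", "n_hits", "db_size_gb", "normalized")])

# Coverage summary: the single synthetic metagenome is labelled freshwater.
hab <- data.frame(metagenome_id = "simlake", habitat = "freshwater",
                  stringsAsFactors = FALSE)
rec$source_metagenome <- rec$metagenome_id
cs <- coverage_summary(rec, orfs, hab, k = 5)
write.table(cs$per_orf, "results/abundance/coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sum(cs$per_orf$freshwater >= 1), " of ", nrow(orfs),
        " ORFs are covered by at least one recruited read.")
message("Wrote results/abundance/")
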