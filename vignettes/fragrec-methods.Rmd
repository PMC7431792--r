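---
title: "Methods: competitive fragment recruitment for viral metagenomes"
author: "fragrec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive fragment recruitment for viral metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`fragrec` measures the prevalence of sequences similar to a focal phage in
viral metagenomes by *competitive fragment recruitment*: a read is accepted
as "focal-phage-like" only if, among all phages in a composite protein
database, its best translated-homology hit is a focal-phage protein. The
package implements the full chain needed to make that measurement
reproducible at desk scale:

1. **Genome annotation** — a maximal-ORF caller for (possibly circular)
   phage genomes plus a two-caller consensus rule, and a simplified
   rho-independent terminator screen.
2. **Translated homology search** — six-frame translation, affine-gap
   Smith–Waterman protein alignment, Karlin–Altschul E-value statistics,
   and a deterministic hit ranking.
3. **Two-stage recruitment** — screen against the focal proteome, then
   competitive best-hit assignment against the composite database, with
   genome-coordinate mapping of recruited reads.
4. **Abundance normalization** — recruited hits per predicted ORF (or per
   kb of genome) per gigabase of metagenome, with cross-metagenome
   coverage summaries.
5. **Synthetic communities** — a generator with known abundances,
   controlled proteome divergence, read errors and background, so the
   whole chain is testable without environmental data.

# Coordinates

All coordinates are 1-based and fully inclusive. Published feature tables
are inconsistent about minus-strand features (some print start > end, some
print start < end with a strand column), so `interval()` accepts either
dialect and canonicalizes to start ≤ end plus an explicit strand;
`interval_length()` is `|end − start| + 1` and therefore dialect-invariant.
For circular genomes, features may span the origin; they are stored
*unwrapped* (start within the genome, end possibly beyond its length), so
every feature appears exactly once and lengths remain additive.

# ORF calling and the consensus rule

The built-in caller reports every maximal start-to-stop reading frame on
both strands with nucleotide span strictly greater than `min_len_nt`
(default 100 bp — the conventional display cutoff for phage genome maps).
Default start codons are ATG, GTG and TTG; translation uses NCBI genetic
code 11. Circular genomes are virtually extended by one full copy minus
one nucleotide, so origin-spanning ORFs are found exactly once; calls are
de-duplicated by (stop position mod genome length, strand).

Published phage annotations often combine two gene finders, keeping the
longer prediction where they differ. Gene finders overwhelmingly agree on
the stop codon and disagree on the start choice, so `consensus_longer()`
defines a *locus* as (stop position, strand): within a locus reported by
both call sets the longer call wins (with the same stop, "longer" means
the earlier start, so the rule is unambiguous); a locus reported by only
one caller is kept. This makes the consensus idempotent and commutative.
The matching rule is this package's design choice — start-coordinate
overlap matching was rejected because it is not transitive and can merge
distinct genes. External caller output can be imported from GFF3 and
combined identically. Note the built-in caller is deliberately simple (it
reports *all* maximal ORFs, with no coding-potential score), so its ORF
counts run higher than a trained gene finder's on the same sequence; the
consensus rule, not the caller, is the scientifically load-bearing part.

# Terminator screen

The screen looks for inverted repeats forming a stem-loop (stem 4–20 bp,
loop 3–10 nt) followed within 5 nt by a run of at least four T residues on
the coding strand, on both strands. The free-energy model is deliberately
transparent so every reported number is reproducible from the
configuration: allowed pairs score G:C = −3, A:T = −2, G:T = −1 kcal/mol,
and the loop costs +4.0 + 0.3·(loop_len − 3) kcal/mol. Candidates at or
below the threshold (default −16 kcal/mol, the conventional screening
threshold) are resolved greedily — lowest energy first, ties to the
leftmost start and then the plus strand — keeping non-overlapping calls.
Each call is annotated with the nearest upstream same-strand ORF within
200 nt, measuring the gap from the ORF 3′ end to the call's 5′ end
(published distance columns range over a few to ~140 nt, which motivates
the 200-nt default). The poly-T requirement is this package's addition to
suppress random hairpins and can be disabled. No claim is made that the
model reproduces any specific thermodynamic tool's calls; its reproducible
content is the thresholded screen and the output schema.

# Translated search and E-values

Reads are translated in all six frames (stops rendered `*`, codons
containing N rendered `X`, trailing partial codons dropped). Frames are
split at stop codons before alignment, so extensions terminate at stops
exactly. Each stop-free segment is aligned to database proteins by
affine-gap Smith–Waterman with BLOSUM62; a gap of length *g* costs
`gap_open + g·gap_extend` (defaults 11 and 1). Percent identity is
computed over aligned residue pairs, excluding gap columns.

Significance uses Karlin–Altschul statistics with the published gapped
constants for BLOSUM62/11/1: λ = 0.267, K = 0.041 (not re-estimated);
`E = K·m·n·exp(−λS)` with *m* the length of the stop-free query segment
actually searched and *n* the total residue count of the protein database
(overridable to model a larger search space). Bit scores are
`(λS − ln K)/ln 2`. The default cutoff is E ≤ 1e−5, the conventional
homology threshold in phage annotation and recruitment.

Two search modes share one code path: *exhaustive* aligns every
query-subject pair; *seeded* first filters subjects by exact 4-mer words
over the 20 standard amino acids and then runs the *full* DP on the
candidates. This is a stronger guarantee than classic X-drop/banded
seeding: the seeded hit set equals the exhaustive one whenever a
reportable alignment contains at least one exact 4-mer word, which at
E ≤ 1e−5 (raw scores ≳ 40) is essentially always. The equality is tested,
not assumed. Hits are ranked within each read by bit score (descending),
E-value (ascending), subject id (ascending) — a total order, so repeated
runs are byte-identical. This replaces the order-dependent
`max_target_seqs = 1` heuristic of common search tools with a true,
reproducible best hit; with duplicated proteins under different ids the
lexicographically smallest subject id wins, deterministically.

One deliberate inversion: classic recruitment pipelines search phage
proteins against a nucleotide read database (tBLASTn) and then reads
against proteins (BLASTx). Here both stages stream reads against protein
databases; under identical scoring and cutoff the hit pairs are the same
by the symmetry of local alignment, and the effective *n* is documented
as the protein database size.

# Two-stage competitive recruitment

Stage 1 (`screen_reads`) keeps reads with at least one hit at E ≤ cutoff
against the focal proteome. Stage 2 (`competitive_assign`) re-searches the
candidates against the composite database (focal proteins plus decoy phage
proteomes) and recruits a read iff its top-ranked hit belongs to the focal
phage. Ties between a focal and a decoy subject with identical scores
resolve by subject id; ties between two focal proteins recruit the read
with the interval taken from the deterministic top hit. Both stages share
the 1e−5 cutoff by default but are independently configurable. Percent
identity, E-value and bit score in the recruitment table come from the
stage-2 alignment — the alignment that justified recruitment.

Recruited reads are mapped onto the genome through the ORF of their best
hit: a hit covering amino acids a1..a2 of an ORF at [g1, g2] maps to
[g1 + 3(a1−1), g1 + 3·a2 − 1] on the plus strand and mirror-image from g2
downward on the minus strand, so mapped intervals always lie inside their
ORF and have length 3(a2−a1+1).

Three monotonicity properties hold by construction and are enforced by
tests: recruited ⊆ candidates ⊆ reads; adding decoys never enlarges the
recruited set; with a focal-only database stage 2 reduces to stage 1.

# Normalization

Two normalizers are implemented because published practice uses both:
hits per predicted ORF per gigabyte of metagenome (`normalize_per_orf`,
the default) and hits per kb of genome per gigabyte
(`normalize_per_length`). A "gigabyte" of metagenome is defined as 1e9
bases of read sequence — reproducible and format-independent, unlike
compressed file size; callers who mean file size can pass that number
instead. Every abundance row is stamped with its normalizer and rows with
mixed normalizers refuse to rank together. "Multiple" coverage means ≥ 2
metagenomes of a habitat; "extensive" coverage has no standard printed
definition, so it is exposed as a configurable threshold k (default 5)
and given no validated meaning.

# The synthetic community

The generator emulates exactly the statistical structure the analysis
assumes, and nothing more:

* **Genomes** are concatenations of constructed genes (ATG + random
  non-stop codons + TAA, random strand, ~900 nt mean length) with 20-nt
  random spacers — gene-dense like real phage genomes, with a known ORF
  complement. They carry no codon-usage bias, promoters, or repeats.
* **Divergence** (`diverge_genome`) applies codon-aware substitutions
  (always to a different, non-stop amino acid; start/stop codons
  preserved) until the proteome's mean local-alignment identity to the
  original is within ±2 points of the target, iteratively adjusting the
  substitution rate; intergenic positions mutate at the realized coding
  nucleotide rate. No indels are introduced, so coordinates remain
  comparable to the truth table. Real divergence includes indels and
  rearrangements; their absence means mapping accuracy here is an upper
  bound.
* **Reads** are fixed-length, uniformly positioned (wrapping across
  circular origins), strand-random, with Bernoulli per-base substitution
  errors and an i.i.d.-uniform background fraction (default 0.5) standing
  in for non-homologous virome content. There is no quality model, no
  platform error profile, no paired ends.

The standard validation scenario (`standard_community` +
`recovery_harness`) uses five 50-kb phages with log-spaced weights
16:8:4:2:1, 20,000 reads of 150 nt at 1% error, community members at 85%
amino-acid identity to their references, and decoy proteomes at 60%
identity — a regime chosen to resemble "same viral lineage, different
population" recruitment against a diverged decoy database. The harness
runs the full two-stage recruitment with each reference in turn as focal
and reports the Spearman correlation between true weights and per-ORF
normalized recruited hits. Passing (ρ ≥ 0.9) shows the pipeline ranks
known abundances correctly *under these conditions*; it does not show
robustness to lower identities, chimeric reads, or uneven community
structure, which real metagenomes contain.

# Numerical and design choices

* **Determinism.** Every stochastic step funnels through one integer seed
  (stage seeds are fixed offsets from it); RNG state is saved and
  restored so package functions never perturb the caller's stream. All
  rankings are total orders; repeated runs are byte-identical.
* **Degenerate inputs.** Empty read sets search to empty hit tables (not
  errors); empty FASTA files read as empty collections; all-N sequences
  have undefined GC content and error; an all-equal-weights community has
  an undefined rank correlation and errors.
* **X and stops.** `X` keeps its BLOSUM62 scores; `*` never aligns
  (frames are split at stops before the DP ever sees one).
* **Problem sizes.** Module tests run on 5–20 kb genomes with hundreds of
  reads; the end-to-end validation uses the full standard community
  (5 × 50 kb, 20,000 reads). These sizes were chosen so the complete
  validation, including the recovery benchmark, runs in minutes on one
  core while keeping every statistical check well-powered (binomial
  checks at n = 10⁴, null calibration at 9 × 10⁶ aligned residue pairs).

# Known limitations

* The ORF caller has no coding-potential model; on real genomes its raw
  counts exceed curated annotations, and the per-ORF normalizer therefore
  runs lower than one computed from a curated ORF set. Import curated
  calls via GFF3 when comparability with published counts matters.
* The terminator energy model is a screen, not thermodynamics;
  nearest-neighbor stacking is out of scope by design.
* Karlin–Altschul constants are fixed for BLOSUM62/11/1; other matrices
  or gap costs require supplying matching constants.
* Recruitment is protein-level only; nucleotide-level recruitment and
  coverage plotting are out of scope (the recruitment table is the plot's
  data).
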