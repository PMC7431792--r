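# fragrec — competitive fragment recruitment for viral metagenomes

`fragrec` answers a question virologists ask as soon as they isolate a new
phage: **how prevalent are sequences like this phage in environmental
metagenomes?** The approach is two-stage competitive fragment recruitment at
the protein level. Metagenomic reads are first screened against the focal
phage's proteome by six-frame translated local alignment
(Smith–Waterman, BLOSUM62, affine gaps 11/1) with Karlin–Altschul
significance, E = K·m·n·e^(−λS), at the conventional cutoff E ≤ 10⁻⁵.
Candidate reads are then re-searched against a *composite* database — the
focal proteome plus many decoy phage proteomes — and a read is recruited
only if its best hit is a focal protein:

    recruited(r) ⇔ top-hit(r, focal ∪ decoys) ∈ focal,  E ≤ 10⁻⁵

Recruited reads are mapped back onto focal genome coordinates through the
ORF their best hit landed on, and counts are normalized to

    N = n_hits / (n_ORFs × Gb of metagenome)     (per-ORF, default)
    N = n_hits / (genome kb × Gb of metagenome)  (per-length)

so abundance is comparable across metagenomes of different size and phages
of different gene content.

Around that core the package provides what the measurement needs: a
maximal-ORF caller for circular phage genomes with the two-caller
"keep the longer call" consensus rule, a thresholded-energy screen for
rho-independent terminators (−16 kcal/mol default), deterministic tabular
outputs (GFF3 / TSV), and a synthetic-community generator with ground
truth so every stage is verifiable without downloading environmental data.

## Worked example

The bundled analysis (scripts under `analysis/`, run in order, or the
recovery harness in one call) builds the standard synthetic community —
five 50-kb phages at relative abundances 16:8:4:2:1, read at 85%
amino-acid identity through 20,000 150-nt reads with 1% error and 50%
random background, against 60%-identity decoy proteomes — and recruits it
back with each phage in turn as focal:

```r
library(fragrec)
sc <- standard_community(seed = 1)
r  <- recovery_harness(sc$refs, sc$weights, seed = 1)
r$table
#>   phage_id     weight n_true_reads n_candidates n_recruited n_orfs normalized
#> 1   phageA 0.51612903         5202         5177        5166    472  3648.3051
#> 2   phageB 0.25806452         2580         2576        2576    473  1815.3629
#> 3   phageC 0.12903226         1267         1261        1260    479   876.8267
#> 4   phageD 0.06451613          603          602         599    494   404.1835
#> 5   phageE 0.03225806          307          305         305    458   221.9796
r$rho
#> [1] 1
```

Reading the table: of the 5,202 reads truly drawn from the most abundant
phage's 85%-identity relative, 5,177 pass the stage-1 screen and 5,166
survive competitive assignment against the decoys; normalized per ORF and
per gigabase, the five phages rank exactly as their true weights
(Spearman ρ = 1). The containment chain
recruited ≤ candidates ≤ reads holds per phage, and adding decoys can
only shrink the recruited set.

Single steps are ordinary functions: `call_orfs()` / `consensus_longer()`
for annotation, `find_terminators()` for the terminator screen,
`screen_reads()` / `competitive_assign()` for recruitment,
`normalize_per_orf()` / `rank_phages()` / `coverage_summary()` for the
abundance tables, and `run_recruitment_pipeline()` to execute the whole
chain from a config list or YAML file with a JSON run manifest.

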