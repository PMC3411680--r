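# telandscape

Transposable-element (TE) landscape analysis for compact (fungal-sized)
genome assemblies, built around the kind of genome-wide TE census carried
out for the ectomycorrhizal basidiomycete *Laccaria bicolor* (60 Mb, ~24%
TE). The package takes an assembly plus raw TE annotations (RepeatMasker
`.out` or GFF3) and produces a refined annotation, insertion ages for LTR
retrotransposons, the nest/cluster topology of the TE landscape, a
six-column genome census table, and distance-based phylogenies of
retroelement protein domains — with a synthetic-genome simulator providing
ground truth for every stage.

## What it computes

**Annotation refinement.** Consecutive fragments of one element
(interrupted by nested insertions) are re-joined when the gap between them
consists of more than 80% other TE annotations; annotations shorter than
20 bp after discounting simple-repeat overlap are eliminated; copies
covering ≥95% of their family consensus with both termini within 10 bp are
classified full-length.

**LTR insertion dating.** The two long terminal repeats of an element are
identical when it inserts, so their divergence measures its age. The 5′
and 3′ LTRs are globally aligned, transition (P) and transversion (Q)
fractions counted over ungapped columns, and the Kimura two-parameter
distance

    K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

converted to years under a molecular clock, T = K / (2r), with
r = 1.3×10⁻⁸ substitutions · site⁻¹ · year⁻¹ (the factor 2 because both
LTRs accumulate substitutions). Dated families are binned into expansion
periods (defaults: 0–0.5, 1–5 and 10–57 Mya); families with ≥2 full-length
copies above 95% identity are flagged potentially active.

**Topology.** Nests are strict containments (a TE inserted within another
TE); clusters are chains of copies within 10 kb of each other; density is
counted in 10-kb windows along each chromosome, and nests/clusters falling
in the terminal 1 Mb of a chromosome are tallied separately.

**Census.** Per TE order: family count, copy number, full-length /
incomplete split, DNA amount (Mb) and percent of genome, with class I /
class II / fragment subtotals, a grand total, and the genome-wide copy
density (copies per Mb).

**Phylogeny.** Neighbor-joining trees (hand-implemented, deterministic
tie-breaking, consistent on additive matrices) from p-distances of aligned
reverse transcriptase / ribonuclease H amino-acid domains, with seeded
column-bootstrap support, written as newick.

**Simulator.** `simulate_te_genome()` plants TE copies of known family,
age (three-burst mixture), truncation, nesting and clustering into random
chromosomes, applying a K2P substitution process calibrated to the clock,
and emits FASTA + truth GFF3/TSV so every stage can be validated exactly.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
simulated 3 × 1 Mb genome with ~300 planted copies and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_refine.R
Rscript analysis/03_date_ltrs.R
Rscript analysis/04_topology.R
Rscript analysis/05_summarize.R
Rscript analysis/06_phylo.R
```

Output of stage 1 and 2:

```
simulated genome: 3851095 bp over 3 chromosomes
planted copies: 300 (skipped: 0 )
truncated: 220 | nested: 81 | clustered: 282
input copies: 300 -> refined: 289
full-length: 82 | incomplete: 207
```

300 copies were planted; refinement merges same-family copies that the
simulator nested inside each other (logged), leaving 289 annotations of
which 82 are full-length — the truncation record of the simulator, exactly
recovered. Stage 3 dates the uninterrupted full-length LTR retroelements:

```
dated 28 LTR pairs; 1 saturated
families per expansion period:
     0-500000   1e+06-5e+06 1e+07-5.7e+07
            5             5             3
age error (My): mean -0.073, sd 1.694
```

The mean dating error is ~0.07 My, i.e. the clock inverts the simulator's
substitution process without bias; the per-copy scatter (sd 1.7 My, driven
by the oldest copies) is the binomial noise floor of 250–400 bp LTRs.
Stage 4 and 5 report the landscape structure and census:

```
nests: 64 | clusters: 43 | deduplicated union: 43
nested and/or clustered copies: 93.8%
simulated genome: 289 copies, 1.08 Mb of TE (28.1% of 3.9 Mb)
L. bicolor census: 171 families, 25787 copies (930/13787
  full-length/incomplete), 14.56 Mb, 24.3% of the genome, 430 copies/Mb
```

The last two lines are the package's bookkeeping re-run on the transcribed
per-order rows of the published *L. bicolor* table: subtotals, totals,
composition and the 430 copies/Mb density are recomputed, not copied.
Stage 6 builds the NJ tree of a two-clade synthetic domain alignment and
recovers the Copia/Gypsy split with 100% bootstrap support (1000
replicates).

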