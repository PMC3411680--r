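---
title: "Methods: TE landscape refinement, dating and topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE landscape refinement, dating and topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telandscape)
```

# Scope and model

`telandscape` post-processes transposable-element annotations of compact
genome assemblies and analyses the resulting landscape. It deliberately
does **not** discover repeats: homology search (RepeatMasker, TBLASTN),
de novo consensus building, structural LTR detection and tandem-repeat
finding are upstream tools whose outputs this package consumes. Likewise
it stops short of biological interpretation; its products are refined
annotations and tables.

All internal coordinates are 0-based half-open, which makes containment,
gap and window arithmetic free of off-by-one corrections; the GFF3 and
RepeatMasker readers own the ±1 conversions, and round-trip tests pin that
contract down. Minus-strand copies keep unflipped genomic coordinates
(topology works in genome space) and are reverse-complemented only when
sequence is extracted (dating works in element space). Non-ACGT symbols
are treated as missing and excluded from all substitution counts — a
conservative choice where upstream pipelines differ.

# Annotation refinement

Nested insertions chop a host element into consecutive RepeatMasker
fragments. `join_fragments()` re-joins two same-family, same-strand
fragments when (i) they are colinear on the family consensus and (ii) the
genomic gap between them consists of *more than* 80% other TE annotations.
The 80% threshold is the standard defragmentation rule for this kind of
census; the coverage is measured on the gap alone (not the union of gap
and fragments), which is the reading that makes the criterion independent
of fragment lengths. Colinearity allows a 50 bp overlap on the consensus
because adjacent RepeatMasker fragments commonly overlap slightly there;
fragments that physically overlap on the genome (negative gap) are merged
unconditionally and logged. Joining proceeds transitively left-to-right
and is idempotent (tested by property).

`subtract_and_filter()` removes annotations whose length *outside* simple
repeats falls below 20 bp. The simple-repeat overlap is used as a filter
criterion, not a trim: an annotation phrased as "remove overlapping
regions, then drop what is shorter than 20 bp" is ambiguous between the
two, and filtering preserves the input coordinates that downstream
topology depends on.

"Full length" is not given a standard definition by census conventions, so
the package defines it explicitly and configurably: a copy is full-length
when it covers ≥95% of its family consensus *and* both consensus termini
lie within 10 bp of the consensus ends. The second clause keeps a copy
missing one entire terminus from qualifying on coverage alone.

# LTR insertion dating

The two LTRs of a retroelement are identical at insertion and diverge
afterwards. The package aligns them globally (Needleman–Wunsch, affine
gaps: match +1, mismatch −1, gap open 10, gap extend 0.5 — configurable
and recorded), counts transition (P) and transversion (Q) fractions over
columns where both symbols are unambiguous bases, and computes the Kimura
two-parameter distance

$$K = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

A pairwise global alignment replaces the progressive multiple-alignment
step of older pipelines: two sequences need no guide tree. All gap and
ambiguous columns are excluded from counts; whether gap-adjacent columns
should also be masked is a judgment call on which we take the simpler
side.

Age follows the molecular clock as $T = K/(2r)$ with
$r = 1.3\times10^{-8}$ substitutions·site⁻¹·year⁻¹, a rate commonly
adopted for fungal LTR retrotransposons. The factor 2 is there because
divergence accrues on *both* LTRs: each accumulates $rT$ expected
substitutions per site, so their mutual distance is $2rT$. When
$1-2P-Q \le 0$ or $1-2Q \le 0$ the logarithms are undefined — the pair is
saturated. Saturated pairs are excluded from age histograms but counted
and reported; silently dropping them would bias the landscape towards
young elements.

Dating is per-copy; family-level statements (expansion periods, activity)
aggregate over copies. `bin_expansions()` counts a family once in every
age bin that holds at least one of its dated copies, with closed-lower /
open-upper bins defaulting to the three expansion periods resolved for
*Laccaria bicolor*: 0–0.5, 1–5 and 10–57 Mya. Copies dated into the gaps
between periods are tallied under "other" rather than forced into a bin.
A family is flagged *potentially active* when it has at least two
full-length copies above 95% identity (strict inequality at the
threshold): several near-identical intact members are the signature of
recent transposition.

# Topology

A **nest** is strict containment: host start < insert start and insert
end < host end, at least 1 bp of flank on both sides; each insert is
attributed to its *smallest* enclosing host, so triple nesting A⊃B⊃C
yields C→B and B→A. A **cluster** is a maximal chain of copies in which
consecutive inter-copy gaps (next start minus running maximum end) are at
most 10 kb; two members minimum. Measuring the gap between interval ends
(rather than midpoints or starts) matches the visual notion of adjacency
and makes overlapping copies chain automatically. The implementation is
single-linkage chaining over position-sorted copies and is tested to be
identical to the brute-force transitive closure of the pairwise ≤10 kb
relation.

Density is counted in 10-kb windows. The package uses non-overlapping
tiling windows by default (a `step_bp` parameter provides true sliding
windows when wanted) because tiling makes count conservation exact: each
copy is assigned to the window containing its start, so window counts sum
to the copy number on every chromosome — an invariant the tests assert on
every run. Nests/clusters overlapping the first or last 1 Mb of a
chromosome are "terminal"; chromosomes shorter than 2 Mb are entirely
terminal and logged as such. Because nests and clusters overlap as
categories, the package reports nests, clusters *and* a deduplicated
union (a nest whose host already sits in a cluster adds nothing to the
union count).

# Census bookkeeping

The census table follows the six-column convention: TE type, family
count, copy number, full-length/incomplete, DNA amount (Mb), percent of
genome. DNA amount sums each copy's genomic span *without* merging
overlaps between rows — per-row Mb values must add up to the printed
total, which cross-row deduplication would break; a deduplicated
"masked bp" figure is emitted separately for transparency. Fragment
(unclassified) rows carry no full/incomplete split, and are therefore
excluded from the split subtotals. Genome size is an explicit parameter
(60 Mb for the published *L. bicolor* table) rather than being inferred
from the FASTA, so censuses of assembly subsets remain comparable.

The transcribed per-order rows of the published *L. bicolor* census ship
with the package (`laccaria_census_orders()`). Recomputing subtotals from
them reproduces the printed copy/family/full-length numbers exactly;
printed Mb and percentage subtotals differ by up to 0.04 Mb / 0.07
points because the original subtotals were evidently computed from
unrounded per-order values. The printed family total (175) also exceeds
its own column sum (171, matching the reported number of consensus
sequences); the package reports what the rows sum to and does not attempt
to reconcile the discrepancy.

# Phylogeny

Distances between aligned reverse transcriptase / ribonuclease H domains
default to the uncorrected p-distance with pairwise gap deletion; a
Poisson correction ($-\ln(1-p)$) is available. The legacy pipelines this
mirrors ran distance programs whose exact model was rarely recorded, so
the package prefers a transparent default over guessing.

Neighbor joining is implemented directly (rather than delegated) so that
tie-breaking is specified: the $Q$-minimizing pair with the
lexicographically smallest index pair wins, making trees reproducible
across platforms. Negative branch-length estimates are clamped to zero
and counted (`attr(tree, "n_clamped")`). NJ is consistent on additive
matrices, and the tests exercise exactly that: random trees up to eight
taxa are recovered with their branch lengths, cross-checked against an
independent NJ implementation and, for five taxa, against exhaustive
minimum-evolution search. Bootstrap support resamples alignment columns
with replacement under a fixed seed and reports, per internal edge of the
full-data tree, the replicate frequency of the same leaf bipartition.
Tie-broken replicate topologies mean borderline supports can shift when
taxa are reordered; fully supported clades do not.

# The simulator

`simulate_te_genome()` is the package's ground-truth engine, not a
fixture: it plants copies with known family, age, truncation, nesting and
clustering, and its truth tables are what the end-to-end tests compare
against. Design choices:

* **Substitution process.** Per-site independent K2P with transition bias
  κ (expected transition:transversion *count* ratio, default 2) and total
  rate $r$, applied for the copy's age — exactly the generative model the
  K2P estimator inverts, so dating should be unbiased and the
  parameter-recovery tests can demand it (mean recovered age within 3
  standard errors at 0.5, 5 and 20 My). No indels are introduced by
  default.
* **Ages** are drawn from an equal-weight mixture over the three
  expansion periods, Beta(2,2)-shaped within each period: expansion
  episodes wax and wane, so burst ages peak mid-period rather than piling
  up at the period boundaries.
* **Nesting** inserts a copy at a point strictly inside an existing copy;
  the host's truth record keeps one span across the interruption —
  precisely the representation fragment joining is supposed to
  reconstruct. Truth records the *innermost* element containing the
  insertion point, matching the smallest-enclosing-host convention of
  nest detection.
* **Clustering** places a copy within ≤9 kb of an existing copy, outside
  all existing spans (so no accidental nests). Cluster labels in the
  truth are the single-linkage components of the final coordinates.
* **Scale.** Defaults are 3 chromosomes × 1 Mb with ~300 copies across 10
  families (Copia/Gypsy-dominated, as in fungal genomes), 70% of copies
  truncated. These sizes keep the full validation suite at desk scale
  while leaving every structure (nests, clusters, bursts, truncation)
  well populated; the tests run the same configuration.

What the simulator does **not** emulate: simple-repeat/microsatellite
co-occurrence, indel evolution, solo-LTR formation by recombination,
assembly artifacts, or annotation error (truth annotations are perfect).
Passing end-to-end tests therefore demonstrate that the pipeline's logic
is exact under clean input — not that it is robust to noisy boundaries or
mis-assigned families, which real RepeatMasker output will contain.

# Numerical choices and limitations

* Dating refuses LTRs shorter than 30 bp; even at 300 bp the binomial
  noise floor is substantial (≈0.25 My standard deviation for a 0.5 My
  copy at the default clock). Period-assignment of individual young
  copies is accordingly uncertain — a measurement limit, not an
  implementation one; the acceptance suite quantifies it.
* The expansion-period histogram uses half-open bins and an explicit
  "other" tally for the gaps; boundary ages (exactly 0.5 My) fall in the
  gap above the bin by construction.
* The fragment-joining threshold is strict (>0.80), as is the activity
  identity threshold (>95%); boundary cases are tested.
* Same-family nesting is indistinguishable from fragmentation by
  coordinates alone, so refinement merges a same-family insert into its
  host (logged). This is the standard failure mode of defragmentation and
  the reason the census counts such events as one copy.
* `summarize_rows()` works at whatever precision its inputs carry;
  two-decimal formatting happens only in the TSV writers, so repeated
  writes are byte-identical.

# Problem sizes used in validation

The shipped validation runs use: the 13 transcribed census rows for the
bookkeeping checks; 200 simulated LTR pairs per true age for clock
recovery and 300 burst-drawn pairs for period assignment; 100 random
interval instances (up to 200 intervals) for the topology oracles; one
3 × 1 Mb simulated genome (~300 copies) for end-to-end recovery; and 100
random additive trees (up to 8 taxa) plus seeded bootstraps for the
phylogeny module.
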