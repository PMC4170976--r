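---
title: "Cross-species microsatellite markers: discovery, primer design and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species microsatellite markers: discovery, primer design and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmsat)
```

# The problem

Microsatellites (SSRs) are tandem repeats of 1–6 bp motifs whose copy number
is highly polymorphic within populations, which makes them cheap, informative
codominant markers for population genetics and pedigree reconstruction. Their
weakness is transferability: PCR primers designed in one species usually fail
in distant relatives, so each new study species has traditionally required a
new marker panel. When several genome assemblies are available for a clade,
an alternative is to look for repeat loci whose *flanking* sequence is
conserved across all assemblies and to design a single degenerate primer pair
per locus from the consensus of the flanks. `conmsat` implements that
pipeline end to end, together with the population-genetic evaluation used to
characterise the resulting panel, and a synthetic-data module that generates
genome sets and genotype samples with known ground truth.

The pipeline has four stages:

1. **Repeat discovery** (`find_tandem_repeats`) in one query genome.
2. **Conserved-flank search** (`build_masked_query`, `assess_conservation`)
   of each repeat's masked flanks against every genome of the set.
3. **Selection and linkage** (`select_loci`, `physical_linkage`).
4. **Consensus primer design** (`align_flanks`, `call_consensus`,
   `design_primers`) and **marker evaluation** (`summarize_table`,
   `hwe_test`, `ld_test`, `aggregate_summaries`).

# Repeat detection model

Tandem repeats of period $p \le 5$ are found by a banded local self-alignment
of the sequence against itself offset by $p$ ("wraparound" dynamic
programming with drift up to $\pm 2p$, so copy-number changes inside a tract
are representable). Scoring is match $+2$, mismatch $-5$, indel $-7$, and a
tract's score includes its first (defining) copy, so a perfect tract of $L$
bases scores $2L$: a perfect dinucleotide needs 13 copies (26 bp, score 52)
to clear the default reporting threshold of 50, while 12 copies (48) falls
short. The mismatch weight (5), the score threshold (50) and the maximum
period (5) are the conventional settings for this class of detector; match
and indel weights are fixed at the detector defaults $+2$/$-7$ and all five
are exposed as arguments.

Three documented resolution rules keep the reported calls interpretable:

* **Fresh alignments start at drift zero**, so a period-$p$ call genuinely
  begins by aligning at offset $p$ rather than borrowing a shorter period
  through drift.
* **Overlapping calls across periods are resolved on the alignment score with
  the first-copy bonus stripped**, then by smaller period, then smaller
  start. The bonus ($2p$) is a reporting convention, not alignment evidence;
  left in the comparison it systematically favours longer-period
  reinterpretations of short-period tracts.
* **Non-primitive calls are dropped**: a call whose longest-run unit is
  itself a repetition (e.g. `ACAC`) is discarded in favour of the
  primitive-period call that also exists for the same tract.

The motif is read at the start of the longest perfect run inside the tract
(chance matches in the flank can extend a call off-phase), reported in
canonical form: the lexicographically smallest rotation over both strands,
so motifs compare across genomes, strands and repeat phases.
`max_perfect_run` counts consecutive exact copies, maximised over rotations
of the unit, which makes the count independent of where the boundary was
called. N runs partition the input; no call ever spans an N. Homopolymer
tracts are detected but flagged, and excluded from query construction by
default, since single-base repeats make poor genotyping markers.

An exhaustive brute-force scorer (full-matrix, unbanded, independently
written) is used in the tests: on $10^4$ random and planted strings of up to
30 bp the reported call sets and scores agree exactly.

# Conserved-flank search

Each repeat locus is turned into a masked query: up to 200 bp of flank on
each side (truncation at contig edges is flagged) with the repeat tract
replaced by mask characters. The mask aligns to anything at zero score and
gaps adjacent to it are free, so tract-length differences between genomes
cost nothing; masked columns and free gaps are excluded from the identity
denominator, so the mask can neither inflate nor deflate identity.

The search itself is a seeded local alignment: exact 11-mer words of the
unmasked query are matched against the target (the minus strand is handled
by reverse-complementing the query), seeds are grouped by alignment
diagonal, and each candidate window is aligned with a full mask-aware affine
Smith–Waterman (match $+1$, mismatch $-2$, gap open $-5$, gap extend $-2$).
Hits below 60% identity are removed; overlapping hits ($\ge 50\%$ of the
shorter interval) are merged keeping the higher score; a hit must cover at
least half of each flank to support primer design; and hits must score at
least 40, which removes chance seed pairs that the zero-cost mask could
otherwise bridge into spurious "perfect" micro-hits. All thresholds are
arguments.

A locus is `conserved_unique` only when *every* genome of the set — the
query's own included — has exactly one qualifying hit; other outcomes are
classified `non_unique`, `missing_in_genome`, `low_identity`, or
`repeat_absent` (flanks conserved everywhere but no genome's hit interval
contains a repeat). At each unique hit the detector is re-run on the padded
interval to confirm the repeat and record its motif and perfect-run length
per genome. Tests verify self-search identity 1.0, strand symmetry, and
exact score agreement with a reference Smith–Waterman on targets up to 2 kb.

# Selection and physical linkage

A conserved locus is selected when the repeat motif is confirmed in at least
75% of the genomes *and* shows at least `run_min = 10` consecutive perfect
copies in more than one genome (`run_genomes_min = 2`, a strict "more than
one"). The 75% operationalises "most or all" genomes and is a flag, as is
`run_mode = "total"` which counts total copy number including interruptions
instead of perfect runs, for users who read repeat depth that way. Both
filters are monotone in their thresholds, which the tests check. Loci whose
unique hits share a contig in any genome are reported as physically linked
pairs — co-location on an assembly scaffold is independent of (and often
invisible to) statistical linkage disequilibrium at small sample sizes.

# Consensus and primer design

Per-genome flanks of a selected locus (in query orientation) are multiply
aligned by a deterministic progressive scheme: all pairwise global
alignments (match $+1$, mismatch $-1$, gap open $-4$, gap extend $-1$) give
a similarity matrix; sequences join most-central-first, each aligned to the
growing profile; ties in the joining order break on sequence content and
then name, so the alignment is invariant to input order. The aligner is
intentionally self-contained — determinism and an exact pairwise oracle are
worth more for a reproducible pipeline than fidelity to any particular MSA
program.

The consensus per column is: unanimous base → that base; exactly two bases
and no gap → the two-fold IUPAC code (R, Y, S, W, K, M); three or more
bases, or any gap, → N; all-gap columns drop. Primer pairs are enumerated on
the two consensi (forward on the left, reverse reported 5'→3' on the
opposite strand) under explicit constraints: length 18–27; Tm within
52–63 °C *across all degenerate expansions*; GC fraction 20–80%; at most 4
unknown (N) bases per pair; at most 3 non-N degenerate codes per pair (the
published panels of this kind carry at most two); no run of five identical
bases; 3'-terminal base a definite A/C/G/T; product size on the consensus at
most 600 bp. The Tm window brackets both a 55 °C annealing protocol and the
common 60 °C optimum. Pairs are ranked by Tm balance $|T_f - T_r|$, then by
mean distance from 60 °C. Rejected candidate classes are counted and
returned machine-readably. Product sizes are *reported* per genome (mapped
through the flank alignments plus each genome's tract length), never
constrained, because cross-species products legitimately differ.

Melting temperatures use unified nearest-neighbor duplex thermodynamics at
50 mM monovalent salt and 50 nM total oligo, evaluated over every expansion
of the degenerate codes (min and max are reported); N is substituted by the
least-stable base for the minimum and the most-stable for the maximum. The
implementation agrees with an independent reference to $10^{-4}$ °C. One
symmetry note: Tm is invariant under reverse complement (the same physical
duplex read from the other strand), but *not* under plain complementation,
which names a different oligo — the tests assert the former.

# Marker evaluation

For each locus and population the package reports $n$ (fully genotyped
diploids), allele count $A$, allele size range, observed heterozygosity
$H_O$ (heterozygote fraction) and Nei's unbiased expected heterozygosity

$$H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right).$$

The sample-size correction matters at the panel's typical $n = 10$: with
allele frequencies 0.9/0.1 the unbiased estimator gives 0.189 (printed
0.19), where the naive $1-\sum p_i^2$ gives 0.18 — only the unbiased form
reproduces the published per-locus values.

**Hardy–Weinberg deviation** is tested by Monte-Carlo randomisation of the
$2n$ observed allele copies into diploid pairings. The default statistic is
$\hat f = 1 - H_O/H_E$, compared two-sided on $|\hat f|$ — the design of the
classic F-STAT randomisation. P-values use the add-one convention
$p = (1 + \#\,\text{extreme})/(B+1)$, so $p$ is never zero and the test is
valid at any $B$. Because $H_O$ at small $n$ takes few values, large tie
masses make the $\hat f$ test *conservative* (empirically ~0.02–0.03
rejection at $\alpha = 0.05$, $n = 30$); a `statistic = "prob"` mode uses
the conditional probability of the genotype configuration given the allele
counts (Guo–Thompson style), whose fine-grained support attains the nominal
size — the calibration tests bound the probability mode inside
[0.035, 0.065] at $\alpha = 0.05$ and verify the $\hat f$ mode never exceeds
nominal. Both modes are deterministic for a fixed seed and invariant to
allele relabelling.

**Genotypic linkage disequilibrium** between two loci uses the
log-likelihood $G$ statistic on the two-locus genotype contingency table,
with one locus's genotypes permuted among the individuals genotyped at both
loci. A duplicated locus attains the minimal attainable p-value
$1/(B+1)$. **Bonferroni correction** is $\alpha/n_{\text{tests}}$; for a
24-locus panel evaluated in 6 populations the default test count is
$\binom{24}{2} \times 6 = 1656$, giving a per-test threshold of
$3.0 \times 10^{-5}$.

**Aggregation** follows the rules that reproduce a published panel
characterisation shipped with the package as a machine-readable fixture (24
loci × 6 ant species): per-species counts of polymorphic loci (and of
polymorphic loci in HWE) are averaged *across species*, while $A$, $H_O$ and
$H_E$ are averaged by *pooling* all polymorphic-in-HWE loci across species —
pooling, not averaging species means, is the only rule consistent with the
published pooled values (mean $A$ 4.59, $H_O$ 0.534, $H_E$ 0.61). The
fixture preserves two size ranges exactly as printed in reversed order,
flagged with corrected bounds rather than silently fixed, and the package
computes a polymorphic-and-in-HWE mean of 11.0 per species where the
published text states 11.16 — a discrepancy the fixture makes visible rather
than hides.

# Synthetic data: what it does and does not emulate

`make_genome_set` plants `n_loci` repeat loci in `k_genomes` genomes: each
locus has an ancestral flank pair (220 bp per side) copied into every genome
with i.i.d. substitutions at the stated divergence, and a perfect repeat
tract whose copy number is drawn per genome from `repeat_copy_range`.
Background sequence is i.i.d. uniform ACGT, re-randomised per genome, so
*only* the planted flanks are conserved. Defaults (8 genomes, 20 loci, 5%
flank divergence, 10–15 copies, 200 kb per genome) represent the regime the
pipeline is meant for: divergence well inside the 60% identity filter, and
repeat depths around the 10-copy selection threshold. Planted motifs default
to periods 3–5 so that the minimum planted depth (10 copies) clears the
score-50 reporting threshold; dinucleotide plants need ≥ 13 copies, which
the recall tests use explicitly.

`simulate_genotypes` draws diploid genotypes under an inbreeding coefficient
$f$: each individual's two allele copies are identical by descent with
probability $f$, otherwise drawn independently, giving
$P(\text{hom}_i) = p_i^2 + f p_i(1-p_i)$ and
$P(\text{het}_{ij}) = 2 p_i p_j (1-f)$. Same seed, same bytes, for both
generators.

Deliberate simplifications, hence what passing tests do *not* show about
real data: flank divergence is substitution-only by default (an indel-free
regime keeps identity arithmetic exact; real flanks accumulate indels),
base composition is uniform (no GC bias, no repeat families, no
low-complexity background), repeat tracts are planted perfect (no
interruptions), and allele frequencies are fixed parameters rather than the
outcome of a mutation model (no stepwise mutation, no coalescent). Recovery
and calibration results on this generator therefore validate the
*algorithms*, not performance on any particular clade's genomes.

# Validation scale and numerical choices

The shipped test suite runs the detector-vs-oracle equivalence on $10^4$
strings of ≤ 30 bp at thresholds 20/30/50; flank-search equivalence against
a reference Smith–Waterman on 2 kb targets; end-to-end recovery on ten
seeded replicates of the 8-genome/20-locus/200 kb generator (requiring
≥ 95% of planted loci recovered as `conserved_unique` with zero false
loci); and HWE calibration on 1000 replicates of $n = 30$ with $B = 199$
permutations. These sizes were chosen so the whole suite completes in a few
minutes on one core while keeping every Monte-Carlo bound comfortably
binding.

Remaining numerical conventions, in one place: coordinates are 0-based
half-open everywhere inside the package and convert to 1-based only at
report boundaries; permutation p-values are add-one; ties in permutation
statistics count as extreme (conservative); floating-point tie comparisons
use a $10^{-12}$ guard; DP tie-breaks prefer diagonal, then gap in the
second sequence, then gap in the first; the GenePop writer falls back to
rank-coded alleles (with a logged mapping) when sizes exceed its 3-digit
field, and the TSV dialect is the native lossless format.

# Known limitations

The flank search has no E-value model — significance is by identity,
coverage and a score floor, which is appropriate at within-clade divergences
but not for remote homology. Primer design checks base-run complexity only;
it does not model hairpins or primer-dimer thermodynamics. The subjective
final choice of a genotyping panel from the ranked candidates is explicitly
out of scope: the tool reports candidates, statuses and linkage, and stops
there.
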