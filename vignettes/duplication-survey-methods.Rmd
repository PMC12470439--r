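---
title: "Methods: surveying recurrent gene duplications and repeat-derived small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying recurrent gene duplications and repeat-derived small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dupscan` implements the computational side of a recurrent-gene-duplication
survey: how many copies of a gene family a genome carries and where; how
similar the copies are at the nucleotide and protein level; whether their
coding sequences evolve neutrally or under selection; how the copies relate
phylogenetically; whether repeat-embedded copies act as a double-stranded
small-RNA (piRNA) source with a ping-pong amplification signature; and what
protein-level features (intrinsic disorder, intragenic tandem repeats,
residue composition) distinguish diverged homologs. Because the real
substrate of such a survey is a set of genome assemblies and sequencing
libraries, the package ships seeded generators that emulate each data
structure with known ground truth, so every stage is testable at desk
scale. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic data do and do not establish.

# Sequence identity and microsynteny

Percent identity is defined on a pairwise global alignment as the number of
matching residues divided by the number of alignment columns, **excluding
gap-containing columns from both numerator and denominator**. `N` (or `X`)
never counts as a match: assemblies contain gap-filling `N` runs, and
counting them as matches would inflate identity across assembly gaps.

Alignment itself is standard machinery, not the package's contribution, so
`align_global()` delegates to `Biostrings::pairwiseAlignment` with a fixed
scheme: nucleotide match +1 / mismatch −1 with a length-`L` gap costing
`4 + (L − 1)`; protein BLOSUM62 with a gap costing `11 + (L − 1)`. On short
pairs the score is verified in the test suite against an exhaustive
alignment enumerator. Identity values computed this way are expected to
track identities from other aligner choices (e.g. MUSCLE) to within about
±1.5 percentage points, since the formula, not the aligner, carries the
definition.

A locus pair is *microsyntenic* when the fraction of shared flanking genes
strictly exceeds 15%. "Flanking" means up to three genes upstream and three
downstream (≤ 6 slots); sharing is order-insensitive and mediated by a
reciprocal-best ortholog map (`ortholog_map()`, protein identity ≥ 40%).
The 6-slot denominator uses the larger of the two loci's flank counts, so a
locus at a contig edge is not penalized for slots that do not exist. One
shared gene out of six (1/6 ≈ 16.7%) is already syntenic; exactly 15% is
not.

# Copy counting by seeded scanning

`homolog_scan()` estimates copy number by seed-and-verify search: exact
11-mer seeds on both strands anchor candidate full-length ungapped
placements of the query, each candidate is verified by direct mismatch
counting against identity and coverage floors, and same-strand hits that
overlap or abut within 50 bp are merged. The merge radius exists because
tandem copies separated by short spacers must not be double-counted when a
copy is hit by several seed anchors. The ungapped-verification design is
deliberate: the arrays this scanner is aimed at are recent, high-identity
duplications where indel divergence is negligible; a copy fragmented by
large insertions would be found as merged partial hits or missed, and that
limitation is stated openly rather than glossed over. Default floors (80%
identity, 80% coverage) are module policy, not a literature value: no
universal blastn cut-off defines "a gene copy", so the floors are exposed
as arguments and recorded with every report.

`dotplot()` reports all exact shared k-mers (both strands) for dot-matrix
comparison of two regions; it is validated against brute-force k-mer set
intersection.

# Selection: Nei–Gojobori with the Z-test of neutrality

For a codon-aligned pair, synonymous site counts per codon enumerate all
nine single-base neighbors; changes that create a stop codon count as
nonsynonymous, so every codon contributes exactly 3 sites and
`S + N = 3 × codons`. Differences for codons differing at 2–3 positions are
averaged with equal weight over all shortest substitution pathways;
pathways through stop codons are excluded (if all pathways pass through a
stop, all are used, with stop-involving steps counted as nonsynonymous — a
degenerate case that cannot occur for the codon pairs of a sense
alignment's shortest paths but is defined for completeness). Codons with a
gap or `N` in either row, and codons that are stops in either row, are
removed pairwise ("pairwise deletion"). Proportions are Jukes–Cantor
corrected, `d = −(3/4) ln(1 − 4p/3)`, with a saturation error at
`p ≥ 0.75`.

The variance of each distance is the delta-method form
`var = p(1 − p) / (L (1 − 4p/3)²)`; the Z statistic is
`(dN − dS) / sqrt(var dN + var dS)` against the standard normal, two-sided
for the neutrality test, lower-tailed for purifying selection, upper-tailed
for positive selection. Identical sequences give zero variance; the test is
then *undefined*, reported as a flag rather than an exception, because an
undefined test on identical paralogs is an expected outcome for
conversion-homogenized arrays, not an error.

Calibration is checked by simulation, not assumed: at the package's
reference conditions (300 codons, total pairwise divergence 0.1
substitutions/site, transition/transversion ratio κ = 2) the two-sided
rejection rate at ω = 1 sits near 0.05–0.07. The residual excess over the
nominal level is the known transition bias of the equal-weight pathway
estimator at κ > 1 (synonymous changes are enriched among transitions, so
dS is slightly overestimated); at larger divergences the bias grows, which
is why the reference conditions match sibling-species rather than
deep-phylogeny divergence. Power against ω = 0.1 at the same scale is
essentially 1.

# Alignment trimming and the distance tree

`gblocks_trim()` applies conserved-block rules to a codon alignment: a
column is conserved when strictly more than half of the rows agree on its
majority residue; a gapped column is kept only when at most `floor(rows/2)`
rows are gapped ("with half"); retained regions may not contain runs of
more than 8 contiguous non-conserved columns; retained blocks must span at
least 10 columns; and columns are dropped in whole codons. Because codon
rounding and block removal can expose new violations, the rules are
re-applied to the trimmed output until a fixed point — the output provably
satisfies both rules, which the test suite asserts on random noisy
alignments. The 8/10/"with half" parameters are the trimming conventions
for codon data; both are exposed as arguments.

Distances are Tamura–Nei (TN93), hand-implemented in closed form with the
two transition classes (A↔G, C↔T) separated from transversions and base
frequencies estimated as the empirical means of the two sequences. The
implementation is cross-checked in the tests against `ape::dist.dna(model
= "TN93")` to 1e-9 and against the K2P transversion limit on
frequency-balanced transversion-only pairs. The tree is neighbor joining
(`ape::nj`) on that matrix — a deliberate stand-in for likelihood tree
search: NJ is consistent on additive inputs (asserted exactly in the
tests), fast enough for bootstrap resampling, and sufficient for the
clade-level questions asked here (which copies form a recent monophyletic
array). Gamma-rate maximum likelihood inference is explicitly out of scope.
Bootstrap support resamples **codons, not columns** (500 replicates by
default), rebuilds the NJ tree each time, and reports the percentage of
replicates containing each internal bipartition; the replicate stream is
seeded and reproducible, and label permutation does not change the
supports. An alignment of identical rows yields a degenerate star-like
tree whose supports are flagged `NA` rather than fabricated.

# The small-RNA pipeline

Reads are filtered by length (23–30 nt inclusive — the piRNA size class)
and quality. The quality rule is interpreted as **mean** Phred strictly
greater than 30; a per-base minimum is a stricter alternative but discards
reads for single low-quality tails, which is not what a mean-quality
specification implies. Phred+33 is the only supported encoding.
Contaminant removal drops any read mapping to a structural-RNA reference
(rRNA, tRNA, sn/snoRNA, miRNA) with ≤ 1 mismatch on either strand.

`map_reads()` is an ungapped, mismatch-bounded mapper: `m + 1`
non-overlapping exact seeds anchor candidates for a read allowed `m`
mismatches, so by pigeonhole every qualifying placement is found —
completeness is asserted against a brute-force sliding-window scan in the
tests. The bound of ≤ 1 mismatch over the full read reproduces, for ≤30-nt
reads, the behaviour of a 30-nt-seed short-read mapper run with one
permitted seed mismatch; identity-fraction mapping (e.g. "min identity
0.95") is expressed as `max_mismatches = floor(0.05 × readlen)`.

*Locally unique* attribution is two-pass: pass 1 maps against the genome
with the focal interval excised, and any read that maps anywhere else is
discarded; pass 2 maps the survivors to the focal sequence. The returned
reads are, by construction, mappable only within the focal region — the
correct attribution unit for a repeat cluster whose spacer sequences recur
elsewhere in the genome. For counting and coverage, a read is placed once
at its minimal-mismatch, leftmost, plus-strand-first hit (deterministic);
all hits remain available in the hit table.

Counts are stratified by minimal mismatch count (0/1/2; the "0–2" row is
their sum) and strand, normalized as reads per million. The rpm denominator
is the number of reads surviving the length/quality and contaminant
filters, and it is recorded alongside the table so any alternative
denominator can be recomputed — which normalization a published table used
is often unrecoverable, so the package makes its own explicit.

The ping-pong statistic tallies, for each offset `o` in 1..25, the number
of (sense, antisense) read pairs whose 5′ ends overlap by exactly `o` nt;
the antisense 5′ end is its rightmost plus-strand base. The score
`z10 = (count₁₀ − mean(others)) / sd(others)` uses offsets 1..25 excluding
10 as background. With a zero background sd the score is undefined and
flagged. The histogram is validated against an O(n²) all-pairs oracle, the
null behaviour (|z10| < 2 in ≈95% of runs at zero planted bias) and the
monotone response of z10 to the planted bias are checked by simulation.

# Protein features

Disorder is consumed, not predicted: `disorder_fraction()` takes per-residue
scores in [0,1] (2-column TSV), calls a residue disordered at score ≥ 0.5,
calls the protein highly disordered at ≥ 50% disordered residues, and
reports maximal disordered runs of ≥ 50 residues as IDR intervals. Both
thresholds follow the conventions for per-residue disorder predictors; the
comparison directions (≥ in both cases) are stated here because predictor
documentation rarely specifies them.

`find_tandem_repeats()` detects intragenic arrays by self-alignment
periodicity: for each candidate unit length `u`, the sequence is compared
with itself shifted by `u`, the best run of shifted matches is found by
maximal-scoring-substring search (+1 match / −1 mismatch, flanking
mismatches trimmed), and a call requires mean shifted identity ≥ 60% and
≥ 2 copies. The reported span is the matched run plus one trailing unit, so
copy numbers are fractional (reported to one decimal, e.g. 6.5 copies).
Calls at an exact multiple of a smaller detected period covering the same
span are suppressed (the shift-2u self-match of a u-periodic array is not a
second array), then remaining overlapping calls resolve by score. On exact
arrays of random units (lengths 3–60, 2–12 copies) the detector returns the
unit period, never a multiple; with 5% substitution noise a planted
54-aa × 11 array is recovered with the correct period and ±0.5 copies.

`residue_composition()` reports the percentage of a residue set (default
D/E/S — the acidic/serine class typical of disordered repeat arrays) over
the whole protein or an explicit span, flagged strictly above 40%. The span
argument exists because "composition of the repeats" and "composition of
the protein" are different statements; both are computed in the analysis
scripts.

# Synthetic data: what it emulates, and what it does not

The codon evolver runs a κ/ω Markov substitution process (per-site
exponential waiting times; changes into stop codons rejected), normalized
so that one unit of branch length equals one expected neutral substitution
per nucleotide site. It is intentionally simpler than a full
codon-frequency model (GY94): uniform codon usage and no indels. That is
sufficient for its purpose — making dN/dS recoverable and calibrating the
Z-test — but it does not emulate codon-usage bias, indel evolution, or
rate heterogeneity, so passing tests say nothing about those properties of
real data. `evolve_family()` adds duplication events (a copy created at the
top of a stated branch) and gene conversion (each cluster member is
overwritten by the array consensus with a per-branch probability), which at
high rates maintains the >99% intra-array identity characteristic of
recently homogenized tandem arrays.

`build_cluster_genome()` lays out: unique random background, a focal
region of `n` repeat copies separated by transposon-like spacers
(composition-matched shuffles of one AT-rich base sequence), and exact
decoy copies of every spacer outside the focal region. The decoys are the
minimal structure that makes the locally-unique filter non-trivial: spacer
reads map both inside and outside and must be rejected, repeat reads must
not. Each repeat copy carries independent substitutions at rate 0.002 per
base by default, keeping pairwise intra-array identity above 99% on
average. Real pericentromeric repeat regions differ in ways the generator
does not model: nested and truncated transposon copies, segmental
rearrangements, and assembly gaps.

`simulate_small_rna()` draws sense reads uniformly over the repeat
intervals (lengths uniform on 23–30 nt, qualities Phred 33–40). In
dual-strand mode each sense read receives an antisense partner: with
probability `pingpong_bias` the partner's 5′ end sits exactly 10 nt into
the sense read (the ping-pong geometry); otherwise it is placed uniformly.
A configurable fraction of reads falls outside the focal region as
background. Real piRNA libraries additionally show a 1U/10A nucleotide
bias, non-uniform precursor coverage, and sequencing errors; none of these
are modelled, and conclusions from the simulations are limited to the
geometric/counting behaviour of the pipeline.

All generators require an explicit seed and route every draw through R's
RNG, so identical seeds give byte-identical outputs.

# Problem sizes and reproducibility

The shipped analysis scripts and tests run at desk scale, chosen as the
smallest sizes at which each statistical claim is stable: Z-test
calibration at 200–500 replicate pairs of 300 codons; tree recovery on 8
taxa × ~5 kb with 200–500 bootstrap replicates; mapper validation on
200–1000 reads against 20–50 kb references; ping-pong calibration on
libraries of 2000 reads over a 4-repeat cluster, 40–100 seeded runs; the
copy-number and attribution analyses on a 21-copy cluster in a ~75 kb
genome. `scripts/acceptance.R --seed N --out file.json` re-runs the
package's main computations from scratch at these sizes and writes the
resulting quantities as JSON; all randomness derives from the given seed.

# Known limitations

* The scanner and mapper are ungapped; indel-diverged copies and spliced
  reads are out of scope.
* NG86's equal-weight pathway convention slightly overestimates dS at
  κ > 1; the Z-test's type-I error is honest at sibling-species divergence
  but degrades with depth.
* NJ + bootstrap is a topology/support stand-in, not a substitute for ML
  inference when branch-length inference or rate modelling matters.
* The rpm denominator convention must be read from the report header when
  comparing against externally published tables.
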