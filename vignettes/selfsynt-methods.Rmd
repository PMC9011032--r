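---
title: "Recombination maps, chromosome domains and synteny in selfing nematodes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination maps, chromosome domains and synteny in selfing nematodes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfsynt)
```

# Scope

`selfsynt` implements the bespoke statistical steps of a chromosome-level
comparative-genomics study of selfing *Caenorhabditis* nematodes: building a
genetic map from a panel of selfed recombinant inbred lines (RILs) with a
series of marker-quality filters, segmenting the resulting Marey map into
recombination-rate domains, scoring gene-order collinearity between species
from single-copy ortholog ranks, summarising genome-wide divergence, and the
assembly/annotation QC arithmetic that accompanies a reference genome. Every
analysis is exercisable on synthetic data with recorded ground truth, so the
whole pipeline is testable without any external downloads.

# The RIL simulator

`simulate_ril_panel()` reproduces how such panels are built in the lab. A
chromosome's recombination landscape is a piecewise-constant rate in cM/Mb
(`rec_landscape()`), following the canonical tip / arm / center / arm / tip
structure of holocentric nematode chromosomes: near-zero-rate terminal tips,
high-rate arms, and a low-rate center.

Each line starts as a genome-wide F1 heterozygote; an F2 is formed by the
union of two F1 gametes; the line is then self-fertilized for
`selfing_generations` rounds (default 10, the panel design the map pipeline
assumes) with both homologs tracked explicitly. Per meiosis and chromosome
the crossover count is Poisson with mean equal to the map length in Morgans
— no crossover interference, which is also the assumption of the Haldane map
function used downstream — and crossover positions are drawn with density
proportional to the local rate. Residual heterozygous sites at the end are
emitted as `HET` rather than being resolved, because real RIL panels retain
rare heterozygous calls and the filters must tolerate them.

Simulating selfing explicitly, rather than using the Haldane–Waddington
shortcut R = 2r/(1+2r), turns that shortcut into a testable limit: the test
suite verifies that the observed RIL recombination fraction between two
markers converges to it, and that residual heterozygosity after an F2 plus
ten selfing rounds is close to $2^{-11}$ (one half at the F2, halved per
generation).

Marker artifacts can be planted with recorded truth: `distorted` (a line's
call is redrawn as P1 with probability 0.85 — strong enough that a
chi-square test must catch it, weak enough not to be degenerate),
`freq_spike` (15% of lines forced to P1, shifting the local allele frequency
by about 7–8 percentage points, comfortably past the 4% filter threshold
while staying in the range of the skews the filter is meant to catch), and
`unlinked` (calls redrawn 50/50, independent of the genome). These
magnitudes are simulator defaults, not filter inputs.

The simulator does not model sequence-level reads, hyper-divergent haplotype
evolution, segregation-distorting selection, or mitochondrial inheritance
from the reciprocal crosses; passing tests therefore say nothing about those
features of real panels.

# The map pipeline

Filters run in the order the study applied them, each producing a
`filter_report`:

1. **Segregation distortion** (`filter_segregation_distortion()`): per
   marker, homozygous P1/P2 counts are tested against 1:1 by chi-square.
   The source analysis names only the helper used, not its threshold; here
   the rule is Bonferroni-adjusted p < 0.05 across tested markers, a
   conventional family-wise control for a few thousand tests.
2. **Linkage-group membership** (`form_linkage_groups()`): single-linkage
   clustering in which a marker pair joins when pairwise R < 0.35 and
   LOD > 6; markers in groups of fewer than 5 are flagged. The defaults
   were chosen to give clean chromosome-sized groups at RIL sample sizes;
   only the outcome (six groups, a few stray markers) is constrained by the
   study.
3. **Local allele-frequency deviation**
   (`filter_allele_frequency_deviation()`): the 4% rule. The P1 frequency
   of every marker (HET counted one half) is compared with the nearest
   unflagged flanking markers; a contiguous run in which every member
   deviates by at least 0.04 from both flanks (single side at chromosome
   ends) is flagged, shortest qualifying run first, iterating with
   re-anchored flanks to a fixpoint. Flagging the shortest run first
   matters: the deviant group is the minority, and preferring long runs
   would let one outlier marker condemn its entire chromosome flank.
4. **Locally excessive recombination** (`estimate_genetic_map()` with
   `high_rec_rate_threshold`): the study removed 22 such markers manually;
   here the step is reproducible as a cM/Mb threshold on adjacent
   intervals, disabled by default. For an offending interval, the endpoint
   whose removal yields the lower merged-interval rate is flagged and the
   map re-estimated once.

Distances come from adjacent-interval recombination fractions (physical
order is trusted; multipoint estimation and marker ordering are out of
scope). The observed fraction R is clamped to [0, 0.499], corrected for the
selfing design to the meiotic fraction r = R/(2(1−R)), and converted by the
Haldane map function d = −50·ln(1−2r) cM. Whether the original analysis
used adjacent-pairwise or a multipoint estimator internal to its cross
object is not stated; adjacent-pairwise is implemented and recovers
simulated map lengths within the tolerances quoted below.

`impute_genotypes_hmm()` fills genotypes from low-coverage allele counts.
The source pipeline names a hidden Markov model without defining it, so the
model is specified here: two hidden states (P1/P2 — heterozygous states are
excluded for inbred lines), reads i.i.d. with probability 1−error of
matching the hidden parent, and a per-interval switch probability
λ·Δbp/L capped at 0.5, with λ the expected number of genotype switches per
chromosome (about twice the chromosome's length in Morgans for a selfed
RIL). Posterior-mode states are called only at posterior ≥ 0.95, a
conservative threshold that leaves ambiguous sites missing rather than
guessing.

`allele_frequency_profile()` averages marker frequencies in 100-kb windows
stepped by 5 kb (half-open, anchored at 0) for transmission-ratio scans.

# Marey-map domain segmentation

`fit_segmented_marey()` fits genetic position against physical position as a
continuous piecewise-linear curve with two breakpoints (left arm, center,
right arm). The fit minimises RSS by a grid search over breakpoint pairs
restricted to marker positions between the 3rd and 3rd-from-last markers
(avoiding two-point segments), thinned to at most 60 candidate positions,
then refines by Muggeo-style iterative linearization until breakpoints move
by less than 1 bp or 50 iterations, keeping the grid optimum if refinement
fails to improve. Grid ties break toward the more central pair for
determinism. Breakpoint standard errors come from the linearization's
parameter covariance (a bootstrap would also be defensible; the
linearization SE is what segmented-regression software conventionally
reports). Perfectly collinear input is flagged `no_changepoint`. A
`truncate_after_bp` option reproduces the study's handling of one chromosome
whose sparse left arm required excluding markers beyond 15 Mb before
fitting; truncation is always an explicit per-chromosome decision, never
automatic.

Tip domains are near-zero-rate terminal segments that a two-breakpoint model
cannot represent, and the study called them manually. `call_tip_domains()`
makes the call algorithmic: a tip is the maximal terminal run of at least 2
inter-marker intervals whose local rate is below 0.1 of the adjacent arm's
fitted slope, with the boundary at the outermost marker of the non-tip
region. The defaults reproduce zero-rate tips without firing on ordinary
arm noise.

`build_domain_table()` assembles the five-domain summary (sizes in kb and
percent, right-end positions, rates) with each chromosome's rates rescaled
so its genetic length is 50 cM — the convention that makes rates comparable
across chromosomes of one map and across studies. Domain sizes sum to the
chromosome length exactly and the scaled rates integrate back to 50 cM on
noiseless input.

# Collinearity and synteny

The rearrangement statistic avoids inferring individual events, which is
unreliable at *Caenorhabditis* rearrangement rates, and instead counts
broken adjacencies. `rank_single_copy_orthologs()` keeps orthogroups that
are single-copy in every included species and numbers the retained genes
along each chromosome (among retained genes only, since the statistic is
defined on the orthologous gene set). `score_collinearity()` then marks each
rank-adjacent reference pair collinear iff the two target orthologs share a
chromosome and differ by exactly 1 in rank. Absolute rank distance makes
the rule orientation-agnostic — a whole-chromosome reversal is fully
collinear — and cross-chromosome orthologs cannot be "distance one", so a
translocated gene breaks its pairs. Window summaries use nonoverlapping
500-kb windows anchored at 0, with each pair assigned by the mean of its two
reference genes' start positions (the assignment rule is not pinned down by
the source; the pair midpoint is the symmetric choice). Blocks are maximal
runs of consecutive collinear pairs, so per chromosome the block gene counts
minus one sum exactly to the collinear pair count — an identity the tests
enforce on every random instance.

The rearranged-genome simulator provides the oracle: m disjoint, internal,
non-adjacent inversions produce exactly 2m noncollinear pairs, and a
single-gene translocation breaks between 1 and 3 pairs depending on the
reference direction. `extract_longest_isoforms()` picks each gene's
representative as the mRNA with the greatest summed CDS length (ties by
lexicographic isoform ID), matching protein-centric orthology clustering;
`patristic_distance()` reads branch lengths off a phylogeny for the
divergence context of the species comparisons.

# Divergence summaries

`protein_identity()` scores pairwise protein alignments as matches over
columns where both rows carry a residue; gap columns are excluded from
numerator and denominator alike (the upstream "custom script" rule was
unstated; this is the symmetric convention, and permuting the rows leaves
the value unchanged). `identity_track()` smooths identity along each
chromosome with tricube-weighted local linear regression (span 0.3 by
default — the smoother family is given by the study, the span is not; 0.3
follows the visual scale of genome-wide divergence figures). `snv_density()`
reports bp-per-SNV per chromosome and per chromosome class, aggregating
counts and lengths before dividing, with the full chromosome span as the
denominator. `filter_inversions()` applies the ≥50-kb inversion filter with
the threshold as a parameter for secondary cutoffs.

# QC arithmetic

`assembly_metrics()` splits scaffolds into contigs at runs of ≥10 Ns (9 Ns
do not split; only N/n counts, soft-masking is ignored) and reports spans,
N50s and gap totals. `qv_error_conversion()` is the Phred-style decibel
conversion between consensus QV and bases-per-error.
`estimate_repeat_copy_number()` scales assembled copies of a collapsed
tandem repeat by the region-to-genome coverage ratio.
`telomere_scan()` calls a scaffold end telomeric when at least half of its
terminal 1 kb is covered by the nematode telomere hexamer `TTAGGC` in either
orientation; the window and coverage thresholds are this package's own
operational definition of "ends in telomeric repeat", and the same scanner
doubles as a generic motif-block scan for subtelomeric repeat units.
`reciprocal_best_hits()` implements the tie-tolerant RBH rule (best =
minimal e-value, then maximal bit score, exact ties all kept; reciprocal if
any tied best is reciprocal) and `protein_length_concordance()` counts
gene-level exact and within-5% length matches, with the reference-species
length as the denominator of the 5% rule.

# Problem sizes, numerics, and what the tests show

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make sampling error small relative to the tolerances they
check: 2,000 lines for the heterozygosity decay (binomial error ~10% of the
expectation), 99 lines and 450 markers for map-length recovery (the panel
size the pipeline is designed for; per-chromosome relative error has
standard deviation around 7–8% at ~85 cM chromosomes, against a 15%
tolerance), 200 replicates at σ = 1 cM noise for breakpoint recovery
(observed errors average well under 100 kb against a 250-kb criterion), and
exact integer identities for the collinearity and QC checks. Degenerate
inputs are handled explicitly: zero-rate landscape segments receive no
crossovers, zero-informative intervals raise an error naming the interval,
collinear Marey inputs are flagged rather than fitted, and symmetric
single-marker HMM evidence yields a missing call rather than a coin flip.

Known limitations: the map estimator is adjacent-pairwise, not multipoint;
tip calling is rule-based where the original calls were manual; the
frequency filter's behaviour on long-range, smooth transmission skews
(as opposed to local deviations) is deliberately conservative; and none of
the simulators attempt sequence-level realism, so agreement on synthetic
panels bounds implementation correctness, not biological fidelity.
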