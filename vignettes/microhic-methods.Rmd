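---
title: "Methods: models, parameters and design choices in microhic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in microhic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microhic)
```

microhic analyses Hi-C chromatin contact maps of small, fungal-sized genomes:
from binned contact matrices to self-interacting domains ("globules"),
statistically significant cis and trans contacts, trans-contact-based
centromere calls, Rabl-type classification of the nuclear architecture, a 3D
coordinate model, and transcription-factor motif scanning at domain
boundaries. This vignette records the models behind each stage, the
parameters that matter, and the reasoning behind design choices that the
published tools this pipeline mirrors leave open.

## The synthetic data generator

Deposited Hi-C sequencing data are large and organism-specific; the package
therefore ships a generator (`sim_params()`, `simulate_genome()`,
`expected_intensity()`, `sample_contacts()`) that emulates the statistical
structure the analyses assume, with full ground truth. It is first-class,
tested code: every recovery and calibration result in the test suite is
defined against its output.

The generator's default regime is a compact filamentous-fungus genome:

* 8 chromosomes of 1.8–5.9 Mb (~31 Mb total), i.i.d. sequence at GC 0.5;
* tandem telomeric repeats `(TTAGGGG)x5` at chromosome ends, planted as the
  reverse complement `(CCCCTAA)x5` at 3' ends, with the 3' end of the last
  chromosome left bare to mimic an incompletely assembled telomere;
* one regional centromere per chromosome, default width 160 kb (the scale
  typical of filamentous fungi; placed with its midpoint uniform in the
  central half of the chromosome);
* self-interacting domains of 2–80 kb tiling both chromosome arms
  independently, sizes uniform on the bin grid; the single bin at each
  junction between consecutive domains is the ground-truth boundary;
* genes of 0.5–3 kb placed uniformly without overlap, one per ~3.15 kb,
  each with a 1.5-kb promoter kept clear of chromosome edges where possible.

The expected intensity over bin pairs factorises into a cis and a trans
part. Cis pairs at bin distance $d$ have

$$\lambda_{ij} \propto (d + d_0)^{-\alpha}\,\beta^{\,[\text{same domain}]}
  \cdot \text{loop fold},$$

with decay exponent $\alpha = 1$ (a convention; measured genome-wide
exponents vary between organisms and protocols), offset $d_0$ of one bin, and
intra-domain boost $\beta = 2$. Trans pairs have a flat baseline times
$1 + k_c c_i c_j + k_t t_i t_j$, where $c$ and $t$ are centromeric and
telomeric bin weights ($k_c = 4$, $k_t = 2$ by default). The weights follow
a trapezoid: 1 inside the annotated interval, decaying linearly to 0 over
one bin beyond each edge, averaged per bin. The trapezoid (rather than a
midpoint indicator) keeps the intensity field centred exactly on the true
centromere regardless of how the interval sits on the bin grid, which
matters when centromere calls are scored at one-bin tolerance.

The cis/trans split is controlled by `trans_frac` (default 0.25): the
expected share of reads that are trans. A per-pair trans baseline defined
relative to the short-range cis intensity is not usable here — the number of
trans pairs grows with the square of the bin count, so any fixed per-pair
ratio makes the trans share resolution-dependent and, at fine bins,
dominant, contradicting the cis-dominance that real fungal Hi-C maps show.
A read-share parameter is resolution-independent; 25% trans is within the
range of typical fungal Hi-C libraries.

Counts are independent Poisson draws given $\lambda$ (negative binomial if
`dispersion > 0`; off by default), normalised so the genome-wide expected
read count equals `n_pairs` (default $10^6$; a deliberate scale-down of a
real fungal Hi-C library, which delivers on the order of $10^8$ valid
pairs). Trans background counts are drawn in aggregate and scattered
uniformly — distributionally identical to per-pair draws by Poisson
superposition/thinning, and much faster at fine resolutions. The generator
plants no diagonal (self-pair) counts: the diagonal is excluded from
significance testing, from the insulation square, and from decay strata, so
it would carry no information. Everything is deterministic under a fixed
seed.

What the generator does *not* emulate: restriction-site spacing and ligation
chemistry, mappability and GC bias, copy-number variation, A/B-compartment
structure, and — important for the 3D stage — any distance structure in the
trans contacts beyond centromere/telomere bundling. Passing recovery tests
on this generator therefore demonstrates correctness of the algorithms under
the stated statistical model, not performance on real libraries.

## Contact-matrix summaries

`decay_curve()` stratifies cis bin pairs by separation (geometric strata,
factor 1.25, or one stratum per bin distance) and reports per-pair contact
probability; `decay_slope()` fits the log-log slope by weighted least
squares. On boost-free simulations the fitted slope recovers $-\alpha$
within $\pm 0.1$ at $5 \times 10^5$ pairs.

`reproducibility_score()` is a random-walk concordance in the spirit of
GenomeDISCO: per chromosome, each cis matrix becomes a row-stochastic
transition matrix, raised to the third power (the upper end of the published
1–3 step sweep, fixed rather than optimised); the score is
$1 - \tfrac{1}{2}\,\|P_1^3 - P_2^3\|_1 / n$ averaged over chromosomes and
clipped to $[0, 1]$. Bins with zero degree in both replicates are dropped;
the denominator counts the union of retained bins. Because transition
matrices normalise scale away, the score is invariant to global count
scaling and equals 1 exactly for identical matrices. No matrix balancing
(ICE) is applied anywhere in the pipeline: the significance model consumes
raw counts.

## Insulation score and globule calling

The raw insulation score of bin $i$ is the mean count in the $w \times w$
square upstream-by-downstream of the bin, restricted to one chromosome.
Squares are never truncated: bins within $w$ bins of a chromosome end are
masked invalid, so scores are comparable along the chromosome. The
normalised score is $\log_2(\text{raw} / \text{chromosome mean of raw})$,
the mean over valid bins only (chromosomes differ in coverage, so
per-chromosome rather than genome-wide normalisation).

Two defaults here are deliberate choices where the mirrored tools are
silent. First, the window: planted domains average ~21 kb (~10 bins at 2
kb), so a 10-bin window is as large as a typical domain and averages the
junction dip away; the single-window default is 5 bins, and the recommended
caller, `insulation_multiscale()`, averages normalised tracks over windows
of 6–12 bins and applies a 3-bin moving mean. Averaging across window sizes
suppresses the window-scale correlated noise of a single-window track
(adjacent squares share most of their cells, so single-window noise is
smooth and produces spurious dips at exactly the scale of real boundaries).

Second, the boundary statistic. `call_boundaries()` offers two strength
definitions. The `"prominence"` rule — depth of a local minimum below the
nearer of its flanking local maxima (valid-segment endpoints count as
flanks) — is transparent but unstable under correlated noise: nearest
flanking maxima are themselves noise features. The default `"flank"` rule
is a matched filter: the strength of bin $i$ is the mean score over the two
flanking windows (2–7 bins away on each side) minus the score at $i$, and
boundaries are local maxima of this statistic reaching `min_strength`. At
the default study conditions the flank rule raises boundary F1 from ~0.75
to ~0.87 at identical recall bookkeeping. `min_strength` defaults to 0.25
log2 units, above the ~0.2-unit prominence floor that sampling noise
produces at $10^6$ read pairs; a 0.1 threshold admits noise dips wholesale.

Globules are the intervals between consecutive boundary bins, closed by
chromosome ends; boundary bins belong to neither flanking globule. Each
bin is labelled `boundary`, `interior` or `edge` (insulation mask).
`globule_bin_stats()` compares boundary and interior bins on per-bin gene
count, mean expression and GC by two-sided Wilcoxon rank-sum tests,
reporting `NA` when a class has fewer than two informative bins or a metric
is degenerate.

## Contact significance

`fit_distance_prior()` re-implements the distance-stratified null of
spline-based Hi-C significance callers with deliberate simplifications:
equal-occupancy strata (default 100, each carrying a similar share of the
cis reads), stratum probability = read share / possible pairs, isotonic
(non-increasing) correction by pooled-adjacent-violators, piecewise-linear
interpolation in log distance, and renormalisation so the expected total
probability over all cis pairs is 1. The published tool's second
refinement pass (outlier-bin removal) is omitted — acceptance is
calibration-based, not count-matching. Monotone piecewise-linear
interpolation is used instead of a free cubic spline because it guarantees
positivity and monotonicity without knot tuning.

`cis_significance()` tests every cis pair with at least one read: the
p-value is the exact binomial upper tail of the observed count in
$N_\text{cis}$ trials at the prior's per-pair probability;
Benjamini–Hochberg q-values run over all tested cis pairs. The diagonal is
excluded. `trans_significance()` uses the uniform null (one over the
number of possible trans pairs, $N_\text{trans}$ trials), corrected
separately — cis and trans are never pooled. The tested universe (pairs
with $k \ge 1$) is recorded in the result metadata. `filter_significant()`
applies the reporting thresholds, defaults $q \le 0.01$ and count $\ge 3$
("more than 2 reads"; the count rule dominates, so a pair with two reads is
dropped however small its q-value).

Under null simulations from the fitted prior ($10^6$ reads, 10-kb bins) the
empirical type-I error at $p \le 0.01$ sits near 0.011 — inside the
(0.005, 0.02) band that discreteness of small counts allows. For
false-discovery calibration, 50 loops at 8-fold enrichment are planted at
separations of 3–30 bins (30–300 kb at 10 kb): that is the separation range
in which an 8-fold boost clears the one-read noise floor at $10^6$ pairs,
i.e. the regime where a recall target is meaningful — loops planted beyond
~400 kb have expected counts below one read and are undetectable by any
method at this depth. Realised FDR at $q \le 0.05$ averages ~0.04 with
recall above 90%.

## Centromeres, aggregate chromosome analysis, Rabl classification

`trans_profile()` sums each bin's contacts to other chromosomes (each pair
counted at both ends), flags bins within `max(2 bins, 40 kb)` of chromosome
ends (telomere bundling otherwise masquerades as a centromere), and smooths
with a 5-bin moving mean. `call_centromeres()` takes, per chromosome, the
contiguous run of bins rising at least halfway from the chromosome's median
to its maximum, anchored at the leftmost argmax. The halfway rule is
measured from the median, not from zero: the uniform trans background is
always more than half the peak here, so a "50% of maximum" rule would
select entire chromosomes. The reported midpoint is then refined by a
Poisson template fit — a boxcar-on-flat-background model slid over the raw
per-bin counts on a 0.1-bin grid with the width profiled over a small range
— which is standard peak localisation and approaches the information limit
of the counts; run-edge quantisation alone recovers only ~90% of planted
centromeres within one 20-kb bin, the template fit ~97%. Chromosomes whose
smoothed profile has max/median below 2 are flagged `flat` (the expected
outcome when centromere bundling is absent).

`aca()` rescales every chromosome arm to `F = 20` slots
(overlap-weighted averaging; arms shorter than `F` bins are averaged, never
interpolated beyond data) and aggregates all chromosome pairs over both
orders and both orientations into one $2F \times 2F$ isochromosome map,
centromere slots adjacent at the centre, telomeres at the corners, then
symmetrises. The aggregate map includes cis and trans signal; the corner
scores (mean of the central $3 \times 3$ centromere block and of the four
$3 \times 3$ telomere corners, each over the map mean) are computed on the
trans-only aggregation, where bundling is not swamped by the cis diagonal.
`classify_rabl()` calls `type_I_rabl` when the centromere score reaches 1.5
(inclusive). The map is invariant to chromosome input order and to
reflecting any chromosome, by construction of the orientation sweep.

## 3D embedding

`counts_to_wish_distances()` converts observed counts to target distances
$\delta_{ij} = c_{ij}^{-1/3}$ (the count-to-distance convention of
MDS-based structure tools; the exponent is a flag), rescaled so the median
adjacent-bin distance is 1. Unobserved pairs are missing, not far.
`mds_embed()` minimises the weighted squared stress
$\sum w_{ij} (\|x_i - x_j\| - \delta_{ij})^2$, $w_{ij} = \delta_{ij}^{-2}$,
by SMACOF majorisation from a deterministic start: classical scaling of the
wish-distance matrix completed by graph shortest paths. Repeated runs are
identical without a seed; stress is non-increasing at every iteration by
construction (asserted in the tests); disconnected graphs embed the
largest component and flag the rest.

A limitation worth stating plainly: under this package's generator the
trans intensity is flat apart from bundling, so trans wish distances are
essentially constant, and no 3D configuration can hold the ~$10^6$
inter-chromosomal bin pairs of an 8-chromosome genome mutually equidistant.
The genome-wide Pearson correlation between embedded and wish distances
therefore saturates near 0.45 at any sequencing depth, and even the ideal
single-chromosome case — exact noiseless intensities, converged SMACOF —
caps near 0.89, because the $d^{1/3}$ wish metric is a space-filling-curve
scaling not exactly realisable in three dimensions. These ceilings are
properties of the data model, not of the optimiser: the same machinery
recovers exact synthetic geometries (a 50-point helix) to Procrustes RMSD
below $10^{-3}$ of the helix radius. Fit-quality on simulated Hi-C should
be judged against these ceilings.

`structure_metrics()` reports centromere/telomere clustering ratios (mean
pairwise distance within the set over the mean of 100 seeded random
equal-size bin sets) and a per-chromosome clothes-pin score: distance
between centromere and telomere centroids over the chromosome's radius of
gyration. On default Rabl simulations the centromere ratio falls below 1
(clustering), as the bundled trans contacts demand.

## Motif scanning at boundaries

`scan_pwm()` scores both strands of every window by summed log2 odds
(motif probability over a 0-order background estimated from the scanned
sequence and strand-symmetrised; uniform background is a flag). PFM counts
receive a pseudocount of 0.25 per cell before normalisation. The p-value of
a score is the upper-tail mass of the exact null distribution, computed by
dynamic programming over motif positions with scores discretised to a
$10^{-3}$-log2-unit grid; for motifs of width $\le 6$ the DP distribution is
verified against full enumeration of all $4^w$ words. Hits at
$p \le 10^{-4}$ (the conventional default) are reported without
multiple-testing correction, matching common practice for motif scans;
boundary proportions are descriptive ranks. A boundary "contains" a motif
when any hit overlaps it by at least 1 bp; ties in the proportion ranking
break by motif id. Note the chance-containment rate for a boundary of
length $L$ is $1 - (1 - p_\max)^{2(L - w + 1)}$ — about 0.33 for a 2-kb
boundary and an 8-bp motif at defaults — so planted-fraction recovery is
assessed against this inflation, and proportions from long boundary
intervals should be read comparatively, not absolutely.

`promoters()` takes the 1.5-kb window 5' of the gene start on its strand,
truncated at chromosome edges; genes without strand are skipped with a
warning.

## Gene-level annotation

Genes are assigned to globule boundaries/interiors by the bins they overlap
(at least 1 bp; genes touching both classes are `spanning`). Significant
contacts map to every gene overlapping either anchor bin; per-gene cis and
trans tallies count each contact once per overlapped gene, and contacts
touching no gene are tallied as intergenic. Hub rankings sort descending
with gene-id tie-breaks. `telomere_repeat_scan()` looks for at least
`min_copies` tandem repeat units in the outer 5 kb of each chromosome end
(unit as written at 5' ends, reverse complement at 3').

## Problem sizes and reproducibility

The test suite and the demonstration pipeline run at the generator's
default scale — 8 chromosomes (~31 Mb), $10^6$ read pairs, 2-kb bins for
domain calling, 10-kb bins for significance, 20-kb bins for centromeres,
ACA and the 3D model — with calibration and recovery properties evaluated
over multiple seeds (5 for type-I error, 20 for FDR/recall and for
boundary/centromere/Rabl recovery). `run_pipeline()` additionally plants a seeded set of point interactions
(150 cis loops at 30-300 kb, 60 trans loops; `demo_loops()`) so the
significance and hub-gene stages act on genuine signal, writes every stage
output as plain text, and is byte-reproducible under a fixed seed; all stage
seeds derive from the master seed. `scripts/acceptance.R` recomputes the
headline quantities from scratch on seeded simulations and writes them as
JSON.
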