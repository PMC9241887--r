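# microhic

Hi-C contact-map analysis for small genomes, in tidy R.

Chromosome conformation capture (Hi-C) turns spatial proximity of genomic
loci into read pairs; binned into a contact matrix, those counts expose how
a genome folds. In compact fungal genomes the interesting structure sits at
scales mammalian tooling often skips past: self-interacting domains
("globules") of just 2–100 kb delimited by insulating boundaries, strong
centromere–centromere and telomere–telomere inter-chromosomal bundling (the
Rabl configuration), and chromosomes folded like clothes-pins with the
centromere at one end. `microhic` implements that analysis stack end to end
for analysts working on fungal-sized genomes, with every function taking
and returning tidy tables:

* **Contact matrices** — sparse symmetric bin-pair counts, with readers and
  writers for chrom.sizes, valid-pairs text, triplet matrices, BED,
  GFF-lite, FASTA and JASPAR PFMs.
* **Matrix summaries** — contact-decay curves (cis contact probability
  `P(d) ~ (d + d0)^-alpha`), cis/trans partitions, and a GenomeDISCO-style
  random-walk reproducibility score between replicates.
* **Globule calling** — insulation scores (mean counts in a `w x w` square
  sliding along the diagonal, `log2`-normalised per chromosome), multi-scale
  averaging, boundary calling by a matched-filter dip statistic, and
  segmentation into globules with boundary/interior gene statistics
  (Wilcoxon tests on gene density, expression, GC).
* **Contact significance** — a Fit-Hi-C-style distance-decay prior
  (equal-occupancy strata, isotonic monotone smoothing, renormalisation)
  with exact binomial upper-tail p-values for cis pairs, a uniform-null
  binomial test for trans pairs, separate Benjamini–Hochberg FDR, and the
  conventional reporting filter (`q <= 0.01`, more than 2 reads).
* **Nuclear organisation** — centromere calling from per-bin trans-contact
  profiles (with a Poisson template-fit midpoint), aggregate chromosome
  analysis (arms rescaled to a common axis, aggregated over all chromosome
  pairs and orientations), and Rabl type-I classification from the
  centromere corner score.
* **3D modelling** — counts to wish distances (`delta = count^(-1/3)`),
  metric MDS by SMACOF majorisation with a deterministic classical-scaling
  start, and structural metrics (centromere/telomere clustering ratios,
  clothes-pin scores).
* **Boundary motifs** — PWM scanning with exact DP p-values under a 0-order
  background, FIMO-style defaults, boundary-containment proportion ranking,
  and 1.5-kb promoter scans.
* **Synthetic data** — a fully seeded generator of Rabl-structured Hi-C
  (power-law decay, planted domains, centromere/telomere bundling, Poisson
  sampling, telomeric repeats, boundary-planted motifs) with complete
  ground truth, used throughout the tests.

Results come back as tibbles or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()` figures, so they drop straight into dplyr/ggplot2
workflows.

## A worked example

Simulate a small Rabl-structured genome with planted domains, call
globules, centromeres and the architecture class:

```r
library(microhic)

params <- sim_params(n_chrom = 4, chrom_len_range = c(8e5, 1.2e6),
                     n_pairs = 4e5, cen_width = 60000)
truth <- simulate_genome(params, seed = 1, with_sequence = FALSE)
truth
#> <hic_truth> 4 chromosomes, 96 planted domains, 88 boundaries, 673 genes (no sequence)

hic <- sample_contacts(expected_intensity(truth), seed = 2)
hic
#> <contact_matrix> 2026 bins @ 2000 bp; 216583 nonzero pairs; cis 299675, trans 99780

decay_slope(decay_curve(hic))
#> [1] -1.17          # close to the planted decay exponent of -1

track    <- insulation_multiscale(hic)
globules <- segment_globules(call_boundaries(track), hic$bins,
                             valid = track$valid)
glance(globules)
#> # A tibble: 1 x 5
#>   n_globules n_boundaries min_kb max_kb median_kb
#> 1         86           82      4    106      41.1

boundary_f1(globules$boundaries, truth, hic$bins)
#> [1] 0.918          # called boundaries vs planted truth, +-1 bin

hic20 <- sample_contacts(expected_intensity(truth, 20000), seed = 3)
cens  <- call_centromeres(trans_profile(hic20))
cens[, 1:4]
#> # A tibble: 4 x 4
#>   chrom   start    end    mid
#> 1 chrI   300000 400000 342000    # truth: 314000-374000 (mid 344000)
#> 2 chrII  580000 680000 624000
#> 3 chrIII 640000 740000 698000
#> 4 chrIV  600000 700000 652000

am <- aca(hic20, cens)
am
#> <hic_aca> 40x40 map; cen score 3.45, tel score 1.99
classify_rabl(am)
#> [1] "type_I_rabl"  # centromere corner score >= 1.5
```

The numbers mean: the fitted decay slope recovers the generator's power-law
exponent; 86 globules of 4–106 kb are segmented from 82 insulation
boundaries, matching the planted boundary set with F1 = 0.92 at one-bin
tolerance; each called centromere midpoint lands within one 20-kb bin of
the planted centromere; and the centromere corner of the aggregate
chromosome map is 3.5-fold enriched over the map mean, classifying the
architecture as Rabl type I.

Significance testing and the 3D model follow the same pattern:

```r
prior <- fit_distance_prior(hic)
sig   <- filter_significant(cis_significance(hic, prior),
                            trans_significance(hic))
tidy(sig)            # chrom1/start1/end1/chrom2/start2/end2, count, p, q, kind

structure <- mds_embed(counts_to_wish_distances(hic20))
glance(structure)    # stress, iterations, convergence
structure_metrics(structure, truth$layout)$cen_ratio   # < 1: clustered
```

`run_pipeline(outdir, seed)` chains every stage on a simulated dataset and
writes all outputs (matrices, tracks, BED files, significance tables,
coordinates, reports) as plain text; the run is byte-reproducible for a
fixed seed.

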