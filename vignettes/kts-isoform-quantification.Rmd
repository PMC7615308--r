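---
title: "Quantifying WT1 +KTS/-KTS isoform usage from junction reads and BaseScope images"
author: "wt1kts package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying WT1 +KTS/-KTS isoform usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wt1kts)
```

## The measurement problem

WT1 is produced in two isoform families that differ by a single tripeptide,
Lys-Thr-Ser (KTS), inserted between zinc fingers 3 and 4. The insertion is
controlled by two competing 5' splice donors at the end of exon 9: the
canonical donor produces -KTS transcripts, and an alternative donor 9 nt
further downstream (in transcription direction) appends the three KTS codons.
The +KTS/-KTS balance steers the fate of gonadal supporting cells, and
Frasier-type donor mutations that abolish +KTS shift the balance toward
-KTS. Two questions follow directly from this biology:

1. **Per cell, what fraction of Wt1 transcripts is -KTS?** Only sequencing
   reads that span the exon-9/exon-10 splice junction can distinguish the
   isoforms, because the two mature mRNAs differ by just those 9 nt.
2. **In tissue, how much probe signal of each isoform does each cell
   carry?** BaseScope in situ hybridization resolves the 9-nt difference as
   discrete dots; the readout is probe area in um^2 per nucleus.

This package implements both quantification arms, the group-level statistics
used to compare genotypes of the -KTS allelic series, and a synthetic-data
generator that provides ground truth for every step.

## Junction-read classification

Coordinates are 0-based and half-open throughout; a splice gap is the
genomic interval `[first intronic base, first exonic base)`. A
`junction_spec()` fixes the geometry: the canonical (-KTS) donor
`donor_minus`, the +KTS donor at `alt_offset = 9` nt downstream in
transcription direction, and the shared exon-10 `acceptor`. The exact mouse
genome coordinates of the Wt1 donors are configuration, not code: the
package defaults are placeholders with the correct geometry, and real
analyses supply their own spec (as JSON via `read_junction_spec()`).

A read is called `MINUS_KTS` or `PLUS_KTS` when it has exactly one
acceptor-reaching splice gap whose genomic interval equals the respective
isoform's junction gap, with at least `min_anchor = 6` aligned bases on both
sides of the gap and mapping quality at least `min_mapq = 20`. Reads whose
gap reaches the acceptor from an unexpected donor position, or that fail the
anchor/mapq filters on an otherwise matching junction, are `AMBIGUOUS`;
everything else is `NON_JUNCTION`. The four calls partition any input, so
read accounting is exact. Two deliberate choices:

* **Ungapped reads are not +KTS evidence by default.** A contiguous read
  lying across the 9-nt extension is compatible with unspliced pre-mRNA, so
  it cannot prove +KTS origin; `contiguous_plus = TRUE` opts in to counting
  ungapped reads that span the canonical donor boundary.
* **Multi-gap reads are evaluated only on the single gap that reaches the
  acceptor** (if exactly one does). Other gaps are tolerated; they typically
  come from upstream junctions of the same transcript.

On the `-` strand "downstream" means decreasing coordinate; the +KTS donor
sits at `donor_minus - alt_offset` and all interval arithmetic mirrors. The
test suite verifies that mirroring a whole scenario across strands leaves
every call unchanged, and that the CIGAR-walking classifier agrees exactly
with a brute-force oracle that reconstructs each read's genomic footprint
base by base.

## Per-cell ratios and their uncertainty

`count_cells()` tallies calls per cell barcode. When UMIs are present,
reads sharing a `(cell, UMI)` pair collapse to one unit by majority call
(ties become ambiguous) so that PCR duplicates do not inflate the evidence;
deduplication is on by default whenever UMIs exist, and both modes are
supported because read-level and molecule-level ratios are both legitimate
summaries. The per-cell -KTS fraction is `n_minus / (n_minus + n_plus)`
with a 95% binomial confidence interval - Wilson score by default (good
coverage at the 20-100 junction reads per cell this assay produces), exact
Clopper-Pearson as an alternative. Cells with no informative units are
flagged undefined rather than dropped silently. `aggregate_groups()` pools
cells by genotype, sex or stage labels; the pooled fraction
`sum(n_minus) / sum(n_minus + n_plus)` equals the informative-count-weighted
mean of per-cell fractions.

## Image quantification

The image arm reports probe area in um^2 per nucleus from multichannel
fluorescence images. The operator chain is deliberately conventional and
fully parameterised:

* **Nucleus segmentation** (`segment_nuclei()`): Gaussian smoothing
  (`smooth_sigma = 2` px), Otsu or fixed threshold, hole filling, then a
  distance-transform watershed (seed radius `peak_min_distance = 5` px) to
  split touching nuclei, removal of regions under `min_area_px = 50`, and
  contiguous relabelling.
* **Dot detection** (`detect_spots()`): threshold, connected components at
  8-connectivity (4 available), drop components under `min_spot_px = 4`,
  report `area_px * pixel_size^2` in um^2.
* **Assignment** (`assign_spots()`): containment first; otherwise nearest
  nucleus centroid within `max_dist_um = 10` um (BaseScope signal is
  perinuclear, and the cap prevents cross-cell bleed); exact ties break to
  the lowest label. Whether published per-nucleus dot protocols assign by
  nearest centroid, Voronoi territory or cytoplasm expansion varies; the
  containment-plus-capped-nearest rule used here is a documented,
  reproducible choice, and the cap is the parameter to tune when cells are
  dense.
* **Per-nucleus summation** (`per_nucleus_area()`): explicit zero rows for
  empty nuclei, and an exact conservation invariant - per channel, assigned
  plus unassigned area equals total detected area.
* **Marker calls** (`classify_marker_positive()`): per-nucleus mean marker
  intensity against a fixed cutoff or an Otsu threshold over the means; the
  positive fraction (e.g. SRY+ / DAPI+) carries an exact binomial CI.

Areas scale exactly with calibration: doubling `pixel_size` multiplies
every um^2 value by four without touching pixel data.

## The genotype model behind the simulator

`genotype_model()` pairs two alleles. A `WT` allele emits +KTS reads with
probability `wt_plus_fraction` and -KTS otherwise; a `FRASIER` allele has
lost the +KTS donor and emits only -KTS; a `NULL` allele emits nothing.
`wt_plus_fraction` defaults to 0.5: total WT1 protein is observed unchanged
when the +KTS donor is lost while -KTS doubles, which is only consistent
with roughly equal use of the two donors in the wildtype. With
`compensation = TRUE` the total expected output of the non-NULL alleles is
held at the two-WT-allele level, so a `FRASIER/FRASIER` genotype produces
as many junction reads as `WT/WT` - all of them -KTS, i.e. twice the WT/WT
-KTS output. The allelic series (two vs one -KTS-encoding allele) is
simulated with compensation off, where a `FRASIER/NULL` genotype emits half
the -KTS of `FRASIER/FRASIER`.

Per cell, read counts are Poisson at the genotype-adjusted depth - the
standard count-noise model, and the one that makes the downstream binomial
ratio analysis exact conditional on depth. Each read becomes a
junction-spanning alignment with anchors drawn uniformly from
`anchor_range` (default 20-40 nt, typical for short-read junction
evidence). The error model perturbs a read's donor-side gap boundary by
1-3 nt with probability `error_rate`, which downstream classification
reports as ambiguous: this exercises classifier robustness without
simulating base-level errors, which would require a full aligner to be
faithful. The per-cell junction-read depth of the original FACS-sorted
experiment is not published, so depth is always an explicit argument rather
than a hidden default.

The image simulator rasterises elliptical nuclei and circular dots (a pixel
belongs to a shape when its centre does), paints channels additively, and
adds i.i.d. Gaussian noise. Truth tables record both the continuous dot
area `pi r^2 px^2` and the rasterised pixel count actually painted - exact
recovery is only meaningful against the rasterised truth. Dots are placed
perinuclearly by `random_scene()`, and the truth assignment (nearest
nucleus centroid) matches the quantifier's default rule so that noise-free
recovery is exact by construction. A single integer seed makes both
simulators bit-reproducible; all draws come from one sequential stream per
call.

What the generator does *not* emulate, and what passing tests therefore do
not show: real per-cell depth follows expression heterogeneity far beyond
Poisson; alignment artefacts are richer than donor-boundary shifts
(soft-clipping, multimapping); real nuclei are not ellipses, tissue
autofluorescence is structured rather than i.i.d. Gaussian, and BaseScope
dot intensity varies with probe accessibility. The pipelines' correctness
on synthetic truth bounds implementation error, not biological validity.

## Group statistics

`fold_change()` estimates the ratio of mean per-cell -KTS units between two
genotypes - per-cell means rather than pooled totals, so unequal cell
numbers cannot bias the estimate - with a percentile bootstrap CI
(resampling cells within groups) and a two-sided permutation p-value on the
mean difference. Permutation p-values use the add-one correction
`(b + 1) / (n_perm + 1)` and therefore are never zero; an exact mode
enumerates all relabellings for small groups. `dose_trend()` tests
dose-ordered increase across the allelic series with a Jonckheere-type
pairwise concordance statistic (antisymmetric under dose-order reversal),
also by permutation. No multiple-testing correction is applied by default
because the package reports a handful of planned contrasts;
`p.adjust()`-style correction belongs upstream of reporting if many
contrasts are run.

## Numerical and design notes

* Binomial CIs are closed-form (Wilson; Clopper-Pearson via beta quantiles)
  and are cross-checked in the tests against `prop.test()` /
  `binom.test()` and against a direct tail-probability root search.
* Connected components use an explicit pixel-adjacency graph so that
  8-connectivity (the default for dots) is available; 4-connectivity is a
  parameter.
* Otsu thresholds on whole images come from the image-processing backend;
  the Otsu cutoff over per-nucleus marker means is an exhaustive
  between-class-variance search over value midpoints, which is exact for
  the few dozen nuclei a field of view contains.
* Degenerate inputs are defined, not errors: blank images give zero nuclei,
  scenes without nuclei leave dots unassigned, cells without informative
  reads are flagged undefined, an all-NULL genotype simulates zero reads
  with a warning.
* SAM is 1-based; conversion happens only at the SAM read/write boundary,
  and BAM conversion on read coordinate-sorts records (the TSV dialect
  round-trips in order).

## Validation scale

The test suite validates the pipelines at sizes chosen to make Monte-Carlo
bounds tight while keeping a full run fast: 200 cells per genotype at depth
100 for the compensation fold change (the bootstrap CI must contain 2),
10,000 mixed-genotype error-perturbed reads for exact classifier/oracle
agreement, 1,000 cells per -KTS fraction at depth 50 for ratio MAE (within
10% of the binomial expectation `sqrt(f(1-f)/50) * sqrt(2/pi)`) and 92-98%
empirical CI coverage, 100 randomized scenes for exact area conservation,
and 500 null replicates at `n_perm = 999` for permutation-test size within
[0.03, 0.07] at the 5% level. `scripts/acceptance.R` re-derives the same
quantities from scratch against the installed package.

## A compact worked example

```{r example, eval = FALSE}
spec <- junction_spec(donor_minus = 1000, acceptor = 2000)
sim <- simulate_experiment(list(genotype_wt(), genotype_plus_ko()),
                           n_cells = 100, depth = 50, seed = 1,
                           spec = spec)
counts <- count_cells(classify_reads(sim$alignments, spec),
                      labels = sim$truth[, c("cell_id", "genotype")])
aggregate_groups(estimate_ratio(counts), "genotype")
fold_change(counts[counts$genotype == "WT/WT", ],
            counts[counts$genotype == "FRASIER/FRASIER", ], seed = 2)
```

## Known limitations

The classifier requires exact donor/acceptor matches; it does not model
annotation uncertainty in the donor coordinates (a misconfigured spec turns
every real junction read ambiguous - the partition accounting makes this
visible immediately). The image arm is 2D only, treats multi-page TIFFs as
channels rather than z-planes, and its watershed can oversplit lobulated
nuclei; no learned segmentation is provided. Fold changes compare exactly
two groups; factorial designs should go through a count model upstream.
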