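---
title: "Methods: CGI positional profiling, transcript extent and imprinting summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGI positional profiling, transcript extent and imprinting summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgimprint)
```

`cgimprint` implements the computational toolkit used to characterise a CpG
island (CGI) lying *downstream* of the promoter of an imprinted macro
non-coding RNA — the configuration found at the mouse *Airn*/*Igf2r* locus,
where the ~118 kb unspliced *Airn* ncRNA starts upstream of its CGI, is
expressed only from the paternal allele, and silences the overlapped *Igf2r*
promoter in cis. The package covers five analysis stages and, because no
array or sequencing data are deposited for this kind of study, a set of
seeded generators that emulate each input with known ground truth.

## Coordinates

All intervals are 0-based half-open (`end` exclusive), the native BED
convention. Printed locus ranges `chrN:A-B` are interpreted with
length = B − A, because the published length arithmetic obeys that
convention (the 1129 bp CGI deletion at chr17:12934414–12935543 matches
exactly). The parser accepts hyphen and en dash and never silently adjusts
an input; a range with A ≥ B is an error. One published fragment (a "692 bp"
SacII–NsiI range whose printed endpoints differ by 695) does not satisfy any
consistent convention; the package does not special-case it.

```{r}
interval_width(parse_locus("chr17:12934414-12935543"))
```

Minus-strand genes are handled by measuring every offset in transcript
orientation: the oriented 5' edge of a minus-strand anchor is `end - 1`, and
"downstream" always means 3' of the gene.

## TSS metagene profiling around CGIs

Each island is extended by 50% of its own length on both sides, so the
extended window is 2L long and the island body occupies relative
coordinates [0.25, 0.75). A TSS falling in the window is assigned a
relative coordinate in transcript orientation (the window is mirrored for
minus-strand genes; a configuration flag `orient_by_strand` disables this)
and binned into 100 equal bins, `floor(100 r)` clamped to 99 so no TSS on
the window edge is dropped. Summing bins over all islands gives the
metagene profile; the summary fractions use two denominators, matching how
such surveys are reported: *associated* is a percentage of all genes,
*inside/upstream/downstream* are percentages of the associated genes.

Design choices where the procedure is genuinely open:

* **Multiple covering windows.** Islands can sit closer than their own
  length, so extended windows may overlap. The island whose body midpoint
  is nearest to the TSS wins; ties break to the lower start coordinate.
  Any deterministic rule would do; this one is symmetric and cheap.
* **Odd island lengths** split the flanks floor/ceil with the upstream
  (left, genomic orientation) flank taking the floor. This conserves the
  2L window length exactly but makes mirror symmetry exact only for even
  lengths — a 1 bp effect the test suite documents.
* **One designated TSS per gene.** Genes with several closely spaced
  starts contribute the 5'-most start in transcript orientation.
* **Clipped windows** (islands near a chromosome start) keep the ideal
  window geometry for binning and carry a `clipped` flag.

The profiler is validated three ways: against a brute-force classifier that
tests every (gene, island) pair directly; by a conservation invariant
(bin counts plus unassociated genes equal the gene total on every input);
and by parameter recovery — profiles built on `sim_annotation()` output
reproduce the generator's requested class fractions exactly gene-by-gene,
and at n = 5000 the summary fractions sit within binomial 99% confidence
intervals of genome-survey values (57% associated; 88.5/8.7/2.8% of
associated genes inside/upstream/downstream).

## Tiling-array relative intensity and transcript extent

The array model: ~50 bp probes every 100 bp of single-copy sequence, a cDNA
channel and a genomic-DNA channel per probe. Processing follows the
published pipeline:

1. per-probe ratio cDNA/gDNA (probes with zero genomic signal are dropped
   and logged; probes overlapping pseudogene masks are removed);
2. Tukey biweight normalisation — a one-step biweight location
   (c = 5, eps = 1e-4, median/MAD centred, weights `(1-u^2)^2`) computed on
   log-ratios and divided out. Log space is the conventional scale for
   array ratios; the choice is observationally minor because of step 3;
3. rescaling by the arithmetic mean so the region mean is exactly 1 —
   "relative signal intensity";
4. smoothing: overlapping windows of 9 tiles at step one tile; window
   means grouped into consecutive disjoint blocks of 20; each displayed
   point is the mean ± sample SD of its 20 window means, positioned at the
   central probe of its block. With 100 bp spacing one displayed point
   therefore spans 2 kb. A trailing block with fewer than 20 windows is
   flagged `partial`, never silently averaged as full. The grouping phase
   and window step are configuration, since only "overlapping windows of
   9 tiles averaged in 20s" is fixed by the procedure.

The locus is segmented in oriented coordinates (bp downstream of the
ncRNA's major TSS) into a sense-gene-specific part (negative coordinates up
to 0), the sense/antisense overlap ([0, 28 kb) by default) and the
ncRNA-specific part ([28, 118 kb)); all boundaries are arguments.

### Extent calling

`call_extent()` operationalises the visual readout "unchanged to X kb,
reduced after X kb, absent from Y kb" as two run criteria on the displayed
points of a mutant profile versus its wildtype control:

* **reduction** — first point with mutant < (1 − delta) × wildtype for k
  consecutive points (defaults delta = 0.25, k = 3);
* **absence** — first point with mutant ≤ background mean + z × background
  SD for k consecutive points (default z = 2).

Two numerical choices matter and are worth stating plainly.

*Scale calibration.* Each profile is normalised to its own region mean, so
a truncated transcript removes signal from the region and inflates every
remaining mutant point relative to wildtype. Thresholding the raw relative
intensities therefore calls reduction kilobases late and can never reach
"absence" (the mutant's background sits above the wildtype's). When a
`calibration` segment is supplied — naturally the sense-gene-specific part,
where the genotypes are expected to agree — the mutant profile and its
background are rescaled by the wildtype/mutant mean ratio over that segment
before thresholding.

*Background spread.* `estimate_background()` reports the background level
as the mean of the displayed points outside annotated transcription, and
the spread as the *pooled window-mean SD* of those points — the same
quantity the profile plots as error bars, i.e. the band against which a
signal is visually judged absent. The spread of the point means themselves
is several-fold narrower, and a threshold placed a fixed number of those
SDs above background is exceeded by a constant ~2% of background points
*whatever the noise level*, which makes a consecutive-points rule
arbitrarily fragile. The error-bar scale does not have that defect.

### Strand-specific read ratios

`strand_log_ratio()` tiles a region with non-overlapping windows (3.2 kb by
default), counts forward- and reverse-strand reads and reports
`log2((fwd + α)/(rev + α))` with pseudocount α = 1. Windows overlapping
masks (sense-gene exons, pseudogenes), and windows with no reads at all,
carry no ratio. Swapping every read's strand negates every ratio exactly.

## Synthetic data: what the generators emulate

`sim_tiling()` builds the two-colour probe table: constant genomic channel,
cDNA = baseline + sense transcript over its extent + antisense ncRNA over
its extent, all with multiplicative lognormal noise (`noise_sd` is the
log-scale SD; signals are positive and ratio-scaled, so lognormal is the
natural noise model). Default levels (sense 1.0, antisense 1.3,
baseline 0.2, 10% noise) give profiles whose overlap step, specific-region
levels and error bars look like published two-colour tiling data.

A truncation is parameterised by `decline_start` and `truncation`: full
signal before `decline_start`, an immediate fractional drop
(`initial_drop`, default 0.35) followed by a gradual decline (linear by
default, exponential optional) reaching exactly zero at `truncation`. The
initial drop is deliberate: a pure linear ramp to zero over ~22 kb only
reaches a 25% reduction 5.5 kb past the true boundary, so no threshold
detector could attribute the boundary to within one displayed point — yet
the phenotype is described as visibly reduced *at* the boundary against SD
error bars, which implies a promptly visible (≳25%) drop there. The decline
is still gradual, not a plateau step as alternative polyadenylation would
produce. The default array extends 12 kb beyond the transcript end so that
background can be estimated from the same profile.

Under the study geometry (truth: decline 68 kb / absent 90 kb for the
repeat deletion; halved initiation and absent 73 kb for the island
deletion; 10% noise; 20 replicate seeds), the caller recovers each boundary
within one displayed-point spacing (2 kb) in at least 90% of runs — this is
asserted by the test suite and recomputed by `scripts/acceptance.R`. What
passing this does **not** show: robustness to probe dropout,
sequence-dependent probe affinity, spatial artefacts or replicate-level
biological variation, none of which the generator models.

`sim_annotation()` places one island per associated gene with
non-overlapping extended windows (uniform island lengths 200–2000 bp,
10 kb gaps), so the realised class of every gene is unambiguous and equals
the truth record exactly; recovery tests are then pure binomial sampling
checks. `sim_bisulfite()` draws per-CpG calls Bernoulli(p) with injected
no-calls and binomial conversion failures over 50 non-CpG sites (1%
failure rate by default, i.e. most clones pass a 95% conversion
threshold). `sim_allelic_series()` generates Ct values under perfect
doubling with 0.1-cycle Gaussian noise, so zero noise recovers ratios
exactly. `sim_litter()` is a multinomial draw. All generators pin the RNG
(Mersenne-Twister) to their `seed` argument and restore the caller's RNG
state, so outputs are bit-reproducible from (seed, arguments).

## Bisulfite, qPCR and genotype statistics

* **Clone QC** emulates standard bisulfite-analysis settings as two
  thresholds, both configurable and both recorded per clone with the
  failure reason: non-CpG conversion ≥ 95% and ≥ 90% of CpGs called.
  A clone with no non-CpG cytosines has no conversion evidence and fails.
* **Percent methylation** is `100 × #M / (#M + #U)` per clone; unreadable
  positions are excluded from the denominator rather than imputed. Allele
  summaries report mean/min/max of per-clone percentages and a per-CpG
  methylated fraction.
* **Relative quantification** is the comparative-Ct formula
  `100 × E^(-ΔΔCt)` with efficiency E = 2 by default (configurable per
  assay); the calibrator recovers 100 exactly.
* **Allelic ratios** divide the maternal/paternal quantity ratio by the
  ratio of a biallelic reference condition, which is therefore exactly 1.
* **t-tests** use the pooled-variance Student test by default (matching
  the web calculator such analyses conventionally cite), Welch by flag;
  two all-constant groups return t = 0, p = 1 with a warning rather than
  an error. Stars follow the 0.05/0.01/0.001 convention — the only
  defensible reading of a figure legend whose printed star thresholds are
  internally inconsistent.
* **Genotype ratios** use the Pearson chi-square goodness of fit
  (`stats::chisq.test`) against Mendelian weights; the suite cross-checks
  it against a literal Σ(O−E)²/E.

```{r}
genotype_ratio_test(c(19, 34, 12), expected_weights = c(1, 2, 1))[c("chi2", "df", "p")]
```

## Problem sizes used by the checks

The test suite and the acceptance script use n = 5000 genes for fraction
recovery, 20 seeds × ~1900 probes for extent recovery, 24 clones × 20 CpGs
per methylation regime and 3 replicates per qPCR condition — the sizes at
which the corresponding published quantities were reported, or (for the
synthetic-only checks) sizes at which the binomial confidence intervals are
a few percentage points wide.

## Known limitations

* The BED reader is deliberately minimal (BED3/BED6); full-feature GFF3
  parsing, liftover and sequence handling are out of scope.
* Extent calling assumes mutant and wildtype were processed on the same
  probe grid; no resampling is attempted across grids.
* The generators model marginal distributions, not probe-level affinity,
  spatial correlation or biological replicate structure; recovery results
  quantify estimator behaviour under the stated noise model only.
* Allele assignment of bisulfite clones is metadata-driven (amplicon and
  genotype), mirroring allele-specific primers; no sequence alignment is
  performed.
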