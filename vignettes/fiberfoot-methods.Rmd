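---
title: "fiberfoot: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fiberfoot: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

Antibody-directed methylation experiments tether an adenine
methyltransferase (Hia5) to a chromatin factor via an antibody. Upon
activation, the enzyme deposits N6-methyladenine (6mA) — a mark essentially
absent from vertebrate DNA — on accessible adenines near the bound factor.
Long-read sequencing with modified-base calling then reads both the
exogenous 6mA and endogenous CpG methylation from the same molecules, so
every read is a single-fiber footprint of protein occupancy, nucleosome
organization, and CpG state.

`fiberfoot` implements the downstream computation: decoding MM/ML
modified-base tags from aligned reads, motif-centered aggregate profiles
with non-targeting (IgG) control subtraction, exponential-decay fits to the
nucleosome-phased methylation peaks flanking bound sites, single-read
panels, haplotype-resolved allele contrasts, motif scanning with region
classification, and 3D immunofluorescence quantification. A generative
single-fiber simulator with known ground truth drives validation.

## Score scale

Modified-base callers store per-call confidence as an 8-bit integer `s` in
the ML tag, denoting the probability bin `[s/256, (s+1)/256)`. `fiberfoot`
reports the bin midpoint `(s + 0.5)/256`; under this convention the two
conventional thresholds, 225 for aggregate analyses and 250 for single-read
panels, correspond to 0.88 and 0.98 at two decimals. Binarization is a
single cutoff (methylated iff `score >= threshold`); sub-threshold calls
stay in denominators, which keeps pileup depth independent of the
threshold.

## The generative model

`fiber_sim_config()` fixes the simulator's study conditions. Defaults: a
600 kb random-base contig carrying 50 non-degenerate CTCF-like consensus
instances (`CCACCAGGGGGCGCTA`) every 10 kb on alternating strands,
sequenced at 25-fold coverage with ~15 kb fragments — a desk-scale analogue
of a deeply sequenced run over a strongly bound peak set.

Per fiber and site, occupancy is Bernoulli(`p_bound` = 0.85; strongly bound
ChIP-defined sites are occupied on most fibers). Around each bound site:

* a **footprint** of half-width 60 bp with zero accessibility (the bound
  factor excludes the enzyme);
* **phased nucleosomes**: 147 bp cores butted against the footprint edge and
  repeating every `NRL` = 190 bp, each flank independently. The k-th core is
  displaced by `Normal(0, (jitter_sd * sqrt(k))^2)` with `jitter_sd` = 10 bp:
  positioning errors accumulate linker by linker, so positional variance
  grows linearly with index — the standard statistical-positioning model,
  and the reason phasing oscillations fade with distance while remaining
  visible out to ~1 kb;
* elsewhere, and on unbound fibers, cores tile the fiber with a uniform
  random phase (no alignment across fibers, so they average out).

Accessible adenines are methylated through two channels that apply in
*every* condition:

* **tethered deposition** with probability `A_teth * exp(-lam_teth * d)`
  (`A_teth` = 0.6, `lam_teth` = 1/200 bp^-1, `d` = distance to the nearest
  bound site), and
* **free-enzyme background** at `bg_rate` = 0.03 per accessible adenine,
  boosted 3-fold within 200 bp of any site (open chromatin at bound motifs
  is intrinsically more accessible to free enzyme).

The two combine as independent hits,
`p = access * (1 - (1 - p_teth)(1 - p_bg))`. Background is present in the
targeting condition too — it arises from free enzyme, which antibody
targeting does not remove — and the `igg` condition simply has no bound
fibers. This is what makes control subtraction meaningful: the
site-proximal accessibility bump appears in both conditions and cancels,
while the tethered oscillation survives.

Endogenous CpG methylation is a property of the allele, not of the
antibody: CpGs within 300 bp of a binding-competent site are methylated
with probability 0.1 (binding-competent loci are CpG-hypomethylated), CpGs
near non-competent sites with probability 0.9, and all others with 0.7
(bulk genome). In diploid mode two identical contigs named
`<contig>_MATERNAL` / `<contig>_PATERNAL` carry allele-specific occupancy
(0.8 maternal, 0 paternal) — the logic of an imprinting control region,
where the hypomethylated maternal allele is bound and the methylated
paternal allele is not. The `igg` condition leaves CpG states untouched.

Integer call scores are drawn from discretized `255 * Beta(9, 1)` for truly
methylated bases and `255 * Beta(1, 9)` otherwise. This places the ROC knee
inside the conventional 0.75–0.98 confidence band: the true-positive rate
varies substantially across that band (so threshold choice matters for
absolute signal), while the false-positive rate is negligible throughout
(so target/control *ratios* are threshold-insensitive) — the behavior the
enrichment analysis is designed to exhibit.

What the simulator does **not** emulate: base-calling errors in the
sequence itself (reads are emitted as perfect-match alignments), mapping
ambiguity, fragment-length heavy tails, co-methylation correlations beyond
the shared nucleosome geometry, partially occluded (breathing) nucleosomes,
or inter-site cooperativity. Passing recovery tests therefore demonstrates
that the estimators are correct under the stated model, not that they are
robust to alignment artifacts or repeat-mediated mapping errors in real
data.

## Aggregate profiles

`aggregate_at_sites()` pools base-level counts across sites at offsets
`-W..+W` from the site center (`floor((start + end)/2)`; for even-length
motifs the 1 bp asymmetry is far below the smoothing scale). Minus-strand
sites have their offset axis reversed before pooling, so profiles are in
motif orientation. Pooling is depth-weighted (count-based), which keeps
integer accounting exact and makes the profile reproducible from any
partition of the site set.

Smoothing is an equal-weight centered moving average on the fraction scale
with truncated edges; the two display conventions are a 50 bp window
(interphase panels) and 30 bp (mitotic panels). Control subtraction is a
plain position-wise difference of fractions after smoothing, without
renormalization; negative values are retained as information about control
excess. `enrichment_ratio()` compares unsmoothed mean fractions over a
central window, by default 300 bp: that window spans the footprint, the
first nucleosome core and the first flanking linker, where tethered signal
concentrates. (A window inside ~200 bp would fall entirely within the
footprint-plus-first-core region, which is occluded on bound fibers and
therefore carries almost no tethered signal under this geometry.)

## Decay fitting

Peak heights flanking a bound site decay with distance because the tether
concentration decays. `find_flank_peaks()` takes strict local maxima of the
smoothed profile, greedily accepted in descending height with a minimum
mutual separation of 120 bp, and pools both flanks as `d = |offset|`.
`fit_decay()` then solves `height = a * exp(-lam * d) + c` by bounded
Levenberg–Marquardt (all parameters >= 0), starting from
`a = range(heights)`, `c = min(heights)`, `lam = log(2)/500`, with restarts
over a grid of `lam` starts; standard errors come from the local curvature.
Constant heights return the degenerate branch `a = 0, c = mean(height)`
(flagged, not an error). `--no-baseline` gives the strict two-parameter
form.

Two defaults in the fitting wrapper differ from the peak-detection API
defaults, both for estimator quality:

* **exclusion half-width 200 bp** (not just the 60 bp footprint): with
  jittered first nucleosomes, a fraction of fibers opens a sliver of
  accessible DNA right at the footprint boundary. The resulting bump at
  |offset| ~60–90 bp is core-edge leakage, not a linker peak, and including
  it badly corrupts the fit.
* **fitting range 1400 bp** (not the 1000 bp display range): the outer
  phased peaks carry little tether signal but pin the baseline `c`, which
  decorrelates `a` from `lam` and stabilizes the decay constant.

The baseline term `c` is included by default because aggregate profiles sit
on a nonzero free-enzyme background; omitting it forces the tail into the
exponential and biases `lam`. Both flanks are pooled into one fit because a
single `(a, lam)` pair per condition is the quantity of interest.
`compare_fits()` reports amplitude and decay-constant ratios between
conditions with first-order error propagation; a larger `lam` is a
spatially tighter distribution.

The fitted `a` estimates the *observed* peak methylated fraction
extrapolated to distance zero. Its generative value is
`p_bound * A_teth * TPR(threshold)` — occupancy and base-caller sensitivity
scale every observed peak — and `expected_decay_params()` computes exactly
this quantity for parameter-recovery comparisons. Smoothing and residual
nucleosome jitter bias the amplitude estimate somewhat downward and the
decay constant slightly upward; the validation suite quantifies both on
seeded simulations.

## Single-read panels

`reads_at_sites()` emits one row per (read x site window) pair — a long
read legitimately appears at several sites, as in genome-browser panels —
with cells methylated/unmethylated at called positions and absent
elsewhere. The per-row methylated fraction is computed within the displayed
window (matching what a panel shows; a whole-read variant is available).
`order_matrix()` groups rows by read strand and sorts by descending
fraction, breaking ties by read identifier so the ordering is deterministic
and permutation-invariant. Column sums of the matrix reproduce the
unsmoothed aggregate profile exactly at the same threshold — a cross-module
identity the tests enforce.

## Haplotypes

Reads are assigned to alleles purely by contig suffix
(`_MATERNAL`/`_PATERNAL`), matching alignment to a haplotype-resolved
diploid assembly; no SNP-based phasing is attempted. The
`imprinting_contrast()` regions are user-supplied homologous windows (the
two alleles' coordinates differ in real assemblies; no liftover is
attempted). Deltas are reported with two-proportion z statistics over
pooled call counts. In the simulator's validation runs the window spans the
whole planted site cluster — the analogue of an imprinting control region,
which contains several CTCF sites — because 6mA signal is concentrated in
flanking linkers and CpG contrast in near-site zones; a window restricted
to a single site at reduced coverage is underpowered.

## Motifs and region classes

`scan_motif()` performs exact IUPAC-consensus matching on both strands
(via `Biostrings`), reporting minus-strand matches in forward coordinates.
A log-odds PWM scanner is deliberately out of scope: no position weight
matrix is shipped, and an exact consensus is reproducible and sufficient
for synthetic validation; users with a PWM should scan externally and
supply BED. `classify_by_region()` labels each site by the annotation
containing its *center* (consistent with the center-anchored profile
convention), resolving nested annotations by smallest interval, then file
order. `class_profiles()` simply partitions the sites and delegates;
classes under 5 sites are flagged low-confidence.

## 3D immunofluorescence quantification

Per ROI (one mitotic cell), the DAPI channel is median-filtered with a
7 x 7 x 3 voxel kernel (reflection padding; the smaller extent is axial),
thresholded, and labeled by 26-connected components with a minimum-size
filter. The threshold defaults to Otsu's method on the filtered ROI with a
manual override. The cytoplasm estimate is a dilation shell: the mask
dilated by a radius-2 ball, minus the mask. All morphology is implemented
natively in 3D (the installed image package operates slice-wise in 2D).

One measurement choice matters: boundary voxels eroded from the mask by the
median filter are chromatin, and they land exactly in the first shell
layer. `quantify_cell()` therefore excludes shell voxels whose raw DAPI
exceeds the segmentation threshold from the cytoplasm mean — chromatin must
not be counted as cytoplasm. On binary phantoms this exclusion is the
difference between recovering the generative ratio and underestimating it
by roughly the shell's chromatin fraction. Group comparison uses Welch's
(unequal-variance) two-sided t-test of per-cell ratios against the
reference group, with no multiple-testing correction (per-line reporting).

The phantom generator (`simulate_cells()`) draws random ellipsoid
chromosome masses with bright DAPI, a target channel at
`true_ratio x cytoplasm_level` inside and `cytoplasm_level` outside, and
Gaussian noise on both channels. Phantoms validate the measurement
arithmetic and segmentation plumbing; they do not emulate point-spread
blur, anisotropic voxels, or autofluorescence gradients, so recovery there
does not certify robustness to those effects.

## Validation problem sizes

The validation suite and `scripts/acceptance.R` run at sizes chosen to give
stable statistics on a single CPU: parameter recovery on the default 50
sites at 25x; condition contrast on 100 sites per condition at 25x
(two fits enter each ratio, so the contrast run uses twice the sites);
imprinting on a 200 kb diploid locus with 16 sites at 25x; phantom cohorts
of 10 cells per group at 40 x 40 x 16 voxels. Oracle checks (brute-force
pileup, nested-loop 3D median, all-pairs interval containment) use small
fixtures where exhaustive computation is trivially correct.

## Known limitations

* SAM text is the native interchange format; BAM input should be converted
  with `samtools view -h` first.
* Only the `A+a` and `C+m` modification channels are supported; others are
  skipped with a warning. The implicit-skip (`.`) MM flavor is treated as
  explicit listing.
* The decay model is an envelope fit to peak heights, not a fit of the full
  damped oscillatory waveform; per-site (single-locus) fits are out of
  scope.
* Interval classification is center-based; a site straddling an annotation
  boundary is assigned wholly by its center.
* The IF arm consumes manually identified ROIs (one cell each); automatic
  mitotic-cell detection is out of scope.
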