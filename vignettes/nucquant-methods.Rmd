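---
title: "Quantification methods: nuclear morphometry, translocation and foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: nuclear morphometry, translocation and foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`nucquant` implements the quantification chain used in chronic-toxicity
imaging studies of cultured epithelial cells: chronic stress (e.g. low-dose
arsenite around 1 µM, i.e. ~75 µg/L or ppb for elemental arsenic) induces
*giant cells* (GCs, enlarged nuclei) and *multinucleated cells* (MNCs),
nuclear translocation of NF-κB p65, and accumulation of γH2AX foci marking
DNA double-strand breaks. The package provides, as testable code:

1. a synthetic-microscopy generator producing ground-truthed DAPI / MARKER /
   CELLBODY scenes;
2. nucleus and cell segmentation;
3. per-nucleus morphometry and the vehicle-referenced GC/MNC classifier;
4. the nuclear:cytosolic translocation ratio and a LoG foci counter;
5. tabular statistics: viability %, 2^−ΔΔCt, an in-house Benjamini–Hochberg
   step-up, the CPM/FDR/fold-change DEG filter, cytokine normalization and
   the µM → µg/L dose conversion.

Because such studies deposit no raw images, every imaging stage is
benchmarked against the generator's planted truth rather than against
archived data; the `analysis/` scripts and `scripts/acceptance.R` re-run
those benchmarks end to end.

# The giant/multinucleated-cell classifier

The vehicle (control) arm anchors the classifier. From all uncensored
vehicle nuclei we take the sample mean and SD (n−1 denominator) of nuclear
area and perimeter; the giant thresholds are

$$T_A = \bar A + 3\,s_A, \qquad T_P = \bar P + 3\,s_P.$$

A cell is **giant** when its *total* nuclear area exceeds $T_A$ **or** its
total nuclear perimeter exceeds $T_P$ (strict inequalities; ties, possible
only when the SD degenerates to zero, are not giant). A cell is
**multinucleated** when it contains more than one nucleus, and for cells
that are both, totals are the sums over all member nuclei (the summation
rule). The "at least three SDs of the mean" phrasing admits a literal
reading (value > 3·SD alone), which is dimensionally implausible — it would
flag nearly every nucleus — so `mean + 3·SD` is the default and the literal
rule remains available as `gc_rule = "3sd_abs"`.

Percentages are reported over all classified cells pooled across scenes,
with per-scene percentages alongside so an SEM across independent fields
can be formed, mirroring how imaging experiments report 4–6 independent
replicates. When no cell-body channel exists, each nucleus is its own cell
and multinucleation is reported as *unavailable* (`NA`), never as zero:
multinucleation cannot be inferred from DAPI alone.

# The synthetic generator: what it emulates, and what it does not

Each scene renders three channels at a default 0.25 µm/pixel (a typical
60× confocal sampling):

* **DAPI** — nuclei as filled ellipses at 120 counts over a 5-count
  background. Vehicle nuclear areas are log-normal (mean 100 µm², CV 0.1) —
  strictly positive and right-skewed like real nuclei; the study itself
  reports no vehicle size summary, so these defaults are this package's
  choice, not literature values. Aspect ratios are uniform in [0.85, 1].
* **MARKER** — cytosol at 40 counts, nuclei at `marker_ratio × 40`, so the
  planted nuclear:cytosolic mean ratio is exact with noise off. Foci are
  isotropic Gaussians (σ = 2 px) with peak amplitude 5× the cytosolic
  level, Poisson counts per nucleus, planted pairwise-separated
  (≥ max(4σ, 8) px) and away from the nuclear rim.
* **CELLBODY** — a GFP-like disk covering all of a cell's nuclei.

Camera noise is Poisson shot noise followed by additive Gaussian read noise
(SD 2 counts), applied last and independently per z-plane; z-stacks are
repeated planes with fresh noise. Not emulated: optics beyond Gaussian
spots (no PSF model), engulfment/time-lapse dynamics, intensity gradients,
autofluorescence, or touching/overlapping cell bodies. Passing benchmarks
therefore demonstrate correctness of the measurement chain on images whose
statistical structure matches the design assumptions — not robustness to
every artifact of real microscopy.

## Composition and the giant/multinucleated geometry

Per scene, exactly `round(fraction × n_cells)` cells are flagged giant and
multinucleated, with membership sampled uniformly and the two subsets drawn
independently (a cell can be both). Exact counts rather than per-cell
Bernoulli draws keep the recovery benchmark an assessment of pipeline
error instead of binomial sampling noise; the empirical flag fraction still
sits inside any binomial interval around the nominal rate.

Giant cells scale each nuclear semi-axis by `giant_scale` (default 2, i.e.
~4× area — well clear of the 3σ thresholds at the default CV). A
multinucleated cell with $k$ nuclei that is *not* giant draws each nucleus
from the vehicle distribution scaled by $1/k$ in linear dimension. This is
deliberate: splitting a vehicle-sized *area* across $k$ equal nuclei
inflates the perimeter sum by $\sqrt{k}$, which would push essentially
every multinucleated cell over the perimeter threshold and make the planted
giant fraction unrecoverable in principle. The $1/k$ linear scaling keeps
the perimeter sum vehicle-typical and the area sum below it, so the two
planted phenotypes stay independently recoverable; biologically it
corresponds to nuclear content divided among daughter nuclei. Cells that
are both giant and multinucleated scale by `giant_scale`/k and exceed both
thresholds.

Cells are placed by rejection sampling with a minimum center distance (an
over-dense configuration fails with an explicit error); nuclei of one cell
are placed inside its body, pairwise separated.

# Segmentation

Nuclei: Gaussian smoothing (σ = 2 px) → Otsu threshold (or fixed) → hole
filling → distance-transform watershed → area filter (≥ 50 px²) → border
exclusion → label compaction. The watershed uses a *depth tolerance*
(default 1 px in distance units): basins merge when the peak rises less
than the tolerance above the connecting saddle. This splits genuinely
touching nuclei (whose neck is shallow relative to both peaks) without
fragmenting one large nucleus along the discretization wiggles of its
medial ridge — a failure mode of fixed-window peak seeding on elongated
giant nuclei. Border-touching nuclei are censored because truncated
geometry would bias the vehicle reference. Foreground labeling is
4-connected.

Cells: the cell-body channel is thresholded the same way; every connected
foreground component containing at least one nucleus becomes one cell, so
the nuclei of a multinucleated cell — which share one unbroken component —
are never split between cells. A nucleus outside all foreground becomes its
own flagged one-nucleus cell (its 5-px dilation). Each nucleus is assigned
to the cell holding the majority of its pixels, and nucleus pixels are
forced into their cell so nuclear and cytosolic regions nest.

Areas are pixel counts (× pixel-size² for µm²); perimeters use the
4-direction Crofton estimator, near-exact on digitized disks and ~8% low on
squares whose corners the 4 directions round. Since the classifier is
vehicle-referenced, only internal consistency of the estimator matters.

# Intensity read-outs

The cytosolic signal intensity is
$(ID_{\text{cell}} - ID_{\text{nucleus}})/(A_{\text{cell}} - A_{\text{nucleus}})$
— the mean marker intensity of the cytosol ring. "Cytosol" is read as the
whole-cell region: subtracting the nuclear integrated density would be
redundant if the region already excluded the nucleus. A strict-cytosol mode
(ring integrated density over ring area) is provided; for nested masks the
two are algebraically identical, which the tests verify. The translocation
ratio divides the nuclear mean by this cytosolic mean, is invariant to
rescaling the image, and is undefined (flagged, excluded from group means)
when the cytosolic mean is not positive. The positive-cell proportion uses
a strict, caller-supplied cutoff — no default pretends to a published one.

Foci: scale-normalized, zero-mean, negated LoG filter at σ = 2 px; 3×3
local maxima inside each nucleus; threshold `median + 5·MAD` of the
in-nucleus response (offset-invariant, so no background subtraction is
needed); maxima closer than 3 px merge into the stronger. Counting operates
on the maximum projection by default, the conservative choice for focus
visibility when the reduction used upstream of 2-D measurements is not
otherwise specified; `sum` or single-plane alternatives are a projection
call away.

# Tabular statistics

* **2^−ΔΔCt** — per sample ΔCt = Ct(gene) − Ct(reference); ΔΔCt is the
  difference of group mean ΔCt; replicate spread is summarized by
  per-replicate folds against the vehicle mean ΔCt (the propagation scheme
  is a package choice; none is standard).
* **BH step-up** — written in-house and cross-checked in the tests against
  both an exhaustive step-up oracle and `stats::p.adjust`.
* **DEG filter** — strict inequalities as printed (CPM > 1 in ≥ 2 samples,
  adjusted p < 0.05, |log2FC| > 0.5); BH is applied after the expression
  filter (standard edgeR practice), with `bh_scope = "all"` available.
* **Cytokine normalization** — pg/mL × mL / cells × 10⁶, i.e. pg per 10⁶
  cells (the output unit is fixed here; "normalized to cell counts" admits
  several).
* **Dose conversion** — 1 µmol/L × M g/mol = M µg/L; the default molar
  mass is elemental As (74.92 g/mol), under which 1 µM ≈ 75 ppb; the
  NaAsO₂ formula mass (129.91) is selectable but breaks that equivalence.
* **Group comparisons** — delegated to `stats::t.test` (pooled and Welch)
  and `aov`/`TukeyHSD`.

# Numerical choices and degenerate inputs

* Strict inequalities at every classifier and filter boundary.
* Zero-variance vehicle reference: warned, thresholds collapse to the mean,
  ties are not giant. Fewer than 2 uncensored vehicle nuclei: error.
* All-zero or constant images segment to an empty label map, not an error.
* An empty value list for the positive fraction, a zero live+dead total, a
  missing reference-gene Ct, and non-nested masks are errors.
* TIFF stacks are stored as 32-bit float scaled into [0, 1] with a JSON
  sidecar carrying channel names, z-count, pixel size and scale; round-trip
  is exact to float32 precision (~1e-7 relative).
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; population seeds derive deterministically from a
  master seed, so regeneration is order-independent and bit-identical.

# Benchmark problem sizes

The standard benchmarks (also what `scripts/acceptance.R` reruns) use:
15 scenes × 35 cells per arm (525 cells/arm) at 900×900 px for GC/MNC
recovery; 60 cells per planted ratio (1, 2, 4) for translocation; 160
nuclei with Poisson(5) foci plus 160 blank nuclei; 200 repetitions × 4
planted folds for ΔΔCt; and a 1000-gene table with 50 planted DEGs. These
sizes give sub-point sampling error on the recovered percentages while
keeping a full run to a couple of minutes on one core.

# Known limitations

* The classifier is only as good as the vehicle arm: a contaminated or
  tiny control sample shifts the 3σ thresholds directly.
* Multinucleation requires a cell-body channel; without one it is reported
  unavailable rather than guessed from nuclear proximity.
* The generator's disjoint circular cell bodies make cell segmentation
  easier than in confluent cultures; the cell-merging rule ("one unbroken
  component = one cell") would over-merge truly touching cells.
* The foci detector is tuned for sparse, diffraction-limited spots;
  clustered foci closer than the merge radius count as one.
* No ploidy/DNA-content estimation, colocalization, 3-D segmentation or
  learned models.
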