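---
title: "Methods: apoptotic-score screening, robust Z hit calling and downstream analyses"
author: "apoScreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apoptotic-score screening and robust Z hit calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoScreen)
```

## The screen and its readout

A high-content microRNA inhibitor screen transfects a library of 954
antisense inhibitors into three breast cancer cell lines -- parental,
drug-responsive MCF7 and two endocrine-resistant derivatives, TamR
(tamoxifen-resistant) and LTED (long-term estrogen-deprived) -- in
biological triplicate, and images each well in two fluorescence channels:
a Hoechst nuclear stain and a caspase-3/7 activity reporter. The primary
measurement is the **apoptotic score**: the fraction (0--1) of nuclei in a
field whose *nuclear* caspase signal is positive, averaged over the fields
of a well. Counting and measuring in the nucleus only is what makes the
score a per-cell death fraction rather than a bulk-intensity readout.

`apoScreen` implements that measurement and everything downstream of it:
hit calling on the score tables, direct-target nomination from expression
data, highest-single-agent synergy scoring of drug combinations, and the
small bench-assay formulas used alongside.

## Image quantification

`segmentNuclei()` uses a deliberately transparent stack -- Gaussian
smoothing (`smoothSigma = 2` px), a global Otsu threshold on the Hoechst
channel, hole filling, connected-component labelling, an area filter
(`minArea = 10`, `maxArea = 5000` px) and an optional distance-transform
watershed for touching nuclei. The imaging instrument's proprietary
segmentation is not public, so the package favours a fully parameterised,
inspectable pipeline over fidelity to an unknown algorithm. The caspase
channel is measured only inside each nucleus mask, giving per-nucleus mean
intensities.

`callApoptotic()` defaults to a **fixed intensity threshold** (16-bit
scale, default 10000) rather than a per-field adaptive cut: a fixed
threshold keeps wells comparable across a plate and can be calibrated on
the control wells every plate carries. An Otsu-on-nuclei alternative is
provided for exploratory use; with fewer than two nuclei it falls back to
the fixed threshold with a warning.

Wells aggregate by the **unweighted mean of field scores** (fields are the
replication unit of the readout), with a `poolCells` option that weights
by cell count instead. Fields with no cells are dropped from the mean; a
well whose every field is empty is flagged missing rather than scored.
Whether low-cell-count wells should be excluded outright is left to the
caller -- the package reports `total_cells` so any cut can be applied
downstream.

Pixel coordinates are 1-based `(row, col)` throughout, the native R
matrix convention.

## The screen statistic

For each inhibitor $i$, with $\bar{X}_{\mathrm{res}}$ the mean apoptotic
score across the two resistant lines and $X_{\mathrm{MCF7}}$ the parental
score (each a replicate mean),

$$\mathrm{LFC}_i = \log_2\!\left(\frac{\bar{X}_{\mathrm{res}} + c}
  {X_{\mathrm{MCF7}} + c}\right),$$

with pseudocount $c = 0.001$ guarding near-zero parental scores
($c = 0$ restores the literal ratio). Over the library's LFC vector,

$$\mathrm{RZ}_i = \frac{0.6745\,(x_i - \tilde{x})}{\mathrm{MAD}},
  \qquad \mathrm{MAD} = \mathrm{median}\,|x_i - \tilde{x}|,$$

where $\tilde{x}$ is the library median. The constant
$0.6745 = \Phi^{-1}(0.75)$ makes the MAD a consistent estimator of the
normal $\sigma$, so RZ-scores are comparable to classical Z-scores while
being insensitive to the hit outliers themselves. An inhibitor is
**significant** when $|\mathrm{RZ}| \ge 2.5$, a one-sided normal tail
probability of $1 - \Phi(2.5) = 0.00621$.

Two properties justify the defaults. First, the RZ-score is invariant
under any positive affine transform of the LFC vector, hence under the
choice of log base -- only the reported LFC column changes, so base 2 is a
presentation choice, not an analysis choice. Second, for normal data the
robust and classical Z-scores converge (the package's tests check maximum
absolute disagreement at $n = 10{,}000$ draws), which is exactly what the
0.6745 constant encodes.

A degenerate LFC spread (MAD = 0, e.g. in a noise-free simulation) leaves
every RZ undefined; `callHits()` reports such inhibitors with
`significant = FALSE` and `NA` scores rather than dropping them.

Independently of significance, each inhibitor receives a **phenotype
category** from its per-line mean scores, evaluated in priority order:

* `pan` -- score $\ge 0.50$ in all three lines;
* `resistant_only` -- $\ge 0.20$ in both resistant lines while the
  parental score is below 0.20;
* `responsive_only` -- $\ge 0.10$ in the parental line while both
  resistant scores are below 0.10;
* `none` otherwise.

The "only" in the category names is interpreted as the other line(s)
falling below *that criterion's own threshold*; the priority order
prevents double assignment. Significance and category are reported as
independent flags because they answer different questions -- whether an
inhibitor's resistant-vs-parental contrast is an outlier, and in which
lines it kills -- and neither implies the other.

Replicates collapse by arithmetic mean before the LFC (median available
via `collapse = "median"`).

```{r hits}
tbl <- genScreenTable(screenScenario(noiseSd = 0.02), seed = 1)
hits <- callHits(tbl$scores)
table(hits$category)
head(hits, 3)
```

## Synthetic data: what it emulates and what it does not

The generators reproduce the screen's *design*: 954 inhibitors, three
lines, triplicates, control wells (mock, negative control, cell-death
control), five-field imaging, planted hits in the three categories with
counts 4/9/13 -- and they record ground truth for every quantity the
pipeline later estimates. Defaults chosen once as study conditions:
baseline apoptotic scores 0.05 (MCF7) and 0.07 (TamR, LTED) -- resistant
derivatives show modestly higher basal death, which centres the bulk LFC
slightly above zero as observed in real screens -- replicate noise SD
0.02, and planted effect scores (0.15 / 0.30 / 0.60) sitting safely above
their respective criteria. Microscopy fields render nuclei as
Gaussian-profiled discs (radius 5 px with 10% jitter) over additive
Gaussian read noise, placed by rejection sampling with a minimum
separation of `2 * radius + 4` px.

What the generators deliberately do **not** model: optics (PSF, uneven
illumination), plate spatial artefacts (edge effects), cell morphology
beyond nuclei, and per-well seeding variability at imaging time (exposed
as a parameter, with no claim of fidelity). Passing recovery tests on
these images therefore demonstrates the *correctness of the measurement
chain* -- segmentation, nuclear-restricted intensity measurement, score
arithmetic, aggregation -- not robustness to the artefacts of real
microscopy, which would need illumination correction and more aggressive
de-clumping than the defaults perform.

Every generator is a pure function of (parameters, seed): the caller's
RNG state is saved and restored, and per-generator streams derive
deterministically from the one seed.

## Direct-target intersection

A gene is nominated a candidate direct target when it is differentially
expressed at `p < 0.05` (strict inequality) *and* appears in the union of
the target databases (predicted: miRDB, TargetScan; validated:
AGO-PAR-CLIP, miRTarBase -- the label set is open). Matching is by exact
case-insensitive symbol; alias resolution would require an external
dictionary and is a documented non-feature. The raw p-value column is the
default because the in-vivo intersection is a nomination step, not a
final inference; the FDR column can be selected instead. Direction of
change is reported but never filtered on -- genuine direct targets can
move in either direction in vivo (de-repression of the direct target,
secondary loss elsewhere).

## HSA synergy

Viability readings normalise to inhibition fractions
$e = \mathrm{clamp}(1 - \mathrm{raw}/\mathrm{control},\,0,\,1)$ with the
untreated cell as anchor. The highest-single-agent reference expects the
combination at dose pair $(i, j)$ to do no better than its best
constituent, $\max(e_{i,0}, e_{0,j})$; the **surplus** is the observed
effect minus that reference. It is the most conservative of the classical
references (Loewe and Bliss are out of scope here), linear in the
combination cells at fixed single-agent anchors -- so replicate matrices
may be averaged before or after scoring -- and exactly zero on
single-agent rows and columns. The dose-0 row and column are required in
the input: they are what defines the reference unambiguously. No
significance surface is fitted; the package reports raw surplus with
replicate means and standard errors.

## Assay formulas

* **ddCt**: per sample, $\Delta Ct$ = target Ct minus the arithmetic mean
  of the reference-gene Cts (the geometric-mean normaliser on the linear
  scale -- standard multi-reference practice); fold change
  $= 2^{-\Delta\Delta Ct}$. No efficiency correction is applied.
* **Tumour volume**: $w^2 \times \ell / 2$ (modified ellipsoid), the
  dimensionally consistent form, with the width-shorter-than-length
  convention enforced by swapping with a warning.
* **IHC score**: the three-point rubric plus two rubric-completion cells
  -- weak staining above 20% and strong staining at or below 10% both
  score 2 -- chosen as the nearest-neighbour extension that preserves
  monotonicity in staining intensity; completed cells are flagged
  `extrapolated`.
* **Relative growth**: day-$t$ absorbance over day-0 absorbance.

## Numerical choices and problem sizes

Degenerate inputs resolve explicitly, never silently: empty fields score
`NA` with zero cells, all-empty wells are flagged missing, MAD-0 libraries
carry `NA` Z-scores, zero parental scores with pseudocount 0 raise an
error naming the inhibitor, and infeasible nucleus placement fails after
bounded retries. Classification boundaries are inclusive (a parental score
of exactly 0.10 meets the responsive criterion), the DEG threshold is
strict, and caspase positivity is inclusive (`>=` the threshold).

The test suite and the reproduction script exercise the full 954-inhibitor
screen (noiseless plus 20 noisy instances), 50 generated fields of 50--300
nuclei at 512 x 512 px, a 5000-gene DEG table against a 1075-gene target
union, and 1000 random vectors against the brute-force median/MAD oracle;
these sizes keep a complete run within a couple of minutes on one CPU
while matching the screen's real dimensions where it matters (library
size, target-union size, significant-DEG count).

## Known limitations

Segmentation quality on real (non-synthetic) images will depend on
illumination correction and de-clumping not implemented here; plate-
position normalisation (B-score, median polish) is intentionally absent
because the screen statistic operates on the pooled library distribution;
and the category criteria are applied to mean scores without propagating
replicate uncertainty -- the robust Z carries the inferential weight.
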