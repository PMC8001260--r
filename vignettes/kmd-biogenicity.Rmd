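---
title: "Classifying the biogenicity of complex organic mixtures from Kendrick histogram images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the biogenicity of complex organic mixtures from Kendrick histogram images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmdclass)
```

## The problem

Deciding whether a complex organic mixture derives from biology is hard
precisely where it matters most: aged, degraded or extraterrestrial samples
in which no individual diagnostic compound can be identified with
confidence. FT-ICR mass spectrometry resolves thousands of peaks in such
mixtures, but a single m/z match "could" be any of an astronomical number
of isomers. The approach implemented here is deliberately agnostic about
compound identity: it classifies samples from the relational structure of
the whole peak list — how peak counts distribute jointly over mass,
relative abundance and Kendrick mass defect (KMD).

The intuition is chemical. Iterative abiotic chemistries (formose, HCN
polymerisation) build mass ladders on their repeat units; petroleum is
dominated by long CH2 homologous series from lipid degradation; fresh
biological material concentrates its signal in fewer, high-contrast
compounds; meteoritic organics are extraordinarily diverse with broad KMD
spread. These signatures survive coarse binning, so no ultrahigh mass
resolution is required at the classification stage.

## From peak list to feature image

A peak list (m/z, intensity, optional S/N and formula) is first filtered to
the m/z 150–750 export window (inclusive endpoints) with S/N strictly
greater than 2 where an S/N column exists, then split by the parity of the
nearest integer to the measured m/z. Parity carries real information — even
and odd nominal masses sample different compound classes (the nitrogen
rule) — and doubles the number of data points; each sample contributes one
even and one odd feature image.

Each (sample, parity) peak list becomes a 3-D histogram:

* **Mass axis.** 32 equal bins over m/z 150–750, i.e. 18.75 Da per bin.
  Individual compounds are deliberately unrecoverable at this resolution.
* **Abundance axis.** For peak intensities $a_i$,
  $$y_i = \frac{\ln a_i - \langle \ln a \rangle + 0.5}{9.2},$$
  and $y \in [0,1]$ is mapped into 32 bins. The natural logarithm is used
  throughout: the constants only reproduce the transform's documented
  output range (lower bound $\approx 0.0987$) under the natural log. The
  offset 0.5 and scale 9.2 fit both the strongest peaks and the instrument
  noise floor into the unit interval, giving the axis a dynamic range of
  9.2 natural-log units ($\approx 10^4$ in intensity). Subtracting the mean
  log intensity self-calibrates each image: multiplying every intensity by
  a constant changes nothing, which the test suite asserts exactly.
  Peaks with $y$ outside $[0,1]$ are **dropped**, not clipped (a
  `clip = TRUE` switch exists for sensitivity analysis). The mean is
  computed per feature image — after windowing, S/N filtering and the
  parity split — so every data point is calibrated on exactly the peaks it
  contains.
* **KMD axis.** The Kendrick mass is $m/z \times 14.00000/14.01565$; the
  KMD is (nearest integer − Kendrick mass) × 1000, in mDa, with ties
  rounded half away from zero so the KMD always lies in $(-500, 500]$ —
  no peak can fall off the axis. Five 200-mDa bins cover the range.

All bins are half-open $[lo, hi)$ with the final bin closed. The raw counts
$n_{ijk}$ are normalised **over the mass index** for each fixed
(abundance, KMD) column,
$$N_{ijk} = \frac{n_{ijk}}{\sum_i n_{ijk} + \varepsilon}, \qquad
\varepsilon = 10^{-8},$$
which resolves faint structures and dense clusters on comparable footing,
and finally compressed:
$$X_{ijk} = 0.5 \ln(0.1 + N_{ijk}) + 1.25,$$
so every cell lies in $[0.5\ln 0.1 + 1.25,\; 0.5\ln 1.1 + 1.25] \approx
[0.0987, 1.2977]$. The 32 × 32 × 5 image is flattened mass-major
(element $((i-1) \cdot 32 + (j-1)) \cdot 5 + k$ is cell $(i,j,k)$) into a
5120-vector. The order is arbitrary for PCA — a coordinate permutation —
but fixed for reproducibility, and `unflatten_image()` inverts it exactly.

The featurizer is verified element-wise (to $10^{-12}$) against an
independent brute-force implementation that loops over peaks and bin edges.

## Classification protocol

`fit_biogenicity()` is the model proper: centered PCA (no per-feature
scaling, the standard default) of the flattened images, followed by
multinomial logistic regression on the leading component scores. The
logistic regression is `nnet::multinom` with weight decay 0.5 — the
conventional unit-strength L2 ridge penalty $\|w\|^2/2$ — and an iteration
cap of 500, which converges comfortably on 15-dimensional inputs.

Evaluation uses stratified $k$-fold cross-validation (`cross_validate()`,
default $k = 5$): a seeded shuffle within each class followed by
round-robin assignment with a fold pointer persisting across classes, so
per-class counts and overall fold sizes each differ by at most one across
folds. Within every fold the PCA is fitted on the training portion only
and both portions are transformed with the training loadings — no
information from held-out samples reaches the projection. Accuracy is the
micro-averaged fraction of correct test predictions.

Two protocol choices deserve comment:

* **Parity pairs and leakage.** The even and odd images of one sample are
  correlated. The default (`grouped = FALSE`) stratifies over data points,
  mirroring the straightforward protocol; `grouped = TRUE` keeps both
  parity points of a sample in the same fold, eliminating this mild
  leakage channel. The synthetic benchmark passes either way.
* **Component sweep.** `sweep_components()` reuses one fold assignment
  across the whole grid so the accuracy curve varies only with
  dimensionality, and fits one PCA per fold at the largest grid value,
  truncating the nested leading columns for smaller values — numerically
  identical to refitting, since principal components are nested.

## The synthetic-data generator

The study spectra behind the original analysis are not publicly archived,
so the package ships a generator (`generate_dataset()`) whose default
presets encode the qualitative class structure described above:

* **Petroleum** — 25 CH2 homologous series (mean length 25) with KMD drawn
  in a narrow 0–90 mDa band, each followed by an "echo": the same series
  offset by +150 mDa in KMD at 0.15× intensity.
* **Synthetic** — 12 mass ladders on HCN (27.010899 Da) or CH2O
  (30.010565 Da) repeat units with geometrically decaying intensity along
  the ladder; because the repeat units are not the Kendrick base, the KMD
  drifts stepwise, producing the characteristic diagonal progressions.
* **Biological** — 70 discrete masses with high log-intensity contrast
  (sdlog 2.5) plus four short lipid-like CH2 series.
* **Meteorite** — 4000 random masses across the window (KMD uniform over
  the full axis) with moderate contrast.

All classes share a noise floor of 300 random low-intensity peaks (S/N is
referenced to its scale, so the S/N > 2 export filter removes roughly half
of it, as it would on an instrument) and 0.2 ppm RMS seeded mass jitter —
small enough not to disturb 1 ppm biomarker matching. Intensity scales are
chosen so the structured signal spans roughly 9 natural-log units above
the noise floor, i.e. the dynamic range the abundance axis is built for.
Peak counts per class (here ~10² to ~4×10³ after filtering) intentionally
differ: peak density itself is a class feature.

A `structure` knob interpolates every class toward one common random model
(structured peak counts scale by `structure`, a shared random background
by `1 - structure`), so class separability is tunable; the tests verify
that accuracy degrades toward the 25% chance rate as structure is removed.

What the generator does **not** emulate: isotopologue patterns, realistic
formula-constrained mass positions, correlated series families, detector
saturation, chromatographic artefacts. Passing the end-to-end benchmark on
these caricatures demonstrates that the pipeline recovers the intended
relational structure when present — not that real samples of these four
classes are separable at any particular accuracy. The benchmark (40
spectra per class, master seed 0, 15 components, 5-fold CV) is the
property-based stand-in for the original study's held-out accuracy on its
own 56 spectra; at these settings the synthetic benchmark scores ≥ 0.95,
its label-permuted null sits at the chance rate, and the accuracy-versus-
components curve rises to a plateau. Those problem sizes keep the full
suite and the acceptance script to a few minutes on one CPU.

## Biomarker mass enumeration

Proteins decay abiotically into diketopiperazines (cyclic dipeptides,
DKPs), so DKP masses are a natural degraded-biology target set. A DKP's
neutral mass is the **sum of the two residue masses** (cyclisation removes
the two condensation waters; residue = amino acid − H2O), a relation the
code states explicitly. All 210 unordered pairs of the 20 coded amino
acids are enumerated and masses within $10^{-4}$ Da merged.

Every merge at that tolerance is an exact elemental-formula coincidence:
20 sequence degeneracies from Leu = Ile (C6H11NO) and 13 cross-pair
identities (Gly+Glu = Ala+Asp, Gly+Gln = Ala+Asn, Gly+Thr = Ala+Ser,
Ala+Met = Val+Cys, Asn+Trp = His+Tyr, ...), leaving **177 unique masses**.
This count is two lower than the figure of 179 sometimes quoted for the
same combinatorics, which misses the Ala+Met = Val+Cys (C8H14N2O2S) and
Asn+Trp = His+Tyr (C15H16N4O3) identities; both are exact for any
consistent mass table, as the exhaustive pairwise oracle in the test suite
confirms. The merge tolerance of $10^{-4}$ Da is deliberate: exact formula
coincidences merge, while near-isobars such as Lys vs Gln pairs (~36 mDa
apart) never do, so the count is stable over many orders of magnitude of
tolerance.

Saturated fatty acids CnH2nO2 (`sfa_series()`, default C2–C40) complete
the target sets. `match_peaks()` converts neutral masses to [M−H]⁻ m/z
(−1.00727646 Da, the proton mass) and reports the nearest measured peak
per target within a ppm tolerance (default 1 ppm, FT-ICR-appropriate).
Targets whose expected m/z falls below the detection cutoff (default
m/z 150) are flagged and excluded from the measurable denominator; direct
computation places four DKPs below that cutoff (cGlyGly, cGlyAla, cAlaAla,
cGlySer). Matches are m/z coincidences, never identifications — the
isomer space behind any one formula is astronomically large.

## Visual reconstructions

`reconstruct_image()` inverts the PCA at any score coordinate: the
training-mean image plus the chosen components scaled by their scores.
Reconstructions are raw linear combinations — they may leave the
transform's output range and are clipped only at render time.
`reconstruct_grid()` spans an 8 × 8 grid between the observed per-component
extremes of the first two scores (independent spans per component), the
"map of spectral space" view. `render_rgb()` displays three KMD slices of
an image as red, green and blue — by convention the zero-based slices
2, 3, 4, i.e. R indices 3, 4, 5, configurable — rescaled from the
transform's theoretical range to [0, 1]; where the slices agree the image
renders gray or white. `van_krevelen()` computes H/C vs O/C atomic ratios
from assigned CHNOS formulas for maturation-trend plots.

## Numerical choices and degenerate inputs

* Nearest-integer roundings (nominal Kendrick mass, parity) break ties
  half away from zero; the rule matters only on exact .5 boundaries.
* An empty (or fully filtered) spectrum is not an error: it yields the
  all-zero count tensor and the constant floor image
  $0.5\ln 0.1 + 1.25 \approx 0.0987$.
* The $\varepsilon = 10^{-8}$ stabiliser makes empty histogram columns map
  to 0 rather than 0/0; every nonzero column sums to $T/(T+\varepsilon)<1$.
* `fit_feature_pca()` refuses more components than
  $\min(n_\text{train}-1, p)$; degenerate requests fail loudly rather than
  silently truncating.
* Fold assignment requires at least $k$ members per class and refuses
  groups with inconsistent labels.
* Duplicate m/z values are kept as distinct peaks throughout; the sort is
  stable.

## Known limitations

* The generator is a caricature (see above); benchmark accuracies say
  nothing quantitative about real FT-ICR data.
* Only the [M−H]⁻ adduct is implemented; multiply charged species and
  adduct diversity are out of scope.
* Elemental-formula assignment is consumed, never performed.
* Vendor binary formats are not read; peak lists are delimited text.
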