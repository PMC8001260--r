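# kmdclass

Agnostic biogenicity classification of complex organic mixtures from
ultrahigh-resolution mass spectra.

Complex organic mixtures — microbial extracts, petroleum, meteoritic
organics, products of abiotic simulation chemistry (formose, HCN
polymerisation, Miller–Urey-type reactions) — yield thousands of resolved
peaks under FT-ICR MS. Deciding whether such a mixture is of biological or
abiological origin without identifying a single compound is the problem this
package addresses: instead of matching individual masses to biomarkers, it
classifies samples from the *relational* structure of the whole peak list.

## Method

Each peak list (m/z 150–750, S/N > 2) is split by nominal-mass parity and
converted into a 3-D histogram over mass, log relative abundance and
CH₂-based Kendrick mass defect (KMD):

- **mass axis**: 32 bins of width 18.75 Da over m/z 150–750;
- **abundance axis**: for peak intensity *aᵢ*,
  *yᵢ* = (ln *aᵢ* − ⟨ln *a*⟩ + 0.5) / 9.2, with *y* ∈ [0, 1] mapped into 32
  bins (mean-log subtraction makes the image invariant to overall intensity
  scale);
- **KMD axis**: KMD = (nominal Kendrick mass − Kendrick mass) × 1000 mDa,
  five 200-mDa bins over (−500, 500].

The raw counts *n₍ᵢⱼₖ₎* are normalised over the mass index,
*N₍ᵢⱼₖ₎* = *n₍ᵢⱼₖ₎* / (Σᵢ *n₍ᵢⱼₖ₎* + ε) with ε = 10⁻⁸, and compressed by a
truncated log transform *X₍ᵢⱼₖ₎* = 0.5 ln(0.1 + *N₍ᵢⱼₖ₎*) + 1.25, whose
output lies in ≈[0.0987, 1.2977]. The 32 × 32 × 5 image is flattened to a
5120-vector; centered PCA followed by multinomial logistic regression on
the component scores classifies samples into Biological / Meteorite /
Petroleum / Synthetic, evaluated under stratified 5-fold cross-validation.

Companion analyses: enumeration of diketopiperazine (cyclic dipeptide) and
saturated-fatty-acid target masses with [M−H]⁻ ppm matching against peak
lists; reconstruction of model images from PCA score extremes; KMD-slice
RGB renderings; van Krevelen (H/C vs O/C) coordinates from assigned
formulas. A synthetic-spectrum generator produces labelled four-class
datasets with class-typical homologous-series structure so the whole
pipeline is testable end to end.

## Worked example

```r
library(kmdclass)

gd <- generate_dataset(per_class = 10, master_seed = 0)
ds <- featurize_dataset(gd$spectra)
ds
#> <labeled_dataset> 80 data points x 5120 features
#> Biological  Meteorite  Petroleum  Synthetic
#>         20         20         20         20

cross_validate(ds, n_components = 15, k = 5, seed = 0)
#> 5-fold CV, 15 PCA components (seed 0)
#>   fold accuracies: 1.000 0.812 0.938 0.875 0.875
#>   mean 0.900  sd 0.071

sweep_components(ds, c(1, 2, 5, 10, 15), k = 5, seed = 0)
#> Component sweep, 5-fold CV (seed 0)
#>  n_components mean_accuracy sd_accuracy
#>             1         0.725      0.0559
#>             2         0.950      0.0685
#>             5         0.938      0.0884
#>            10         0.925      0.0815
#>            15         0.900      0.0713
```

Forty spectra (ten per class) become 80 data points — each sample
contributes its even- and odd-mass subspectrum. Held-out accuracy reaches
0.90–0.95 once a handful of principal components is retained, against a
0.25 chance rate for four balanced classes; one component is already well
above chance. `fit_biogenicity(ds, n_components = 15)` fits the final model
on all data and `predict()` classifies new feature vectors.

Biomarker enumeration:

```r
enumerate_dkp_masses()
#> <target_mass_list> 177 targets (DKP)
#>    114.04293  cGlyGly
#>    128.05858  cGlyAla
#>    142.07423  cAlaAla
#>    ...
```

The 210 unordered pairs of the 20 coded amino acids collapse to 177 unique
neutral masses: Leu/Ile sequence degeneracy plus 13 exact elemental-formula
coincidences (e.g. Gly+Glu = Ala+Asp = C₇H₁₀N₂O₄).
`match_peaks(s, enumerate_dkp_masses(), ppm_tol = 1)` then reports which
targets have a measured [M−H]⁻ peak within 1 ppm, flagging targets below
the m/z 150 detection cutoff.

A thin command-line front end over these functions is installed at
`inst/cli/kmdclass.R` (subcommands `synth`, `cv`, `match`, `filter`).

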