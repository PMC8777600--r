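---
title: "Screening ginkgo supplements by two-trace 2D correlation spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ginkgo supplements by two-trace 2D correlation spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginkgocos)
```

## The screening problem

Ginkgo biloba food supplements are frequently adulterated with cheap
flavonols — rutin, or the aglycones quercetin and kaempferol — to mimic a
standardized flavonoid content. Genuine leaf extract is glycoside-rich
and contains aglycones only in traces, so a high free-aglycone signal is
a red flag. UV-Vis spectra of supplement extracts are cheap to acquire
but consist of broad, overlapping flavonoid bands (band I, the cinnamoyl
band, at roughly 320–385 nm; band II, the benzoyl band, at 240–280 nm),
so single spectra are hard to read directly.

`ginkgocos` implements a correlation-spectroscopy approach to this
problem. From a *pair* of spectra — a sample trace $s(\nu)$ and a
reference trace $r(\nu)$ on a common wavelength grid — two-trace
two-dimensional (2T2D) correlation maps are computed:

$$\Phi(\nu_1, \nu_2) = \tfrac12\left[s(\nu_1)s(\nu_2) + r(\nu_1)r(\nu_2)\right],
\qquad
\Psi(\nu_1, \nu_2) = \tfrac12\left[s(\nu_1)r(\nu_2) - r(\nu_1)s(\nu_2)\right].$$

The synchronous map $\Phi$ is symmetric and captures shared intensity
structure. The asynchronous map $\Psi$ is antisymmetric with a zero
diagonal, vanishes identically whenever $s \propto r$, and develops
off-diagonal cross peaks exactly where the two traces differ in
*relative* band content. Because only ratios of band weights matter,
$\Psi$ is insensitive to overall concentration — the property that makes
it usable on extracts of unknown dilution.

Three series of asynchronous maps are assembled per product cohort:

* **Series A** — methanolic extract vs. aqueous extract of the *same*
  product. Quercetin and kaempferol dissolve well in 80% methanol and
  poorly in water, so an aglycone adulterant produces band-I cross peaks;
  an unadulterated, glycoside-dominated product gives a near-empty map.
* **Series B** — methanolic extract vs. an authentic reference-extract
  spectrum. Cross peaks flag any deviation from the authentic matrix.
* **Series C** — methanolic extract vs. the average of the three
  adulterant standard spectra, each pre-scaled to unit area (sum of
  absorbances × grid step) so that no standard's arbitrary concentration
  dominates the mean.

The per-product maps are stacked and summarized by multiway PCA, and the
chromatographic flavonol table (percent peak area of rutin / quercetin /
kaempferol) is clustered by Ward linkage.

## Wavelength grid and map conventions

All analysis happens on a uniform inclusive-endpoint grid, by default
245–410 nm at 1 nm (166 points). Spectra on other grids are linearly
interpolated onto the analysis grid — the simplest defensible choice for
smooth UV-Vis bands at 1 nm spacing — and extrapolation is never
performed: a spectrum that does not cover the analysis range is rejected,
not padded. Maps are stored with rows indexing the sample axis $\nu_1$
and columns the reference axis $\nu_2$; this convention is arbitrary but
fixed, and the map CSV format stores both axes explicitly. Maps are
computed on raw (resampled) absorbance, not pre-normalized spectra: the
defining equations act on $s$ and $r$ directly, and concentration scale
is removed later by the MPCA row normalization.

## Cross-peak detection

Cross peaks of $|\Psi|$ are localized as 8-neighbour local maxima in the
upper triangle ($\nu_2 > \nu_1$; the lower triangle holds mirror images),
subject to three tunable filters:

| parameter | default | units | role |
|---|---|---|---|
| `rel_threshold` | 0.10 | fraction of max $\lvert\Psi\rvert$ | discard ripples far below the dominant peak |
| `min_offdiag` | 5 | nm | exclude near-diagonal artifacts (diagonal is exactly zero, but noise creates shoulders) |
| `merge_radius` | 4 | nm (Chebyshev) | collapse ridge doublets into one reported peak |

The defaults were chosen once against noise-free synthetic maps, where
the expected answer is known (a single adulterant band pair must yield a
single peak). Exact plateaus — possible in constructed maps, measure-zero
in noisy data — count once, at the lexicographically lowest $(\nu_1,
\nu_2)$ grid point of the plateau. Detected peaks are reported with their
sign (the sign of $\Psi$ at the peak), sorted by descending magnitude.

## Multiway PCA

A stack of $n$ maps of size $p \times p$ is unfolded row-major into an
$n \times p^2$ matrix; MPCA is then, definitionally, ordinary PCA of the
unfolded matrix (a property the test suite checks by computing both
paths). Preprocessing is two-step and its parameters are stored for
projecting new samples:

1. **Row normalization** — each unfolded map is divided by its Euclidean
   (Frobenius) norm. This removes the quadratic concentration scale of
   the maps; scores become invariant to positive scaling of any input
   map. Zero-norm rows (all-zero maps) are left unchanged and flagged.
2. **Autoscaling with offset** — each column is mean-centered and
   divided by its standard deviation ($n-1$ denominator) plus an offset,
   default $10^{-5}$. The additive offset guards the many
   near-constant map pixels against division blow-up.

Rows are normalized before columns are scaled; the reverse order is also
defensible, but one order has to be fixed and this one removes sample
scale before estimating per-variable spread. The decomposition itself is
a thin SVD; each loading vector's sign is flipped so its
largest-magnitude element is positive, making scores reproducible across
platforms. Explained variance per component is
$\sigma_i^2 / \sum_j \sigma_j^2 \times 100$, and
$\mathrm{RMSEC}(k) = \sqrt{\sum \text{residual}^2 / (n p^2)}$ over the
rank-$k$ reconstruction, in preprocessed (unitless) units with the
denominator counting all matrix entries.

Cross-validation uses the venetian-blinds scheme, default ten splits
with two samples per blind: sample $i$ (in stack order, 0-based) joins
split $\lfloor i/2 \rfloor \bmod 10$, i.e. contiguous pairs dealt
round-robin. An interleaved variant (`order = "interleave"`) is exposed
because toolboxes differ in their exact dealing pattern. For each split,
preprocessing parameters *and* the PCA are refit on the retained samples
only; the left-out rows are preprocessed with the training parameters
and reconstructed from the first $k$ loadings.

## The synthetic cohort generator

No raw spectra ship with the package, so the generator is a first-class
module: it emulates exactly the statistical structure the analysis
relies on, and the tests quantify the pipeline against its known ground
truth.

Each component is a sum of Gaussian bands. The flavonol models place
bands at the literature absorption maxima with invented but
spectroscopically plausible widths:

| component | band II (nm, σ, height) | band I (nm, σ, height) | f(methanol) | f(water) |
|---|---|---|---|---|
| rutin | 257, 12, 1.0 | 355, 18, 1.0 | 0.90 | 0.50 |
| quercetin | 255, 12, 1.0 | 368, 18, 1.0 | 0.95 | 0.10 |
| kaempferol | 265, 12, 1.0 | 365, 18, 0.9 | 0.95 | 0.10 |
| ginkgo matrix | 265, 12, 1.0 (+ shoulder 255, 25, 0.6) | 350, 18, 1.0 | 0.90 | 0.90 |

The extraction fractions $f$ encode the solubility contrast the
dual-solvent series exploits: aglycones nearly vanish from the aqueous
extract (0.10 vs. 0.95), the glycoside rutin is partially water-soluble
(0.50 vs. 0.90), and the glycoside-rich matrix extracts equally into
both solvents. The ginkgo-matrix model is *not* a physical fingerprint —
only its qualitative distinctness from the three adulterants matters,
and the shoulder height (0.6 AU) was fixed once to give a visibly
asymmetric band-II region.

An extract spectrum is
$A(\nu) = \sum_c \text{amount}_c \cdot f_{\text{solvent}}(c) \cdot
\text{component}_c(\nu) + \varepsilon(\nu)$ with iid Gaussian noise,
default $\sigma = 0.002$ AU — about 0.1–0.3% of a typical band height,
a realistic photometric noise floor. Cohort archetypes mirror the
product groups seen in flavonol tables of commercial supplements:

* `authentic` — matrix only;
* `rutin_adulterated` — matrix 1, rutin 6 (adulterant ≈ 6× matrix
  signal, the "dominant component" regime);
* `quercetin_adulterated` — matrix 1, quercetin 6;
* `quercetin_kaempferol_adulterated` — matrix 1, quercetin 3,
  kaempferol 3 (the ≈1:1 dual-aglycone pattern);
* `no_ginkgo` — equal parts rutin/quercetin/kaempferol and no matrix at
  all (a flavonol-only fake).

Per-product amounts get ±15% lognormal jitter (sdlog 0.15). Randomness
uses one root seed from which per-product child seeds are derived by a
fixed integer mix of (root, product index), so enlarging a cohort never
reshuffles the products already generated, and regeneration from one
seed is bit-identical end to end. The generated flavonol table is
computed from the ground-truth amounts (percent of each flavonol in the
total component amount) — chromatogram simulation is deliberately out of
scope.

What the generator does **not** emulate: baseline drift and scatter,
pH/solvatochromic band shifts, instrument stray light, non-flavonoid
matrix absorbers, and calibrated molar absorptivities. Tests passing on
synthetic cohorts therefore demonstrate the correctness and the
discriminating geometry of the *algorithms*, not field performance on
real products.

## Ward clustering of the flavonol table

The packaged 20-product flavonol table is clustered after mean centering
(translation-invariant for Euclidean distances, so it affects only the
score origin, kept as the documented preprocessing step) with Ward's
minimum-variance criterion on Euclidean distances, in the "ward.D2"
convention: squared-distance objective, merge heights reported on the
distance scale. No column standardization is applied beyond centering —
all three columns share percentage units. Flat partitions cut the tree
by undoing the last $k-1$ merges, with labels renumbered in first-seen
row order; `k` is an explicit argument, with `k = 4` as the default
four-group reading (rutin-dominant; quercetin-dominant; quercetin ≈
kaempferol; low-flavonol). On the packaged table the four interpretable
groups all appear as subtrees of the dendrogram, but the uniform-height
four-cluster cut splits a small quercetin-rich branch (S10, S14, S15)
off the quercetin-dominant group before the quercetin≈kaempferol group
separates — a reminder that a flat cut and a visual reading of the same
tree can disagree; the acceptance suite documents this case.

## Numerical choices and edge cases

* Grids are validated to 1e-9 (divisibility of range by step); spectrum
  I/O round-trips to better than 1e-12 relative error (17 significant
  digits in all text output).
* Symmetry/antisymmetry of maps holds to 1e-12 of the max magnitude by
  construction (one `tcrossprod` reused for both triangles).
* Degenerate inputs fail loudly before computation: mismatched grids,
  empty cohorts, nonpositive areas in the adulterant average, training
  folds smaller than two samples, `k_max` beyond the rank bound.
* Ties: equal-cost Ward merges follow the deterministic order of the
  underlying agglomeration; exact peak plateaus resolve
  lexicographically (see above). Neither occurs for continuous noisy
  data.

## Problem sizes

The shipped tests run the full pipeline at the scale the method is meant
for: 166-point grids, 166×166 maps (27 556 unfolded variables), cohorts
of up to 12 products for the score-space recovery study (three
archetypes × 4 products, default noise, series B, k-means on three
score dimensions), and 50×50 random maps for the exhaustive peak-scan
cross-check. The whole suite completes in a few seconds on one CPU.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(c(authentic = 2, rutin_adulterated = 2,
                        quercetin_adulterated = 2), seed = 7)
stA <- build_series(co, "A")
detect_cross_peaks(stA$maps[[3]])   # rutin-adulterated product

model <- mpca(build_series(co, "B"), k_max = 3)
model$explained_variance_pct
model$scores

hca_flavonols(load_table1(), k = 4)$partition
```

## Known limitations

* The synthetic ginkgo matrix is a placeholder, not a measured
  fingerprint; absolute cross-peak coordinates involving matrix bands
  carry no physical meaning beyond the band positions chosen above.
* MPCA figures of merit (explained variance, RMSEC/RMSECV) depend
  entirely on the cohort at hand; values computed on synthetic cohorts
  are not comparable to values from instrument data.
* Adulterant concentrations in real products are unknown; archetype
  effect sizes are tunable presets, not estimates.
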