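---
title: "Methods: pigment templates, MSP fitting, lens refractivity, TMM, and the exact direction test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pigment templates, MSP fitting, lens refractivity, TMM, and the exact direction test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visadapt)
```

`visadapt` collects the bespoke computational pieces needed to study visual
adaptation across amphibian metamorphosis: what the eye's photoreceptors
absorb (visual pigment spectra), what the lens is made of (crystallin
refractivity), and how gene expression shifts between life stages
(normalization and a direction-count test). This vignette explains the
models, their assumptions, the tunable parameters, and the numerical and
design choices that were genuinely open.

## Visual pigment templates

A vertebrate visual pigment is an opsin protein bound to one of two
chromophores: A1 (retinal) or A2 (3,4-didehydroretinal). Pigment absorbance
spectra are strikingly stereotyped: on a normalized wavelength scale they
are described by a closed-form template parameterized only by the wavelength
of peak absorbance, $\lambda_{\max}$, and the chromophore (Govardovskii et
al. 2000). The main (alpha) band is a reciprocal sum of exponentials in
$x = \lambda_{\max}/\lambda$,

$$S_\alpha(x) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D},$$

with chromophore-specific constants, some of which depend smoothly on
$\lambda_{\max}$; a Gaussian beta band (the cis peak in the near UV) is
added. A2 pigments are red-shifted and spectrally broader than A1 pigments
built on the same opsin -- the property that makes chromophore
classification from spectral shape possible at all.

Numerical choices:

* **Constants as data.** All template constants ship in
  `inst/extdata/govardovskii_constants.tsv` and are loaded at run time
  (`govardovskii_constants()`), so a transcription correction is a data
  edit, not a code change.
* **Renormalization.** The raw alpha+beta sum peaks near, but not exactly
  at, 1. Every evaluated curve is rescaled so its global maximum is exactly
  1 (located by golden-section search near the nominal peak and cached per
  $(\text{chromophore}, \lambda_{\max})$), because the fitting pipeline
  compares peak-normalized spectra to peak-normalized templates.
* **Validity range.** $\lambda_{\max}$ is restricted to 350--650 nm --
  covering every amphibian photoreceptor class handled here -- and
  evaluation to 300--800 nm. Outside these, the package errors rather than
  extrapolate.
* **Beta band.** On by default. Fits restricted to the long-wavelength limb
  never touch it, so it is configurable off; whether the original fits
  included it is not recoverable, and with limb fitting the choice is
  inconsequential.
* **FWHM** is found by stepping outward from the peak in 0.5-nm increments
  and polishing each half-maximum crossing by bisection; the crossing
  nearest the peak is used, which stays correct when the beta band
  re-crosses the half-maximum level far to the blue.

`mixture_template()` models a cell containing both pigment forms as a
convex combination of the two pure normalized curves, renormalized to peak
1. Its peak moves monotonically from the A1 peak to the A2 peak as the A2
fraction rises -- the mechanism usually invoked for rods with intermediate
spectra.

## MSP spectrum processing

Microspectrophotometry measures the absorbance of a single photoreceptor
outer segment, scanned from 750 to 350 nm and back. The per-cell pipeline
(`fit_cell()`):

1. **Merge scans** (`merge_scans()`): pointwise mean of the two directions
   on their common grid. The combination rule is not standardized anywhere;
   the mean is the obvious unbiased choice, and merging demonstrably lowers
   peak-recovery error versus either single scan.
2. **Peak estimation** (`find_peak()`): a Gaussian is fit to the top 40
   data points and differentiated for the peak. The fit is quadratic least
   squares on log-absorbance -- exact for a true Gaussian, closed-form, and
   free of iterative-optimizer seed sensitivity. "Top 40" means the 40
   highest-absorbance samples; a contiguous-window mode exists
   (`contiguous = TRUE`), as does a raw-scale nonlinear Gaussian fit
   (`log_scale = FALSE`). A vertex falling outside the selected points, or
   non-negative curvature, flags the estimate unreliable and falls back to
   the empirical maximum.
3. **Normalization** (`normalize_spectrum()`): absorbance divided by the
   fitted peak height, so the fitted peak value is 1 (individual noisy
   points may exceed 1).
4. **Template fitting** (`fit_template()`): grid search over candidate
   $\lambda_{\max}$ (peak estimate $\pm$ 30 nm at 0.1-nm steps -- an order
   finer than the method's $\pm$1 nm accuracy) minimizing the SSE between
   the normalized spectrum and the template. The default fit window is the
   long-wavelength limb: wavelengths beyond the fitted peak where the
   template centred on the peak estimate lies in [0.10, 0.90]. The limb is
   the region most diagnostic of $\lambda_{\max}$ and is insensitive to the
   beta band and to short-wavelength scatter. The window is fixed *before*
   the search rather than per candidate: a per-candidate window makes the
   SSE landscape discontinuous as points enter and leave it, which
   de-stabilizes the argmin at sub-0.1-nm scales. A full-spectrum window
   ($\geq$ 400 nm) is available via `window = "full"`.
5. **Chromophore decision** (`decide_chromophore()`): the fit (A1 or A2)
   with lower SSE wins; exact ties (|ΔSSE| < 1e-9) resolve to A1 with a tie
   flag, the conservative default given that A1 is the ancestral/adult
   state here. Independently, a best-fit $\lambda_{\max} > 580$ nm raises
   the `a2_flag`: no known A1 pigment absorbs that far red, so A2 must be
   present regardless of which template happened to fit better.
6. **Classification** (`classify_cell()`): $\lambda_{\max}$ bins, default
   SWS2 rod 420--445, RH1 rod 490--535, LWS cone 560--645 nm, derived from
   the reported ranid values (433/437, 501--526, 579--635); anything else
   is `unknown`. Bins are configurable and checked for overlap.
7. **Summaries** (`summarize_class()`): per class (or per custom grouping)
   cell count, mean best-fit $\lambda_{\max}$ (reported rounded half-up to
   the nearest integer, matching field practice), and best-fit chromophore
   counts.

Flat spectra are rejected as "no pigment" when the dynamic range of a
25-point moving average falls below 3x the point-to-point noise estimate
(SD of first differences / $\sqrt{2}$). The smoothing matters: over ~400
points, raw iid noise alone spans ~6.5 SD, so a raw-range rule could never
reject a pigment-free scan.

Open questions resolved as configuration: whether the original Gaussian was
fit on raw or log absorbance (default log, exact and deterministic), and
whether SSE is better computed on absorbance or log absorbance (absorbance;
log would up-weight the noisy tail where absorbance approaches zero).

## Protein refractive index increments (dn/dc)

A protein's refractive index increment (mL/g) measures how much it raises
the refractive index of a solution per unit concentration -- for lens
crystallins, their contribution to the focusing power of the lens.
Following the composition-based approach of Zhao, Brown & Schuck (2011),
each residue carries a specific refraction and a partial specific volume
(McMeekin refractivities; Cohn--Edsall volumes), shipped as
`inst/extdata/residue_refractivity.tsv`. For a composition with residue
mass fractions $w_i$:

$$\bar v = \sum_i w_i \bar v_i, \qquad
  \bar r = \sum_i w_i \bar v_i \frac{n_i^2 - 1}{n_i^2 + 2}, \qquad
  \frac{n_p^2 - 1}{n_p^2 + 2} = \frac{\bar r}{\bar v},$$

and the Heller relation converts the protein refractive index $n_p$ to
dn/dc in a solvent of index $n_0$ (default 1.3340; 589 nm, 25 C):

$$\frac{dn}{dc} = \frac{3 n_0 \bar v}{2}\,
  \frac{(n_p/n_0)^2 - 1}{(n_p/n_0)^2 + 2}.$$

Residue refractive indices $n_i$ are derived from the tabulated
residue-level dn/dc values by inverting the same Heller relation at the
table's reference solvent, which makes the homopolymer case an exact
identity. The computation is composition-only (invariant to residue order),
uses residue masses (amino acid minus one water) with no terminal
correction, and uses input sequences exactly as given. Aromatic residues
(Trp 0.277, Tyr 0.240, Phe 0.244 mL/g) raise dn/dc; this is why
aromatic-rich gamma-crystallins out-refract aromatic-poor
alpha-crystallins, the ordering the synthetic profiles reproduce.
Expression weighting (`weighted_mean_dndc()`) is a plain weighted mean over
nonnegative weights -- typically TMM-normalized expression summed over the
samples of a life stage -- and is invariant to rescaling all weights.

Hydration, wavelength dispersion beyond 589 nm, and lens ray tracing are
out of scope.

## TMM normalization

Between-sample comparability of expression requires correcting both
sequencing depth and library composition: if a biased subset of genes is
up in one condition, dividing by total counts alone deflates every other
gene there. TMM (Robinson & Oshlack 2010) computes, against a reference
sample (the one whose upper quartile is closest to the mean upper
quartile), gene-wise log-ratios M and log-abundances A, discards genes with
zeros in either sample, doubly trims (30% on M, 5% on A), and averages the
remaining M values weighted by inverse delta-method binomial variance; the
resulting factors are rescaled to geometric mean 1. `tmm_factors()` follows
the canonical implementation's conventions exactly (the tests confirm
agreement with `edgeR::calcNormFactors` to 1e-10), and
`apply_factors()` divides by effective library size (library size x
factor), rescaled to their mean.

Two subtleties the tests document: TMM factors are (up to the count-based
precision weights) invariant to rescaling any column, so "re-running TMM on
the normalized matrix" only returns unit factors if the re-run is told the
effective library sizes are already equal (`lib_sizes =`); and recovery of
non-DE comparability is assessed on *geometric* means of non-DE genes at
transcriptome scale (10,000 genes), because arithmetic means of
heavy-tailed (lognormal, SD(log) = 1.2) counts with NB dispersion 0.1 do
not concentrate to within 5% at desk scale no matter how good the
normalization -- a few very large genes with ~30% coefficient of variation
dominate them.

## The unconditional exact Z-pooled test

Whether cone-specific genes tilt toward tadpole upregulation while
rod-specific genes tilt the other way reduces to a 2x2 table: $x_1$ of
$n_1$ cone genes up in tadpoles versus $x_2$ of $n_2$ rod genes. The
statistic is the pooled-variance two-sample Z,

$$Z = \frac{x_1/n_1 - x_2/n_2}
  {\sqrt{\hat p (1 - \hat p)\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)}},
  \qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

defined as 0 when $\hat p \in \{0, 1\}$. The unconditional exact test
(Suissa--Shuster / Barnard type) fixes only the row margins: under the null
both counts are independent binomials with a common unknown success
probability $\pi$, the two-sided rejection region is
$\{|Z(y_1, y_2)| \geq |z_{obs}|\}$ (floating-point ties within 1e-12
included), and the p-value is the supremum over $\pi$ of the region's
probability. The supremum is taken on a 0.001 grid over (0, 1) with local
golden-section refinement around the grid argmax -- deterministic, and
stable to grid refinement within 1e-3. Degenerate tables ($\hat p$ 0 or 1)
give $Z = 0$ and $p = 1$. Only the Z-pooled variant is offered; Fisher's
conditional test and other unconditional statistics are deliberately out of
scope.

For the observed table (8/10 vs 3/10) this gives $Z = 2.247$ and two-sided
$p = 0.041$:

```{r}
zpooled_test(8, 10, 3, 10)
```

`simulate_size_power()` checks validity by Monte Carlo: over the whole
nuisance range at $n_1 = n_2 = 10$ the estimated type-I error stays at or
below the nominal 0.05 (up to Monte-Carlo error), and power at the
observed effect size (0.8 vs 0.3) exceeds one half.

## What the synthetic generators emulate -- and what they do not

All generators are pure functions of (configuration, seed) and return truth
records for recovery testing.

* `gen_spectrum()`: template shape x peak absorbance + optional linear
  baseline + iid Gaussian noise. Default peak absorbance is 0.015 -- the
  realistic single-outer-segment MSP scale -- so normalization is exercised
  nontrivially. Noise is *absolute* on the absorbance scale; recovery tests
  that quote "noise SD 0.01" relative to a unit peak therefore set
  `peak_absorbance = 1`. Real MSP noise is not iid Gaussian (it is
  wavelength-dependent and includes baseline curvature and bleaching
  drift), so a green recovery test establishes correctness of the
  estimator, not field performance on the worst tadpole scans.
* `gen_cell_population()`: per-cell true $\lambda_{\max}$ drawn normally
  (default SD 2 nm between cells) with a pure chromophore per class. Real
  populations may contain chromophore mixtures; classification accuracy on
  pure-chromophore synthetics is an upper bound.
* `gen_protein()`: iid draws from a residue frequency profile
  (natural/gamma-like/alpha-like). Real crystallins have domain structure
  and composition constraints that iid sampling ignores; only
  composition-level statistics are meaningful.
* `gen_counts()`: lognormal baseline means (meanlog log 500, sdlog 1.2 --
  typical bulk RNA-seq depth and spread), NB dispersion 0.1, a DE fraction
  upregulated entirely in one sample group (the asymmetric case TMM must
  withstand), and per-sample depth multipliers. No gene-gene correlation,
  batch structure, or length bias is simulated.
* `gen_direction_table()`: independent binomial draws feeding the exact
  test's size/power machinery.

## Known limitations

* Template constants apply to vitamin-A visual pigments within the fitted
  validity range of the published family; very short-wave pigments
  ($\lambda_{\max} < 350$ nm) are excluded.
* Chromophore discrimination degrades for noisy spectra of small outer
  segments; the 580-nm rule exists precisely because template SSE alone is
  not decisive there.
* dn/dc values are composition-level estimates at 589 nm / 25 C; hydration
  and dispersion effects are not modelled, and reproducing any particular
  study's per-protein values requires that study's exact sequences.
* The exact test enumerates outcomes, so it is intended for small gene
  panels (the enumeration bound is $10^6$ outcomes).
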