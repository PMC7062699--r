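---
title: "Estimating leaf N, P and K from all-pair spectral indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating leaf N, P and K from all-pair spectral indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leaf nitrogen, phosphorus and potassium content (mg per g dry matter)
indicate plant nutrition status, and in degraded vegetation they track
the degradation process itself. Leaf-clip spectrometers record
reflectance at 1 nm resolution over roughly 325–1075 nm, and nutrient
content imprints on this spectrum indirectly, through pigments, leaf
structure and water. Rather than committing in advance to a handful of
fixed published band combinations, the approach implemented here scans
*every* two-band combination of the spectrum under ten index formula
families, finds the wavelengths that participate in the most
statistically significant nutrient correlations, and builds stepwise
linear models on those sensitive bands. A registry of 43 published
empirical vegetation indices provides the comparison baseline.

## The pipeline

1. **Trim.** The marginal ranges below 350 nm and above 1000 nm are
   noisy on handheld instruments and are removed; the closed interval
   [350, 1000] nm (651 bands) remains. Wavelengths are always addressed
   by physical nm value, never positional index, so no off-by-one drift
   can arise after trimming or differentiation.
2. **Differentiate.** The first-derivative spectrum is the difference
   in reflectance between successive wavebands. The package's
   convention is the forward difference FD(λ) = R(λ+1) − R(λ) over the
   1 nm step, assigned to the lower wavelength; the derivative grid is
   one band shorter at the upper end (350–999 nm). This is the simplest
   convention consistent with "difference between successive
   wavebands"; a central-difference option exists but is not the
   default.
3. **Index families.** Ten families over bands i, j: reflectance R at
   a single band, difference D = Rj − Ri, ratio RR = Rj/Ri, normalized
   difference ND = (Rj − Ri)/(Rj + Ri), inverse difference
   ID = 1/Rj − 1/Ri, and the same five forms on the derivative (FD,
   FDD, FDRR, FDND, FDID). Two-band families are evaluated over all
   ordered pairs.
4. **Correlation maps.** Each cell is Pearson-correlated with the leaf
   nutrient across samples; the two-sided p-value comes from the t
   transform t = r·√((n−2)/(1−r²)).
5. **Sensitive bands.** Cells with p < α (default 0.05) are tallied per
   wavelength — a significant two-band cell credits both of its bands —
   and the top k (default 22 per nutrient) become the sensitive set.
6. **Stepwise models.** Candidate predictors built from the sensitive
   bands enter a forward-entry/backward-removal loop under partial-F
   thresholds; the held-out samples validate the fitted model by
   regressing predicted on observed values.

```{r example}
library(nutrispec)
data <- generate_dataset(design_spec(seed = 1))
splits <- split_calibration_validation(data, seed = 1)
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run"))
```

## Parameters that matter

* `alpha` (default 0.05, two-sided): per-cell significance of the
  scan. Deliberately **uncorrected** for multiple testing across the
  ~4×10⁶ cells of a full scan — the screening convention this pipeline
  reproduces thresholds each cell's raw p. `count_significant()`
  reports the expected number of false-positive cells under the null as
  a safety rail and offers a Benjamini–Hochberg mode (`adjust = "BH"`)
  for users who want control instead of fidelity.
* `k` (default 22 bands per nutrient): size of the sensitive set. The
  screening literature motivating this default is ambiguous about
  whether such counts are per nutrient or total, so `k` is an explicit
  parameter everywhere it is used.
* `entry_p` / `removal_p` (defaults 0.05/0.10): the common stepwise
  convention of the major statistics packages, which the source
  procedure did not specify. `removal_p < entry_p` is rejected because
  it can cycle.
* `min_n` (default max(3, half the samples)): minimum effective sample
  size for a scan cell. Derivative-ratio families (FDRR, FDND, FDID)
  produce many undefined cells because derivatives cross zero; without
  a floor such cells would be judged on a handful of samples and
  dominate the tallies by chance.
* Red-edge windows: blue edge 490–530 nm, yellow edge 560–640 nm, red
  edge 680–760 nm (common literature convention, configurable). REP is
  the argmax of the derivative in the red window; SDb/SDy/SDr are the
  summed derivative over each window; RES is the derivative value at
  REP.

## Numerical choices

* **Undefined marker.** Zero denominators yield `NA`, never an
  exception and never ±Inf. Derivative values cross zero routinely, so
  the ratio families would otherwise fail on nearly every real
  spectrum. Downstream correlation drops `NA` pairs and reports the
  effective n.
* **Degenerate cells.** A scan cell with fewer than `min_n` defined
  pairs or zero variance is marked invalid (`NA` r and p), never
  silently zeroed; |r| is clamped to [−1, 1] against floating-point
  overshoot, and |r| = 1 maps to p = 0 exactly.
* **Stepwise perfect-fit guard.** When the current model's residual sum
  of squares falls below 10⁻¹⁰ of the total sum of squares, entry
  stops: partial-F p-values computed on zero residuals are numerical
  noise and would admit spurious terms.
* **Collinearity.** A candidate whose addition does not increase the
  rank of the design matrix is skipped with a message; an exact
  duplicate of an entered term can therefore never join it.
* **Tie-breaking** in band ranking is deterministic: larger
  significance count, then larger best |r| among the band's significant
  cells, then lower wavelength.
* **Round-trip IO.** Spectra are written with 15 significant digits so
  write→read reproduces values to better than 10⁻⁹.

## The published-model registry

Twelve stepwise equations (families D, ND, FD, FDD × nutrients N, P,
K) and nine single-index equations (RES, DVI, FD730−570 per nutrient)
from a field calibration on temperate degraded vegetation ship as a
versioned JSON resource, coefficients digit-for-digit as printed. The
stepwise entries name each predictor by family and *one* band (e.g.
`D_937`); the partner band of the two-band families was not recorded
with the printed equations, so the registry treats each such predictor
as an abstract named input the caller supplies — inventing the missing
partner band would be worse than requiring it. Models fitted by this
package always record both bands.

The printed adjusted R² values of the stepwise registry are not
consistent with the standard adjustment formula at the calibration
size those equations report (e.g. R² 0.876 with adjusted 0.850 implies
n ≈ 18, not 64). The registry stores both numbers as printed and makes
no attempt to force agreement; models fitted here report their own
`n_fit` and a freshly computed adjustment.

## The empirical-index registry

The 43 comparison indices are registered by name with a formula
string, a literature citation and the evaluation function itself. The
source material for this comparison lists index *names* only, so each
formula here is the standard literature definition (e.g. NDVI705 =
(R750−R705)/(R750+R705), PRI = (R531−R570)/(R531+R570), OSAVI =
1.16(R800−R670)/(R800+R670+0.16)). For names whose exact source
formula is not recoverable (NVI, NDCI, RI1dB, TVIBL, Viopt, the
broadband MSS-* and AVHRR-GVI entries), a documented choice was made
and recorded in the entry's citation string: broadband legacy-sensor
indices average reflectance over simulated band windows (MSS green
500–600, red 600–700, NIR 700–800 and 800–1000 truncated at the grid
limit; AVHRR red 580–680, NIR 725–1000), MSS-PVI uses the
perpendicular-VI soil line (slope 1.2, intercept 0.04), and MSS-SARVI
substitutes the green band into the blue-band correction because MSS
has no blue band. The registry is data-driven: any entry can be
replaced before evaluation, so a disputed formula can never silently
corrupt the other 42.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the *statistical shape* of a
6-species × 3-degradation-intensity × 8-replicate leaf survey (144
samples, split 64 calibration / 80 validation with a 30-sample
new-index subset, stratified by intensity):

* a smooth green-leaf template (visible floor, green peak near 552 nm,
  chlorophyll well near 680 nm, steep red edge, NIR plateau ≈ 0.45);
* per-nutrient Gaussian absorption features whose depth scales with
  the sample's standardized nutrient value;
* nutrient means shifted monotonically down from light to severe
  degradation, and a small flat albedo increase with degradation
  (degraded, sparser canopies reflect more visible light);
* smooth species-level random curves (low-order cosine series) and
  i.i.d. spectral noise (sd 0.002);
* the full native 325–1075 nm grid, so trimming is always exercised.

Nutrient baselines (N 20 ± 5, P 150 ± 30, K 60 ± 15 mg g⁻¹) are
placeholders chosen to sit in the range implied by the published
equation intercepts; no field distributional summaries stand behind
them. The generator is **not** a radiative-transfer model: it has no
PROSPECT-style leaf optics, no water-absorption features, no
instrument splice artifacts, and its nutrient→spectrum link is a
designed-in Gaussian mechanism. Passing tests on this generator
demonstrate that the pipeline recovers effects of the kind it assumes;
they say nothing about whether real leaf spectra contain such effects.

One consequence worth understanding: because degradation intensity
shifts *both* nutrient means and spectral albedo, the default dataset
contains a real nutrient–spectrum association over and above the
planted features — exactly as a real degradation gradient would. Null
and parameter-recovery experiments in the test-suite therefore zero
the intensity offsets when they need true independence or isolated
planted effects; this is experiment construction, not a change to the
default study conditions.

## Verification experiments and problem sizes

The package's own end-to-end checks run at sizes chosen to make each
property sharp:

* **Type-I calibration.** Ten null datasets (no features, no shared
  intensity factor), families D and ND scanned over 350–500 nm: the
  pooled significant-cell fraction sits at α ± 0.02. Neighbouring
  cells are strongly correlated (adjacent band pairs give nearly
  identical indices), so the per-dataset fraction is far more variable
  than binomial intuition suggests — pooling across ten datasets is
  what makes the check stable.
* **Parameter recovery.** Twenty datasets with three narrow (3 nm sd)
  absorption lines per nutrient at 4× the noise sd, scan over
  350–460 nm with families D, ND, FD, FDD, k = 22: every planted line
  is recovered within ±2 nm, and stepwise models on the selected bands
  reach fit R² ≈ 0.9 with overall p ≪ 0.05. The lines are deliberately
  narrow: a band-level ±2 nm recovery target is only meaningful when
  the planted effect is band-like; wide (≈8 nm sd) features smear
  significance over ~30 nm and make "the" planted band ill-defined.
* **Oracle equivalence.** On ≤10-band toys, the vectorized pair-index
  and correlation engines agree cell-by-cell with nested scalar loops
  to 10⁻¹²; Pearson r/p agree with `cor.test`; the stepwise loop is
  reproduced by an independent RSS-based re-implementation of the same
  greedy rule.

## Known limitations

* Formula fidelity for the 43 empirical indices is to the cited
  literature, not to any single study's private variants.
* The scan's raw-α convention means a full 10-family scan declares
  ~5% of ~4 million null cells significant; sensitive-band counts are
  a ranking device, not an inference.
* Stepwise selection inherits all the known instabilities of greedy
  variable selection; the validation split, not the fit R², is the
  number to trust.
* Full-grid scans hold one n × 651 slice in memory per step and take
  on the order of a minute for 10 families × 3 nutrients at n = 144;
  narrower `scan_window` settings make exploration interactive.
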