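---
title: "Methods: per-cell fluorescence polarization, co-localization and lifetime analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell fluorescence polarization, co-localization and lifetime analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpolcell)
```

# The measurement model

A polarization-resolved confocal microscope splits fluorescence emission
into components parallel (co) and perpendicular (cross) to the excitation
polarization, detected simultaneously on two PMTs and digitized as
registered 8-bit images. The degree of fluorescence polarization per pixel
or per region is

$$\mathrm{Fpol} = \frac{I_{co} - G\,I_{cross}}{I_{co} + G\,I_{cross}},$$

where the G-factor corrects the unequal sensitivity of the two detection
channels. Fpol is a ratio, so it is independent of absolute emission
intensity — the property that makes it usable as a quantitative marker:
methylene blue shows higher Fpol in breast cancer cells than in normal
breast epithelium, driven by dye accumulation in viscous organelle matrices
(mitochondria, lysosomes) and by its shorter excited-state lifetime there.

Assumptions inherited from the acquisition: the two channels are perfectly
registered (simultaneous two-detector acquisition; no registration step is
implemented) and flat-field effects are negligible. No depolarization
correction for high-NA objectives is applied, and the anisotropy variant
$r$ (with $2G I_{cross}$ in the denominator) is deliberately out of scope.

## Thresholding

Before any Fpol arithmetic, pixels are kept only when *both* channels lie
within the inclusive window `[low, high]`, default `[2, 254]` — dropping
dark background (0–1) and saturated (255) pixels. Joint (both-channel)
validity is used because the ratio is corrupted when either channel is
empty or clipped; the threshold bounds are inclusive, matching the usual
image-calculator semantics of keeping the stated limits.

## Per-cell statistics

Per-cell Fpol applies the ratio once to the *mean* intensities of the
compartment's valid pixels (an intensity-weighted estimate), not to the
mean of per-pixel ratios; the two differ under intracellular heterogeneity,
and the mean-intensity protocol is both the conventional one and far more
stable at low counts. The per-pixel alternative remains available
(`method = "pixel_mean"`) for sensitivity analysis. Three compartments are
supported — whole cell, nucleus-excluded, nucleus-only — defined by integer
label masks in which nucleus labels share the owning cell's ID; the
nucleus-excluded and nucleus masks partition the whole-cell mask exactly.

Defaults that matter:

- `min_pixels = 20` valid pixels per compartment (records below this are
  dropped and logged). Chosen to bound the SE of the compartment means at
  8-bit intensities; there is no field-standard value.
- Cells touching the image border are excluded (standard ROI practice).
- Valid-pixel means: thresholded-out pixels inside an ROI are excluded
  from the means, consistent with the thresholding step's purpose.

## G-factor calibration

A homogeneous solution of freely rotating dye in a non-viscous solvent has
Fpol = 0, so $G = \overline{I_{co}} / \overline{I_{cross}}$ over valid
pixels of a reference image pair. The estimate refuses to run on fewer than
100 valid pixels. At typical operating intensities (mean emission ~150 on
the 8-bit scale) and $10^5$ pixels, Poisson photon noise leaves the
estimate well within 1% of truth; 0.75 is used throughout as the realistic
operating value of a two-PMT system.

## Pseudo-colour rendering

Quantitative maps are rendered through a 256-entry monotone LUT (black →
blue → green → yellow → red), black at the low end. The conventional
display range for cellular MB Fpol is 0–0.34; for lifetime maps 0.2–1.0 ns
(blue → red). Values are clamped to the range; invalid pixels render black.
Index mapping rounds half-up, so the midpoint of the range maps to entry
129 of 256 (an even-length LUT has no single middle entry).

# Co-localization

Per cell, co-localization of the dye channel with an organelle channel is
the sample Pearson correlation of paired pixel intensities over the
whole-cell ROI. The whole-cell ROI (rather than an organelle-outlining
sub-ROI) is the reproducible choice and matches the level at which the
synthetic ground truth is defined; raw intensities are used (no background
subtraction). Degenerate inputs — empty/too-small ROI, constant channel —
raise errors rather than returning silent values. Manders/Costes
statistics and 3-D co-localization are out of scope; Pearson's R is the
reported quantity.

# FLIM: bi-exponential reconvolution fitting

TCSPC histograms record photon counts per time bin; the measured decay is
the true decay convolved with the instrument response function (IRF). The
model is

$$m_j = \left[\mathrm{IRF} \circledast \left(a_1 e^{-t/\tau_1} +
a_2 e^{-t/\tau_2}\right)\right]_j + b,$$

with the exponentials *bin-integrated* (the exact integral of the decay
over each bin divided by the bin width) before discrete convolution, which
removes binning bias for lifetimes approaching the bin width — relevant
because the hardware resolves lifetimes down to ~70 ps while a 25 ns /
4096-bin window has 6.1 ps bins. Convolution is FFT-based with zero
padding.

Counts are Poisson, so parameters are estimated by minimizing the Poisson
deviance (maximum likelihood), not unweighted least squares. Optimization
runs in log-parameter space (positivity for lifetimes and amplitudes) with
`nlminb` followed by a Nelder–Mead polish; initialization is deterministic —
τ₂ from a log-linear fit of the decay tail (10%→0.1% of peak), τ₁ from the
early post-peak region (falling back to τ₂/3), amplitudes by a linear
solve at the initial lifetimes — so identical histograms always produce
identical fits. Lifetime ordering τ₁ < τ₂ is enforced by post-hoc sorting
(amplitudes follow), and fits with the two lifetimes within 1% are flagged
as effectively mono-exponential.

When no measured IRF accompanies the histogram, a Gaussian IRF (centre and
FWHM) is fitted jointly with the decay parameters — the minimal-assumption
stand-in for software-reconstructed IRFs; Gaussian is also the synthetic
generator's IRF model.

Goodness of fit is the Neyman-weighted reduced χ²
($\mathrm{var} = \max(\mathrm{count}, 1)$, the convention of TCSPC fitting
software, for comparability with the usual 1–1.5 acceptance gate),
computed over bins whose fitted model counts reach 10, with
dof = bins used − free parameters. The floor matters: in a 25 ns window
most bins are empty tail, and including them deflates the statistic to
meaninglessness; above ~10 expected counts the Neyman weighting is close
to unbiased (its $+3/\lambda$ per-bin bias averages to a few percent over
an exponentially decaying signal, and measured means over replicate
simulations sit near 1.05). The 1–1.5 gate is inclusive; fits with
χ²<sub>red</sub> < 1 are flagged, not auto-rejected, in simulations.

Per-cell lifetimes are fitted from cell-aggregated decays (better photon
statistics than averaging pixel-wise fits); the amplitude-weighted lifetime
$\tau = (a_1\tau_1 + a_2\tau_2)/(a_1 + a_2)$ always lies between the two
components for non-negative amplitudes. Pixel-wise FLIM fitting, phasor
analysis and ≥3-exponential models are out of scope.

# Group statistics

Group summaries are mean ± SE over N cells, with SE = sample-sd/√N (the
n−1 standard deviation, the standard SE-of-the-mean convention). Percent
differences between a cancer and a normal line use the *normal* mean as
denominator — the convention that reproduces all the quoted
cancer-vs-normal ranges from the published per-line means (12–20% whole
cell, 13% smallest nucleus-excluded, 8–14% nuclei) — with half-up rounding
to integer percent for display and the unrounded value retained. One known
irreproducibility is documented rather than reconciled: the quoted 22%
upper bound for nucleus-excluded differences is not obtainable from the
published means under any plain percent-difference convention
((24.24−20.21)/20.21 ≈ 20%).

Repeated observations within an imaging session are correlated, so naive
cell-level tests overstate significance. Instead of a mixed-effects linear
model — whose covariance structure and estimation details would be
assumptions of ours, not testable properties — significance comes from a
hierarchical permutation test, exactly implementable and checkable for
type-I error:

- groups sharing experiment IDs (each session measured both groups):
  group labels permute among cells *within* each experiment;
- disjoint experiments: whole experiments are reassigned to groups;
- fewer than 2 experiments per group: cell-level permutation with an
  explicit pseudo-replication warning.

The statistic is the difference of group means; p-values use the add-one
correction, so they are never 0 and never below 1/(B+1), with B = 10⁴ by
default. A random-intercept model (`compare_groups_lmm`, via lme4) is
offered as an optional cross-check, not as the validated surface. No
multiple-testing correction is applied across compartments (none is
reported in this literature for this design).

# The synthetic-data generator

The generator exists so that every downstream stage has known ground
truth; its defaults are the study conditions the analyses are validated
under.

**Polarized fields.** Cells are non-overlapping ellipses (random semi-axes
within `cell_axes_px`, random orientation) with concentric elliptical
nuclei (`nucleus_fraction = 0.5` of the cell's semi-axes). Shape realism is
irrelevant to the statistics under test; ellipses give exact analytic
ground truth. For target polarization $P$ and per-compartment mean
emission $k$ (`total_intensity`, default 150 of 255 — a bright but
unsaturated working range), the construction inverts the Fpol ratio:
$I_{co} = \tfrac{k}{2}(1+P)$, $I_{cross} = \tfrac{k}{2}(1-P)/G$, so the
analysis run with the same $G$ returns $P$ exactly before noise. Defaults
$P_{nucleus} = 0.24$, $P_{cytoplasm} = 0.20$ mirror the observed
normal-cell heterogeneity (nuclei higher). Noise is applied independently
per channel (independent PMTs): Poisson by default — no photon budget is
published for the instrument, so shot-noise at the stated intensity scale
is the defensible minimal model — then quantization (round-half-up, clip
to [0, 255]). Infeasible packings error out rather than overlap. No PSF,
confocal sectioning or spectral bleed-through is simulated: passing tests
demonstrate correctness of the *statistics*, not robustness to optical
blur or segmentation error on real images.

**Co-localization stacks.** Each cell gets `puncta_per_cell = 6` organelle
puncta (radius 2 px) outside the nucleus; `co_occupancy` ∈ [0, 1] is the
fraction of the cell's dye signal budget placed on puncta, the remainder
spread over non-puncta cell pixels. Consequently the noiseless endpoints
are exact (R = 1 at occupancy 1; disjoint supports, hence R ≤ 0, at 0) and
the Poisson-noise group-mean R increases strictly with occupancy — the
property the analyses are tested against. The negative noiseless endpoint
is a deliberate consequence of keeping the endpoints exact; real diffuse
dye would overlay puncta and push the no-co-localization endpoint toward 0
from below.

**Decays.** Expected counts are the same reconvolution model the fitter
uses mathematically, but generated by an independent code path
(construction by forward model; fitting by optimization), with the
amplitude scale set so expected signal photons equal `n_photons` (default
10⁶, a realistic cell-aggregate TCSPC budget) and Poisson sampling per
bin. Defaults: 25 ns window, 4096 bins (6.1 ps binning, supporting sub-100
ps lifetimes), Gaussian IRF of 0.12 ns FWHM centred at 2 ns, zero
background. Windows shorter than 5·τ₂ trigger a truncation warning.

All generators take a mandatory integer seed and are bit-reproducible:
identical spec + seed ⇒ identical outputs, including file checksums in
`simulate_fixture()` manifests.

# Problem sizes used in the test suite

The suite favours a few deep parameterised checks per operation. Sizes
were chosen to make the Monte-Carlo assertions sharp (2·SE bands) while
keeping a full run on one CPU near a minute: unbiasedness of per-cell Fpol
uses a 200-cell field (860² px) and the compartment-recovery and
acceptance checks 100-cell fields (640² px); co-occupancy monotonicity
uses 40 cells per grid level (15 per level in the fast unit variant);
lifetime recovery uses 10⁶-photon decays — 20 replicate fits at the
cancer-cell lifetimes, an 8-case grid across τ₁ ∈ {0.2, 0.3},
τ₂ ∈ {0.7, 1.0}, a₁/a₂ ∈ {0.5, 2} — and χ² calibration 8 replicate fits;
the permutation test's type-I error uses 200 null simulations at B = 199
and its power 40 simulations at B = 1999 with N = 100 cells per group over
5 shared experiments (between-experiment sd 0.005, within 0.015, shift
0.03 — the nucleus-excluded cancer/normal contrast scale).

# Known limitations

- Segmentation is an input; the package validates statistics given masks,
  not mask quality. No automated nucleus detection is provided.
- The Fpol ↔ lifetime relationship is represented only through the
  parameter values of the synthetic conditions, not modelled physically
  (no Perrin-equation coupling between the modules).
- The permutation test assumes exchangeability at the level it permutes;
  strong experiment-by-group interactions in a disjoint design reduce to
  only `choose(n_exp, k)` distinct relabellings, limiting attainable
  p-values.
- 8-bit quantization bounds Fpol accuracy at roughly ±0.01 per pixel;
  claims below that resolution are not made anywhere in the package.
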