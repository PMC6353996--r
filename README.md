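# fpolcell

Per-cell quantitative analysis of fluorescence polarization (Fpol) imaging,
dye–organelle co-localization and fluorescence lifetime (FLIM) data, built
around the use of methylene blue (MB) Fpol as a single-cell marker that
separates breast cancer cells from normal breast epithelial cells.

## Who this is for

Groups doing quantitative fluorescence microscopy of live cells with a
polarization-resolved detection path (two detectors behind a polarizing beam
splitter), and anyone who needs a tested, scriptable replacement for the
usual ImageJ/MetaMorph click-through for:

- G-factor corrected, pixel-wise Fpol maps with background/saturation
  thresholding and pseudo-colour rendering;
- per-cell Fpol statistics by compartment (whole cell, nucleus-excluded,
  nucleus-only) from label masks;
- G-factor calibration against a zero-polarization dye solution;
- Pearson co-localization of a dye channel with organelle trackers per cell;
- bi-exponential reconvolution fitting of TCSPC photon decays with
  amplitude-weighted lifetimes and a reduced-χ² acceptance gate;
- group summaries (mean ± SE over N cells), cancer-vs-normal percent
  differences, and a hierarchical permutation test that respects the
  experiment/replicate structure.

Every stage can be exercised end to end on synthetic microscopy data with
known ground truth (`generate_polarized_pair()`, `generate_coloc_stack()`,
`generate_decay()`), so the whole pipeline is testable without any
instrument data.

## The quantities

For registered co- and cross-polarized 8-bit images I<sub>co</sub>,
I<sub>cross</sub> and instrument G-factor G,

    Fpol = (I_co − G·I_cross) / (I_co + G·I_cross)

computed after thresholding both channels to [2, 254] (drop background and
saturated pixels). Per cell, the mean I<sub>co</sub> and I<sub>cross</sub>
over the compartment's valid pixels are formed first and the ratio applied
once to the means. The G-factor comes from a homogeneous zero-polarization
reference, where G = mean(I_co)/mean(I_cross).

TCSPC decays are fitted by Poisson maximum likelihood with the
reconvolution model IRF ⊛ (a₁·e^(−t/τ₁) + a₂·e^(−t/τ₂)) + background, and
summarized by the amplitude-weighted lifetime

    τ = (a1·τ1 + a2·τ2) / (a1 + a2),

with fits gated on reduced χ² ∈ [1, 1.5].

## Worked example

Simulate a cancer-like and a normal-like field (Poisson photon noise),
calibrate G from a synthetic zero-Fpol reference, and compare
nucleus-excluded per-cell Fpol:

```r
library(fpolcell)

spec_cancer <- cell_field_spec(n_cells = 12, fpol_nucleus = 0.254,
                               fpol_cytoplasm = 0.239,
                               noise_model = "poisson", seed = 101)
spec_normal <- cell_field_spec(n_cells = 12, fpol_nucleus = 0.235,
                               fpol_cytoplasm = 0.202,
                               noise_model = "poisson", seed = 202)
fc <- generate_polarized_pair(spec_cancer)
fn <- generate_polarized_pair(spec_normal)

g <- calibrate_g(generate_reference_pair(g_factor = 0.75, seed = 7))
#> <g_factor> 0.750179 (calibrated)

rc <- cell_fpol(fc$pair, fc$labels, g, compartment = "excl_nucleus")
rn <- cell_fpol(fn$pair, fn$labels, g, compartment = "excl_nucleus")
records <- data.frame(
  group = rep(c("cancer_like", "normal_like"), c(nrow(rc), nrow(rn))),
  experiment_id = "e1",
  value = c(rc$fpol, rn$fpol)
)
summarize_cells(records)
#>         group n_cells      mean           se
#> 1 cancer_like      12 0.2395316 0.0013725914
#> 2 normal_like      12 0.2025657 0.0007778532

compare_groups(rc$fpol, rn$fpol, n_perm = 9999, seed = 1)
#> <pairwise_comparison> diff = 0.03697 (18.2%), p = 0.0001 [cell_permutation, B = 9999]
```

The recovered group means sit on the prescribed cytoplasmic ground truths
(0.239 and 0.202) within one to two SE, and the 18% relative difference is
the cancer-vs-normal contrast scale this compartment is expected to show.
(With a single synthetic "experiment" the test warns about
pseudo-replication and permutes at cell level; pass real `experiments_a/b`
IDs to get the hierarchical test.)

Fit one synthetic TCSPC decay generated at cancer-cell lifetimes
(τ₁ = 0.266 ns, τ₂ = 0.751 ns, a₁/a₂ = 1.5, 10⁶ photons, 0.12 ns IRF):

```r
h <- generate_decay(decay_spec(tau1 = 0.266, tau2 = 0.751, a1 = 1.5, a2 = 1,
                               seed = 42))
fit_biexponential(h)
#> <biexp_fit> tau1 = 0.267 ns, tau2 = 0.755 ns, a1/a2 = 1.543,
#>             tau_amp = 0.459 ns, chi2_red = 1.020 (accepted)
```

Both lifetimes come back within 0.6% and the fit passes the χ² gate.

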