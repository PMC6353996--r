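test_that("noiseless generation inverts the Fpol ratio up to quantization", {
  sp <- small_field_spec(fpol_nucleus = 0.24, fpol_cytoplasm = 0.20)
  f <- generate_polarized_pair(sp)
  rec <- suppressWarnings(cell_fpol_all(f$pair, f$labels, sp$g_factor))
  truth <- f$truth
  m <- merge(rec, truth, by = c("cell_id", "compartment"))
  expect_gt(nrow(m), 0)
  expect_true(all(abs(m$fpol - m$true_fpol) <= 0.01))
  # zero-polarization spec: I_co = G * I_cross up to quantization
  spz <- small_field_spec(fpol_nucleus = 0, fpol_cytoplasm = 0, seed = 2)
  fz <- generate_polarized_pair(spz)
  inside <- fz$labels$cell_labels > 0
  expect_true(all(abs(fz$pair$co[inside] -
                        spz$g_factor * fz$pair$cross[inside]) <= 1))
})

test_that("generated images and masks satisfy the format invariants", {
  sp <- small_field_spec(noise_model = "poisson", seed = 3)
  f <- generate_polarized_pair(sp)
  for (ch in list(f$pair$co, f$pair$cross)) {
    expect_true(min(ch) >= 0 && max(ch) <= 255)
    expect_true(all(ch == floor(ch)))
  }
  lab <- f$labels
  expect_true(min(lab$cell_labels) >= 0)
  # nucleus pixels sit inside the owning cell (same ID)
  nz <- lab$nucleus_labels > 0
  expect_true(all(lab$cell_labels[nz] == lab$nucleus_labels[nz]))
  # cells are disjoint by construction: per-cell masks never overlap, and
  # every prescribed cell is present
  expect_setequal(unique(as.vector(lab$cell_labels[lab$cell_labels > 0])),
                  seq_len(sp$n_cells))
})

test_that("generation is deterministic in the seed and spec", {
  sp <- small_field_spec(noise_model = "poisson", seed = 11)
  f1 <- generate_polarized_pair(sp)
  f2 <- generate_polarized_pair(sp)
  expect_identical(f1$pair$co, f2$pair$co)
  expect_identical(f1$pair$cross, f2$pair$cross)
  expect_identical(f1$labels, f2$labels)
  d1 <- generate_decay(fast_decay_spec(seed = 11))
  d2 <- generate_decay(fast_decay_spec(seed = 11))
  expect_identical(d1$counts, d2$counts)
  c1 <- generate_coloc_stack(small_coloc_spec(seed = 11))
  c2 <- generate_coloc_stack(small_coloc_spec(seed = 11))
  expect_identical(c1$stack, c2$stack)
})

test_that("infeasible cell packings error instead of overlapping", {
  expect_error(
    generate_polarized_pair(cell_field_spec(
      image_shape = c(64L, 64L), n_cells = 60L, cell_axes_px = c(8, 10),
      noise_model = "none", seed = 1
    )),
    "non-overlapping|too large"
  )
})

test_that("per-cell Fpol estimates are unbiased under Poisson noise", {
  # Monte-Carlo over ~200 cells establishes the SE of the cell mean
  sp <- cell_field_spec(
    image_shape = c(860L, 860L), n_cells = 200L, cell_axes_px = c(7, 11),
    total_intensity = 150, noise_model = "poisson", seed = 1
  )
  f <- generate_polarized_pair(sp)
  rec <- suppressWarnings(cell_fpol(f$pair, f$labels, sp$g_factor,
                                    compartment = "whole_cell"))
  truth <- f$truth[f$truth$compartment == "whole_cell", ]
  m <- merge(rec, truth, by = "cell_id")
  expect_gte(nrow(m), 190)
  err <- mean(m$fpol) - mean(m$true_fpol)
  se <- sd(m$fpol) / sqrt(nrow(m))
  expect_lt(abs(err), 2 * se)
})

test_that("decay generation conserves photons and the mono-exponential slope", {
  # Poisson conservation of the photon budget
  h <- generate_decay(decay_spec(n_photons = 1e6, seed = 11))
  expect_lt(abs(sum(h$counts) - 1e6), 3 * sqrt(1e6))
  # near-delta IRF, single component, no background: log-counts linear in t
  # with slope -1/tau1
  hm <- generate_decay(decay_spec(
    tau1 = 0.5, tau2 = 5, a1 = 1, a2 = 0, window_ns = 30, n_bins = 512L,
    irf_fwhm_ns = 1e-6, irf_center_ns = 0.5, n_photons = 5e6, seed = 2
  ))
  t_mid <- (seq_along(hm$counts) - 0.5) * hm$bin_width_ns
  use <- t_mid > 1 & t_mid < 3 & hm$counts > 0
  fit <- lm(log(hm$counts[use]) ~ t_mid[use])
  expect_lt(abs(-1 / coef(fit)[[2]] - 0.5), 0.01)
  # truncated windows are flagged
  expect_warning(
    generate_decay(fast_decay_spec(tau1 = 0.5, tau2 = 6, window_ns = 20)),
    "truncation"
  )
})

test_that("coloc stack endpoints give perfect and non-positive correlation", {
  g1 <- generate_coloc_stack(small_coloc_spec(co_occupancy = 1,
                                              noise_model = "none"))
  t1 <- suppressWarnings(
    coloc_table(g1$stack, g1$labels, c(mitochondria = "organelle"))
  )
  expect_true(all(t1$pearson_r > 1 - 1e-12))
  g0 <- generate_coloc_stack(small_coloc_spec(co_occupancy = 0,
                                              noise_model = "none"))
  t0 <- suppressWarnings(
    coloc_table(g0$stack, g0$labels, c(mitochondria = "organelle"))
  )
  expect_true(all(t0$pearson_r <= 0))
})

test_that("synthetic specs round-trip through YAML", {
  dir <- withr::local_tempdir()
  for (sp in list(small_field_spec(seed = 7),
                  small_coloc_spec(seed = 7),
                  fast_decay_spec(seed = 7))) {
    p <- file.path(dir, "spec.yaml")
    write_spec_yaml(sp, p)
    sp2 <- read_spec_yaml(p)
    expect_equal(sp2, sp)
  }
})
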