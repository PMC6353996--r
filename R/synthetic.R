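#' Specification of a synthetic polarized cell field
#'
#' Describes a field of non-overlapping elliptical cells, each with an
#' elliptical nucleus, carrying prescribed ground-truth fluorescence
#' polarization per compartment. The generated co/cross channel pair inverts
#' the Fpol ratio: for target polarization `P`, total emission `k` and
#' G-factor `G`, pixel intensities are set to `I_co = k/2 * (1 + P)` and
#' `I_cross = k/2 * (1 - P) / G`, so that the analysis pipeline run with the
#' same `G` recovers `P` exactly before noise and quantization.
#'
#' @param image_shape Integer `(height, width)` in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_axes_px Range `(min, max)` of ellipse semi-axes in pixels.
#' @param nucleus_fraction Nucleus semi-axes relative to the cell's, in (0, 1).
#' @param fpol_nucleus,fpol_cytoplasm Ground-truth Fpol per compartment,
#'   in `[0, 1)`.
#' @param total_intensity Mean emission (`I_co + G * I_cross`) per compartment
#'   on the 8-bit scale; either a single value or `(nucleus, cytoplasm)`.
#' @param g_factor G-factor used to construct the cross channel.
#' @param noise_model `"none"`, `"poisson"`, or `list(type = "gaussian", sd = )`.
#' @param seed Integer RNG seed (mandatory; generation is deterministic).
#' @return A `cell_field_spec` list.
#' @export
cell_field_spec <- function(image_shape = c(256L, 256L),
                            n_cells = 12L,
                            cell_axes_px = c(9, 14),
                            nucleus_fraction = 0.5,
                            fpol_nucleus = 0.24,
                            fpol_cytoplasm = 0.20,
                            total_intensity = 150,
                            g_factor = 0.75,
                            noise_model = "poisson",
                            seed = 1L) {
  stopifnot(
    length(image_shape) == 2L, all(image_shape >= 16),
    n_cells >= 1, length(cell_axes_px) == 2L,
    cell_axes_px[1] >= 2, cell_axes_px[2] >= cell_axes_px[1],
    nucleus_fraction > 0, nucleus_fraction < 1,
    fpol_nucleus >= 0, fpol_nucleus < 1,
    fpol_cytoplasm >= 0, fpol_cytoplasm < 1,
    all(total_intensity > 0), g_factor > 0
  )
  if (length(total_intensity) == 1L) {
    total_intensity <- rep(total_intensity, 2L)
  }
  structure(
    list(
      image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
      cell_axes_px = cell_axes_px, nucleus_fraction = nucleus_fraction,
      fpol_nucleus = fpol_nucleus, fpol_cytoplasm = fpol_cytoplasm,
      total_intensity = total_intensity, g_factor = g_factor,
      noise_model = normalize_noise_model(noise_model), seed = as.integer(seed)
    ),
    class = "cell_field_spec"
  )
}

normalize_noise_model <- function(noise_model) {
  if (is.character(noise_model)) {
    noise_model <- list(type = match.arg(noise_model, c("none", "poisson")))
  }
  stopifnot(is.list(noise_model),
            noise_model$type %in% c("none", "poisson", "gaussian"))
  if (noise_model$type == "gaussian" &&
      (is.null(noise_model$sd) || noise_model$sd < 0)) {
    stop("gaussian noise model requires a non-negative sd")
  }
  noise_model
}

apply_noise <- function(x, noise_model) {
  switch(noise_model$type,
    none = x,
    poisson = matrix(stats::rpois(length(x), lambda = x), nrow(x)),
    gaussian = x + matrix(stats::rnorm(length(x), sd = noise_model$sd), nrow(x))
  )
}

# Round half up and clip to the 8-bit range.
quantize_8bit <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

# Rasterize an ellipse: logical matrix of pixels whose centres fall inside.
ellipse_mask <- function(shape, cy, cx, ry, rx, theta = 0) {
  y <- matrix(seq_len(shape[1]), shape[1], shape[2]) - cy
  x <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1]) - cx
  u <- y * cos(theta) + x * sin(theta)
  v <- -y * sin(theta) + x * cos(theta)
  (u / ry)^2 + (v / rx)^2 <= 1
}

# Place n non-overlapping ellipses fully inside the image (1 px border
# margin so border-exclusion downstream drops nothing). Errors when the
# requested packing is infeasible rather than silently overlapping cells.
place_cells <- function(shape, n_cells, axes_range, max_attempts = 2000L) {
  cells <- vector("list", n_cells)
  placed <- 0L
  attempts <- 0L
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d non-overlapping cells of semi-axes [%g, %g] in a %d x %d image",
        n_cells, axes_range[1], axes_range[2], shape[1], shape[2]
      ))
    }
    ry <- stats::runif(1, axes_range[1], axes_range[2])
    rx <- stats::runif(1, axes_range[1], axes_range[2])
    rmax <- max(ry, rx)
    if (2 * rmax + 4 > min(shape)) {
      stop("cell semi-axes too large for the image")
    }
    cy <- stats::runif(1, rmax + 2, shape[1] - rmax - 1)
    cx <- stats::runif(1, rmax + 2, shape[2] - rmax - 1)
    ok <- TRUE
    if (placed > 0L) {
      for (c0 in cells[seq_len(placed)]) {
        if ((cy - c0$cy)^2 + (cx - c0$cx)^2 < (rmax + c0$rmax + 1.5)^2) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      placed <- placed + 1L
      cells[[placed]] <- list(
        cy = cy, cx = cx, ry = ry, rx = rx,
        theta = stats::runif(1, 0, pi), rmax = rmax
      )
    }
  }
  cells
}

#' Segmentation label masks
#'
#' Integer label images defining per-cell regions of interest: `cell_labels`
#' assigns each cell's pixels its positive integer ID (0 = background) and
#' `nucleus_labels` marks nucleus pixels with the ID of the owning cell.
#'
#' @param cell_labels,nucleus_labels Integer matrices of identical shape.
#' @return A `segmentation_labels` object.
#' @export
segmentation_labels <- function(cell_labels, nucleus_labels) {
  cell_labels <- as.matrix(cell_labels)
  nucleus_labels <- as.matrix(nucleus_labels)
  stopifnot(identical(dim(cell_labels), dim(nucleus_labels)))
  if (min(cell_labels) < 0 || min(nucleus_labels) < 0) {
    stop("label masks must be non-negative integers")
  }
  orphan <- nucleus_labels > 0 & nucleus_labels != cell_labels
  if (any(orphan)) {
    stop("every nucleus pixel must lie inside the cell with the same ID")
  }
  structure(
    list(
      cell_labels = matrix(as.integer(cell_labels), nrow(cell_labels)),
      nucleus_labels = matrix(as.integer(nucleus_labels), nrow(nucleus_labels))
    ),
    class = "segmentation_labels"
  )
}

#' Generate a synthetic co/cross polarized image pair with ground truth
#'
#' Builds the field described by a [cell_field_spec()]: intensity pair per
#' pixel from the inverse Fpol construction, per-channel noise, 8-bit
#' quantization, plus label masks and a ground-truth table of prescribed
#' per-compartment Fpol.
#'
#' @param spec A [cell_field_spec()].
#' @return List with `pair` ([polarized_pair()]), `labels`
#'   ([segmentation_labels()]), and `truth` (data.frame with `cell_id`,
#'   `compartment`, `true_fpol`; the `whole_cell` truth is the Fpol of the
#'   area-weighted compartment mean intensities).
#' @export
generate_polarized_pair <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  cells <- place_cells(shape, spec$n_cells, spec$cell_axes_px)

  cell_lab <- matrix(0L, shape[1], shape[2])
  nuc_lab <- matrix(0L, shape[1], shape[2])
  co <- matrix(0, shape[1], shape[2])
  cross <- matrix(0, shape[1], shape[2])
  g <- spec$g_factor
  truth <- vector("list", spec$n_cells)

  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    cmask <- ellipse_mask(shape, cc$cy, cc$cx, cc$ry, cc$rx, cc$theta)
    nmask <- ellipse_mask(
      shape, cc$cy, cc$cx,
      cc$ry * spec$nucleus_fraction, cc$rx * spec$nucleus_fraction, cc$theta
    ) & cmask
    cyto <- cmask & !nmask
    cell_lab[cmask] <- i
    nuc_lab[nmask] <- i

    k_nuc <- spec$total_intensity[1] / 2
    k_cyt <- spec$total_intensity[2] / 2
    co[nmask] <- k_nuc * (1 + spec$fpol_nucleus)
    cross[nmask] <- k_nuc * (1 - spec$fpol_nucleus) / g
    co[cyto] <- k_cyt * (1 + spec$fpol_cytoplasm)
    cross[cyto] <- k_cyt * (1 - spec$fpol_cytoplasm) / g

    n_n <- sum(nmask)
    n_c <- sum(cyto)
    m_co <- (n_n * k_nuc * (1 + spec$fpol_nucleus) +
               n_c * k_cyt * (1 + spec$fpol_cytoplasm)) / (n_n + n_c)
    m_cr <- (n_n * k_nuc * (1 - spec$fpol_nucleus) +
               n_c * k_cyt * (1 - spec$fpol_cytoplasm)) / (g * (n_n + n_c))
    truth[[i]] <- data.frame(
      cell_id = i,
      compartment = c("whole_cell", "excl_nucleus", "nucleus"),
      true_fpol = c(
        (m_co - g * m_cr) / (m_co + g * m_cr),
        spec$fpol_cytoplasm, spec$fpol_nucleus
      )
    )
  }

  co <- quantize_8bit(apply_noise(co, spec$noise_model))
  cross <- quantize_8bit(apply_noise(cross, spec$noise_model))

  list(
    pair = polarized_pair(co, cross),
    labels = segmentation_labels(cell_lab, nuc_lab),
    truth = do.call(rbind, truth)
  )
}

#' Generate a homogeneous calibration reference pair
#'
#' Emulates imaging a homogeneous dye solution of known polarization — the
#' input of G-factor calibration. A freely rotating dye in a non-viscous
#' solvent has `fpol = 0`, for which the construction gives
#' `I_co = G * I_cross` everywhere before noise and quantization.
#'
#' @param image_shape Integer `(height, width)` pixels.
#' @param total_intensity Mean emission (`I_co + G * I_cross`) on the 8-bit
#'   scale.
#' @param fpol True polarization of the solution (0 for the standard
#'   reference).
#' @param g_factor G-factor of the emulated instrument.
#' @param noise_model As in [cell_field_spec()].
#' @param seed Integer RNG seed.
#' @return A [polarized_pair()].
#' @export
generate_reference_pair <- function(image_shape = c(320L, 320L),
                                    total_intensity = 150,
                                    fpol = 0, g_factor = 0.75,
                                    noise_model = "poisson", seed = 1L) {
  stopifnot(fpol >= 0, fpol < 1, total_intensity > 0, g_factor > 0)
  noise_model <- normalize_noise_model(noise_model)
  set.seed(as.integer(seed))
  k <- total_intensity / 2
  co <- matrix(k * (1 + fpol), image_shape[1], image_shape[2])
  cross <- matrix(k * (1 - fpol) / g_factor, image_shape[1], image_shape[2])
  polarized_pair(
    quantize_8bit(apply_noise(co, noise_model)),
    quantize_8bit(apply_noise(cross, noise_model))
  )
}

#' Specification of a synthetic co-localization field
#'
#' Describes cells containing punctate organelles and a dye channel whose
#' signal budget is split between the puncta and the rest of the cell:
#' `co_occupancy` is the fraction of dye signal placed on organelle puncta
#' (the remainder goes to non-puncta cell pixels), so expected per-cell
#' Pearson correlation between the dye and organelle channels increases
#' monotonically with `co_occupancy`, from negative/near-zero at 0 to 1 at 1.
#'
#' @param image_shape Integer `(height, width)` pixels.
#' @param n_cells Number of cells.
#' @param puncta_per_cell Organelle puncta per cell.
#' @param puncta_radius_px Punctum radius in pixels.
#' @param co_occupancy Fraction of dye signal on puncta, in `[0, 1]`.
#' @param background_level Constant background added to every channel (8-bit
#'   scale).
#' @param signal_budget Total dye signal per cell distributed over its pixels.
#' @param noise_model As in [cell_field_spec()].
#' @param seed Integer RNG seed.
#' @return A `coloc_field_spec` list.
#' @export
coloc_field_spec <- function(image_shape = c(256L, 256L),
                             n_cells = 10L,
                             puncta_per_cell = 6L,
                             puncta_radius_px = 2,
                             co_occupancy = 0.5,
                             background_level = 5,
                             signal_budget = 12000,
                             noise_model = "poisson",
                             seed = 1L) {
  stopifnot(
    length(image_shape) == 2L, n_cells >= 1, puncta_per_cell >= 1,
    puncta_radius_px >= 1, co_occupancy >= 0, co_occupancy <= 1,
    background_level >= 0, signal_budget > 0
  )
  structure(
    list(
      image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
      puncta_per_cell = as.integer(puncta_per_cell),
      puncta_radius_px = puncta_radius_px, co_occupancy = co_occupancy,
      background_level = background_level, signal_budget = signal_budget,
      noise_model = normalize_noise_model(noise_model), seed = as.integer(seed)
    ),
    class = "coloc_field_spec"
  )
}

#' Generate a synthetic dye/organelle/nucleus channel stack
#'
#' @param spec A [coloc_field_spec()].
#' @return List with `stack` (list of 8-bit matrices `mb`, `organelle`,
#'   `nucleus`), `labels` ([segmentation_labels()]) and `truth` (data.frame
#'   `cell_id`, `co_occupancy`).
#' @export
generate_coloc_stack <- function(spec) {
  stopifnot(inherits(spec, "coloc_field_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  cells <- place_cells(shape, spec$n_cells, c(10, 15))

  cell_lab <- matrix(0L, shape[1], shape[2])
  nuc_lab <- matrix(0L, shape[1], shape[2])
  mb <- matrix(spec$background_level, shape[1], shape[2])
  org <- matrix(spec$background_level, shape[1], shape[2])
  nuc_ch <- matrix(spec$background_level, shape[1], shape[2])
  occ <- spec$co_occupancy

  for (i in seq_along(cells)) {
    cc <- cells[[i]]
    cmask <- ellipse_mask(shape, cc$cy, cc$cx, cc$ry, cc$rx, cc$theta)
    nmask <- ellipse_mask(shape, cc$cy, cc$cx, cc$ry * 0.45, cc$rx * 0.45,
                          cc$theta) & cmask
    cell_lab[cmask] <- i
    nuc_lab[nmask] <- i
    nuc_ch[nmask] <- nuc_ch[nmask] + 120

    # puncta centres inside the cell, outside the nucleus, within bounds
    pmask <- matrix(FALSE, shape[1], shape[2])
    placed <- 0L
    tries <- 0L
    while (placed < spec$puncta_per_cell && tries < 500L) {
      tries <- tries + 1L
      py <- stats::runif(1, cc$cy - cc$ry, cc$cy + cc$ry)
      px <- stats::runif(1, cc$cx - cc$rx, cc$cx + cc$rx)
      yi <- round(py)
      xi <- round(px)
      if (yi < 1 || xi < 1 || yi > shape[1] || xi > shape[2]) next
      if (!cmask[yi, xi] || nmask[yi, xi]) next
      pm <- ellipse_mask(shape, py, px, spec$puncta_radius_px,
                         spec$puncta_radius_px) & cmask
      if (!any(pm)) next
      pmask <- pmask | pm
      placed <- placed + 1L
    }
    if (placed < spec$puncta_per_cell) {
      stop("could not place the requested puncta inside a cell")
    }
    org[pmask] <- org[pmask] + 150

    n_p <- sum(pmask)
    n_o <- sum(cmask & !pmask)
    mb[pmask] <- mb[pmask] + occ * spec$signal_budget / n_p
    mb[cmask & !pmask] <- mb[cmask & !pmask] +
      (1 - occ) * spec$signal_budget / n_o
  }

  stack <- lapply(
    list(mb = mb, organelle = org, nucleus = nuc_ch),
    function(ch) quantize_8bit(apply_noise(ch, spec$noise_model))
  )
  list(
    stack = stack,
    labels = segmentation_labels(cell_lab, nuc_lab),
    truth = data.frame(cell_id = seq_along(cells), co_occupancy = occ)
  )
}

#' Specification of a synthetic TCSPC photon decay
#'
#' Bi-exponential fluorescence decay convolved with a Gaussian instrument
#' response function (IRF) and sampled with Poisson photon noise, emulating a
#' time-correlated single photon counting histogram.
#'
#' @param tau1,tau2 Lifetimes in ns, `tau1 < tau2` by convention.
#' @param a1,a2 Non-negative component amplitudes (only their ratio matters;
#'   the total is rescaled to `n_photons`).
#' @param window_ns Total time range of the histogram in ns.
#' @param n_bins Number of time bins (>= 64).
#' @param irf_fwhm_ns Gaussian IRF full width at half maximum in ns.
#' @param irf_center_ns IRF centre (excitation instant) in ns.
#' @param n_photons Expected total signal photons.
#' @param background_rate Flat background in counts per bin.
#' @param seed Integer RNG seed.
#' @return A `decay_spec` list.
#' @export
decay_spec <- function(tau1 = 0.3, tau2 = 0.9, a1 = 1.5, a2 = 1,
                       window_ns = 25, n_bins = 4096L,
                       irf_fwhm_ns = 0.12, irf_center_ns = 2,
                       n_photons = 1e6, background_rate = 0, seed = 1L) {
  stopifnot(
    tau1 > 0, tau2 > 0, a1 >= 0, a2 >= 0, a1 + a2 > 0,
    window_ns > 0, n_bins >= 64L, irf_fwhm_ns >= 0,
    irf_center_ns >= 0, n_photons > 0, background_rate >= 0
  )
  if (tau1 >= tau2) stop("decay_spec requires tau1 < tau2")
  structure(
    list(
      tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2, window_ns = window_ns,
      n_bins = as.integer(n_bins), irf_fwhm_ns = irf_fwhm_ns,
      irf_center_ns = irf_center_ns, n_photons = n_photons,
      background_rate = background_rate, seed = as.integer(seed)
    ),
    class = "decay_spec"
  )
}

# Gaussian IRF discretized on the bin grid, normalized to unit sum.
gaussian_irf <- function(n_bins, bin_width, center_ns, fwhm_ns) {
  t_mid <- (seq_len(n_bins) - 0.5) * bin_width
  delta <- function() {
    irf <- numeric(n_bins)
    irf[which.min(abs(t_mid - center_ns))] <- 1
    irf
  }
  if (fwhm_ns <= 0) return(delta())
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  irf <- stats::dnorm(t_mid, mean = center_ns, sd = sigma)
  # an IRF much narrower than the binning underflows; treat it as a delta
  if (!any(irf > 0)) return(delta())
  irf / sum(irf)
}

#' Generate a synthetic TCSPC decay histogram
#'
#' Expected counts are the discrete convolution of the normalized IRF with
#' the bin-integrated bi-exponential decay, scaled so the expected signal
#' total equals `n_photons`, plus the flat background; observed counts are
#' Poisson draws from that model.
#'
#' @param spec A [decay_spec()].
#' @return A [decay_histogram()] with attributes `truth` (the spec) and
#'   `expected` (the noiseless model).
#' @export
generate_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  if (spec$window_ns < 5 * spec$tau2) {
    warning("window_ns < 5 * tau2: decay truncation will bias lifetimes")
  }
  set.seed(spec$seed)
  dt <- spec$window_ns / spec$n_bins
  irf <- gaussian_irf(spec$n_bins, dt, spec$irf_center_ns, spec$irf_fwhm_ns)
  scale <- spec$n_photons * dt / (spec$a1 * spec$tau1 + spec$a2 * spec$tau2)
  model <- biexp_model_counts(
    tau1 = spec$tau1, tau2 = spec$tau2,
    a1 = scale * spec$a1, a2 = scale * spec$a2,
    background = spec$background_rate,
    irf = irf, n_bins = spec$n_bins, bin_width = dt
  )
  counts <- stats::rpois(spec$n_bins, model)
  hist <- decay_histogram(counts, bin_width_ns = dt, irf = irf)
  attr(hist, "truth") <- spec
  attr(hist, "expected") <- model
  hist
}
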