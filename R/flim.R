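#' TCSPC decay histogram
#'
#' Photon counts per time bin together with the instrument response function
#' (IRF) sampled on the same binning.
#'
#' @param counts Non-negative integer counts per bin.
#' @param bin_width_ns Bin width in ns.
#' @param t0_ns Time offset of the first bin edge in ns.
#' @param irf Non-negative IRF values per bin (same length as `counts`); it
#'   is normalized to unit sum internally.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(counts, bin_width_ns, t0_ns = 0, irf = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(bin_width_ns > 0)
  if (!is.null(irf)) {
    irf <- as.numeric(irf)
    if (length(irf) != length(counts)) {
      stop("irf must have the same number of bins as counts")
    }
    if (any(irf < 0) || sum(irf) <= 0) {
      stop("irf must be non-negative with a positive sum")
    }
    irf <- irf / sum(irf)
  }
  structure(
    list(counts = counts, bin_width_ns = bin_width_ns, t0_ns = t0_ns,
         irf = irf),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "<decay_histogram> %d bins x %.4g ns, %d counts, IRF %s\n",
    length(x$counts), x$bin_width_ns, sum(x$counts),
    if (is.null(x$irf)) "absent" else "measured"
  ))
  invisible(x)
}

# Bin-integrated exponential component on the histogram grid: the average of
# exp(-t/tau) over each bin (exact integral / bin width), so amplitudes keep
# the meaning of counts-per-bin at t = 0 regardless of binning.
binned_exponential <- function(tau, n_bins, bin_width) {
  edges <- (0:n_bins) * bin_width
  (exp(-edges[-(n_bins + 1)] / tau) - exp(-edges[-1] / tau)) *
    tau / bin_width
}

# Linear convolution of a decay basis with the (unit-sum) IRF, truncated to
# the histogram length. FFT-based for speed on long TCSPC histograms.
convolve_irf <- function(decay, irf) {
  n <- length(decay)
  m <- stats::nextn(2L * n, 2)
  full <- Re(stats::fft(stats::fft(c(decay, numeric(m - n))) *
                          stats::fft(c(irf, numeric(m - n))),
                        inverse = TRUE)) / m
  pmax(full[seq_len(n)], 0)
}

#' Expected counts of the bi-exponential reconvolution model
#'
#' Discrete convolution of the normalized IRF with the bin-integrated decay
#' `a1 * exp(-t/tau1) + a2 * exp(-t/tau2)`, plus a flat background. The model
#' is linear in `a1`, `a2` and `background`.
#'
#' @param tau1,tau2 Lifetimes (ns), both > 0.
#' @param a1,a2 Non-negative amplitudes (counts per bin at t = 0).
#' @param background Flat background (counts per bin).
#' @param irf IRF per bin (normalized internally).
#' @param n_bins Number of bins.
#' @param bin_width Bin width in ns.
#' @return Numeric vector of expected counts per bin.
#' @export
biexp_model_counts <- function(tau1, tau2, a1, a2, background,
                               irf, n_bins, bin_width) {
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  if (length(irf) != n_bins) stop("irf must have n_bins entries")
  irf <- irf / sum(irf)
  d <- a1 * binned_exponential(tau1, n_bins, bin_width) +
    a2 * binned_exponential(tau2, n_bins, bin_width)
  convolve_irf(d, irf) + background
}

#' Evaluate the model for a decay histogram
#'
#' Convenience wrapper around [biexp_model_counts()] using a histogram's
#' binning and IRF.
#'
#' @param hist A [decay_histogram()] (must carry an IRF).
#' @param tau1,tau2,a1,a2,background Model parameters.
#' @return Expected counts per bin.
#' @export
model_decay <- function(hist, tau1, tau2, a1, a2, background = 0) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (is.null(hist$irf)) stop("histogram carries no IRF")
  biexp_model_counts(tau1, tau2, a1, a2, background,
                     hist$irf, length(hist$counts), hist$bin_width_ns)
}

# Poisson deviance of observed counts vs a positive model.
poisson_deviance <- function(counts, model) {
  model <- pmax(model, 1e-12)
  ll <- counts * log(ifelse(counts > 0, counts / model, 1)) - (counts - model)
  2 * sum(ll)
}

# Neyman-weighted reduced chi-squared (variance = max(count, 1)) over bins
# whose model counts reach `floor` (low-count tail bins carry no usable
# goodness-of-fit information and would deflate the statistic).
reduced_chi2 <- function(counts, model, n_free, floor = 10) {
  use <- model >= floor
  n_used <- sum(use)
  if (n_used <= n_free) return(NA_real_)
  sum((counts[use] - model[use])^2 / pmax(counts[use], 1)) / (n_used - n_free)
}

# Deterministic initialization: tau2 from a log-linear fit of the decay tail,
# tau1 from the early post-peak region, amplitudes by non-negative linear
# solve at those lifetimes.
init_biexp <- function(counts, bin_width, irf) {
  n <- length(counts)
  peak <- which.max(convolve_irf(binned_exponential(1, n, bin_width), irf))
  peak <- max(peak, which.max(counts))
  cmax <- max(counts)
  # tail: from where counts fall to 10% of peak until 0.1% (or >= 5 counts)
  lo <- counts < 0.10 * cmax & seq_len(n) > peak
  hi <- counts >= max(0.001 * cmax, 5)
  tail_idx <- which(lo & hi)
  t_mid <- (seq_len(n) - 0.5) * bin_width
  fit_slope <- function(idx) {
    if (length(idx) < 5) return(NA_real_)
    cf <- stats::coef(stats::lm(log(counts[idx]) ~ t_mid[idx]))
    s <- cf[[2]]
    if (!is.finite(s) || s >= 0) NA_real_ else -1 / s
  }
  tau2 <- fit_slope(tail_idx)
  if (!is.na(tau2)) {
    # early region: between peak and the start of the tail
    early_idx <- which(seq_len(n) > peak + 2 & counts >= 0.3 * cmax)
    tau1 <- fit_slope(early_idx)
    if (is.na(tau1) || tau1 >= tau2) tau1 <- tau2 / 3
  } else {
    tau2 <- 1
    tau1 <- 0.3
  }
  list(tau1 = tau1, tau2 = tau2)
}

# Non-negative amplitude solve at fixed lifetimes (least squares on the two
# convolved basis vectors, clipped at zero).
solve_amplitudes <- function(counts, tau1, tau2, irf, bin_width, background) {
  n <- length(counts)
  b1 <- convolve_irf(binned_exponential(tau1, n, bin_width), irf)
  b2 <- convolve_irf(binned_exponential(tau2, n, bin_width), irf)
  y <- counts - background
  a <- tryCatch(
    stats::coef(stats::lm(y ~ 0 + b1 + b2)),
    error = function(e) c(b1 = sum(y) / 2 / max(sum(b1), 1e-9),
                          b2 = sum(y) / 2 / max(sum(b2), 1e-9))
  )
  pmax(as.numeric(a), c(1e-6, 1e-6) * max(counts))
}

#' Fit a bi-exponential reconvolution model to a TCSPC decay
#'
#' Maximum-likelihood fit for Poisson counts: minimizes the Poisson deviance
#' of the reconvolution model over lifetimes, amplitudes and (optionally) a
#' flat background. When the histogram carries no measured IRF, a Gaussian
#' IRF (centre and FWHM) is fitted jointly with the decay parameters.
#' Initialization is deterministic (log-linear tail/peak fits), so identical
#' histograms give identical fits.
#'
#' @param hist A [decay_histogram()].
#' @param init Optional named list overriding initial values (`tau1`, `tau2`,
#'   `a1`, `a2`, `background`, and for the fitted-IRF mode `irf_center_ns`,
#'   `irf_fwhm_ns`).
#' @param fit_background Estimate a flat background (default `TRUE` when the
#'   last decade of bins averages more than 0.1 counts, else fixed at 0).
#' @param min_total_counts Histograms with fewer total counts are rejected.
#' @param chi2_gate Acceptance interval for the reduced chi-squared
#'   (inclusive).
#' @return A `biexp_fit` list: `tau1_ns < tau2_ns`, `a1`, `a2`, `background`,
#'   `chi2_reduced`, `tau_amp_ns` (amplitude-weighted lifetime), `converged`,
#'   `accepted` (chi2 gate), `deviance`, `fitted` (model counts), and
#'   `effectively_monoexponential` (lifetimes within 1%).
#' @export
fit_biexponential <- function(hist, init = NULL, fit_background = NULL,
                              min_total_counts = 1000,
                              chi2_gate = c(1.0, 1.5)) {
  stopifnot(inherits(hist, "decay_histogram"))
  counts <- hist$counts
  if (sum(counts) < min_total_counts) {
    stop(sprintf("need >= %g total counts to fit (got %g)",
                 min_total_counts, sum(counts)))
  }
  n <- length(counts)
  dt <- hist$bin_width_ns
  fit_irf <- is.null(hist$irf)

  if (is.null(fit_background)) {
    tail10 <- counts[seq.int(floor(0.9 * n) + 1, n)]
    fit_background <- mean(tail10) > 0.1
  }

  ini <- init_biexp(counts, dt, hist$irf %||%
                      gaussian_irf(n, dt, dt * which.max(counts), 2 * dt))
  bg0 <- if (fit_background) max(mean(counts[seq.int(floor(0.95 * n) + 1, n)]),
                                 1e-3) else 0
  irf0 <- list(center = dt * (which.max(counts) - 0.5), fwhm = 10 * dt)
  if (!is.null(init)) {
    for (nm in c("tau1", "tau2")) if (!is.null(init[[nm]])) ini[[nm]] <- init[[nm]]
    if (!is.null(init$background)) bg0 <- init$background
    if (!is.null(init$irf_center_ns)) irf0$center <- init$irf_center_ns
    if (!is.null(init$irf_fwhm_ns)) irf0$fwhm <- init$irf_fwhm_ns
  }
  amp0 <- if (!fit_irf) {
    solve_amplitudes(counts, ini$tau1, ini$tau2, hist$irf, dt, bg0)
  } else {
    rep(sum(counts) * dt / (ini$tau1 + ini$tau2), 2)
  }
  if (!is.null(init$a1)) amp0[1] <- init$a1
  if (!is.null(init$a2)) amp0[2] <- init$a2

  # optimize in log space for positivity; background via log1p-style bound
  par0 <- log(c(ini$tau1, ini$tau2, amp0[1], amp0[2]))
  if (fit_background) par0 <- c(par0, log(max(bg0, 1e-6)))
  if (fit_irf) par0 <- c(par0, irf0$center, log(irf0$fwhm))

  unpack <- function(p) {
    out <- list(tau1 = exp(p[1]), tau2 = exp(p[2]),
                a1 = exp(p[3]), a2 = exp(p[4]))
    k <- 4L
    out$background <- if (fit_background) exp(p[(k <- k + 1L)]) else 0
    if (fit_irf) {
      out$irf_center <- p[k + 1L]
      out$irf_fwhm <- exp(p[k + 2L])
    }
    out
  }
  objective <- function(p) {
    q <- unpack(p)
    if (q$tau1 > 100 || q$tau2 > 100) return(1e12)
    irf <- if (fit_irf) {
      gaussian_irf(n, dt, q$irf_center, q$irf_fwhm)
    } else {
      hist$irf
    }
    if (sum(irf) <= 0) return(1e12)
    m <- biexp_model_counts(q$tau1, q$tau2, q$a1, q$a2, q$background,
                            irf, n, dt)
    poisson_deviance(counts, m)
  }

  opt <- stats::nlminb(par0, objective,
                       control = list(iter.max = 500, eval.max = 1000))
  # polish with Nelder-Mead from the nlminb solution (helps when the
  # finite-difference gradient stalls near the optimum)
  opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000,
                                      reltol = 1e-10))
  if (opt2$value < opt$objective) {
    opt$par <- opt2$par
    opt$objective <- opt2$value
    opt$convergence <- opt2$convergence
  }

  q <- unpack(opt$par)
  irf_used <- if (fit_irf) {
    gaussian_irf(n, dt, q$irf_center, q$irf_fwhm)
  } else {
    hist$irf
  }
  # enforce tau1 < tau2 by post-hoc sort (swap amplitudes along)
  if (q$tau1 > q$tau2) {
    q[c("tau1", "tau2", "a1", "a2")] <- q[c("tau2", "tau1", "a2", "a1")]
  }
  fitted <- biexp_model_counts(q$tau1, q$tau2, q$a1, q$a2, q$background,
                               irf_used, n, dt)
  n_free <- length(par0)
  chi2 <- reduced_chi2(counts, fitted, n_free)
  converged <- opt$convergence == 0 || is.finite(opt$objective)
  tau_amp <- (q$a1 * q$tau1 + q$a2 * q$tau2) / (q$a1 + q$a2)
  structure(
    list(
      tau1_ns = q$tau1, tau2_ns = q$tau2, a1 = q$a1, a2 = q$a2,
      background = q$background,
      irf_center_ns = q$irf_center, irf_fwhm_ns = q$irf_fwhm,
      chi2_reduced = chi2, tau_amp_ns = tau_amp,
      converged = converged,
      accepted = is.finite(chi2) && chi2 >= chi2_gate[1] && chi2 <= chi2_gate[2],
      effectively_monoexponential = abs(q$tau2 - q$tau1) <= 0.01 * q$tau2,
      deviance = opt$objective, n_free = n_free, fitted = fitted
    ),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<biexp_fit> tau1 = %.3f ns, tau2 = %.3f ns, a1/a2 = %.3f, ",
           "tau_amp = %.3f ns, chi2_red = %.3f%s\n"),
    x$tau1_ns, x$tau2_ns, x$a1 / x$a2, x$tau_amp_ns, x$chi2_reduced,
    if (x$accepted) " (accepted)" else ""
  ))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' `(a1 * tau1 + a2 * tau2) / (a1 + a2)`: the mean fluorescence lifetime with
#' components weighted by their amplitudes. Always lies between `tau1` and
#' `tau2` for non-negative amplitudes.
#'
#' @param fit A `biexp_fit`, or a list/vector with `tau1_ns`, `tau2_ns`,
#'   `a1`, `a2`.
#' @return Lifetime in ns.
#' @export
amplitude_weighted_tau <- function(fit) {
  a1 <- fit$a1
  a2 <- fit$a2
  if (a1 < 0 || a2 < 0) stop("amplitudes must be non-negative")
  if (a1 + a2 == 0) stop("amplitude-weighted lifetime undefined for a1 + a2 = 0")
  (a1 * fit$tau1_ns + a2 * fit$tau2_ns) / (a1 + a2)
}

#' Fit per-cell decays and tabulate lifetimes
#'
#' Fits every per-cell decay histogram and returns one row per cell with the
#' fitted lifetimes, amplitude ratio, amplitude-weighted lifetime, reduced
#' chi-squared and acceptance flag. Cells failing the chi-squared gate are
#' kept in the table (flagged) but excluded from group summaries downstream.
#'
#' @param decays Named list of [decay_histogram()] objects (names = cell
#'   IDs).
#' @param ... Passed to [fit_biexponential()].
#' @return A data.frame with columns `cell_id`, `tau1_ns`, `tau2_ns`,
#'   `a1`, `a2`, `amp_ratio`, `tau_amp_ns`, `chi2_reduced`, `converged`,
#'   `accepted`.
#' @export
fit_cell_decays <- function(decays, ...) {
  stopifnot(length(decays) >= 1)
  ids <- names(decays) %||% as.character(seq_along(decays))
  rows <- lapply(seq_along(decays), function(i) {
    f <- fit_biexponential(decays[[i]], ...)
    data.frame(
      cell_id = ids[i], tau1_ns = f$tau1_ns, tau2_ns = f$tau2_ns,
      a1 = f$a1, a2 = f$a2, amp_ratio = f$a1 / f$a2,
      tau_amp_ns = f$tau_amp_ns, chi2_reduced = f$chi2_reduced,
      converged = f$converged, accepted = f$accepted
    )
  })
  do.call(rbind, rows)
}

#' Render a lifetime map in pseudo-colour
#'
#' Paints each cell of a label mask with its amplitude-weighted lifetime,
#' clamped to the display range (default 0.2--1.0 ns, blue to red); background
#' and cells without an entry are black.
#'
#' @param labels A [segmentation_labels()].
#' @param fits Data.frame from [fit_cell_decays()] (needs `cell_id`,
#'   `tau_amp_ns`).
#' @param range_lo,range_hi Display range in ns.
#' @return `height x width x 3` RGB array in `[0, 1]`.
#' @export
render_flim <- function(labels, fits, range_lo = 0.2, range_hi = 1.0) {
  stopifnot(inherits(labels, "segmentation_labels"), range_lo < range_hi)
  lut <- grDevices::colorRampPalette(
    c("#0000C0", "#00A0E0", "#00C040", "#E0E000", "#E00000")
  )(256)
  tau <- matrix(NA_real_, nrow(labels$cell_labels), ncol(labels$cell_labels))
  for (i in seq_len(nrow(fits))) {
    tau[labels$cell_labels == as.integer(fits$cell_id[i])] <-
      fits$tau_amp_ns[i]
  }
  render_scalar_map(tau, !is.na(tau), range_lo, range_hi, lut)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
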