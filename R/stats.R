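#' Round half away from zero
#'
#' Conventional display rounding (0.5 always rounds up in magnitude), unlike
#' the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Group summary: mean and standard error over cells
#'
#' Summarizes per-cell measurements by group (cell line / condition) as
#' mean, standard error of the mean (`sd / sqrt(N)`) and `N`.
#'
#' @param records Data.frame of per-cell records.
#' @param group_col Name of the grouping column.
#' @param value_col Name of the measurement column.
#' @return Data.frame with `group`, `n_cells`, `mean`, `se`; constant-valued
#'   groups get `se = 0` with a warning (degenerate).
#' @export
summarize_cells <- function(records, group_col = "group",
                            value_col = "value") {
  stopifnot(group_col %in% names(records), value_col %in% names(records))
  groups <- split(records[[value_col]], records[[group_col]])
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small) > 0) {
    stop("groups with < 2 records: ", paste(small, collapse = ", "))
  }
  out <- data.frame(
    group = names(groups),
    n_cells = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    se = vapply(groups, function(v) stats::sd(v) / sqrt(length(v)),
                numeric(1)),
    row.names = NULL
  )
  if (any(out$se == 0)) {
    warning("degenerate group(s) with zero standard error: ",
            paste(out$group[out$se == 0], collapse = ", "))
  }
  out
}

#' Percent difference between two group means
#'
#' `100 * (mean_a - mean_b) / mean_b`, the relative difference of group `a`
#' (e.g. a cancer line) with respect to group `b` (e.g. a normal line, the
#' denominator). The display value is rounded half-up to integer percent; the
#' unrounded value is retained.
#'
#' @param mean_a,mean_b Group means (numbers, or rows/lists with a `mean`
#'   element such as rows of [summarize_cells()] output).
#' @return List with `percent` (unrounded) and `percent_display` (integer,
#'   rounded half away from zero).
#' @export
percent_difference <- function(mean_a, mean_b) {
  a <- if (is.list(mean_a)) mean_a$mean else mean_a
  b <- if (is.list(mean_b)) mean_b$mean else mean_b
  if (b <= 0) stop("denominator mean must be > 0")
  pct <- 100 * (a - b) / b
  list(percent = pct, percent_display = round_half_up(pct))
}

#' Hierarchical permutation test for a two-group difference of means
#'
#' Tests whether per-cell measurements differ between two groups while
#' respecting the replicate structure: cells from the same experiment are
#' correlated, so labels are permuted at the level where exchangeability
#' holds. When the two groups share experiment IDs (each experiment measured
#' both groups), group labels are permuted among cells *within* each
#' experiment; when experiments are disjoint between groups, whole
#' experiments are reassigned to groups. With fewer than 2 experiments per
#' group in the disjoint design the test falls back to plain cell-level
#' permutation with a warning about pseudo-replication.
#'
#' The statistic is the difference of group means (a - b); the p-value is the
#' two-sided permutation p with the add-one correction
#' `(1 + #{|T*| >= |T|}) / (B + 1)`, hence never 0 and never below
#' `1 / (B + 1)`.
#'
#' @param values_a,values_b Per-cell measurements for the two groups.
#' @param experiments_a,experiments_b Experiment (replicate) ID per cell.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed for reproducible permutations.
#' @param alpha_display Display significance threshold recorded on the
#'   result (default 1e-4).
#' @return List of class `pairwise_comparison`: `statistic` (mean_a -
#'   mean_b), `percent_difference` (relative to `mean_b`), `p_value`,
#'   `method`, `n_perm`, `significant` (at `alpha_display`).
#' @export
compare_groups <- function(values_a, values_b,
                           experiments_a = NULL, experiments_b = NULL,
                           n_perm = 10000L, seed = NULL,
                           alpha_display = 1e-4) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(experiments_a) || is.null(experiments_b)) {
    experiments_a <- rep("e1", length(values_a))
    experiments_b <- rep("e2", length(values_b))
    method <- "cell_permutation"
    warning("no experiment IDs supplied: cell-level permutation ",
            "(pseudo-replication risk)")
  } else {
    stopifnot(length(experiments_a) == length(values_a),
              length(experiments_b) == length(values_b))
    shared <- intersect(unique(experiments_a), unique(experiments_b))
    if (length(shared) > 0) {
      method <- "within_experiment_permutation"
    } else if (length(unique(experiments_a)) < 2 ||
               length(unique(experiments_b)) < 2) {
      method <- "cell_permutation"
      warning("fewer than 2 experiments per group: cell-level permutation ",
              "(pseudo-replication risk)")
    } else {
      method <- "experiment_permutation"
    }
  }

  obs <- mean(values_a) - mean(values_b)
  n_a <- length(values_a)
  n_b <- length(values_b)

  perm_stats <- switch(method,
    cell_permutation = {
      pool <- c(values_a, values_b)
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n_a + n_b, n_a)
        mean(pool[idx]) - mean(pool[-idx])
      }, numeric(1))
    },
    within_experiment_permutation = {
      # permute group labels among the cells of each experiment, keeping the
      # per-experiment group sizes fixed
      pool <- c(values_a, values_b)
      grp <- rep(c(TRUE, FALSE), c(n_a, n_b))
      exps <- c(experiments_a, experiments_b)
      by_exp <- split(seq_along(pool), exps)
      vapply(seq_len(n_perm), function(i) {
        g <- grp
        for (idx in by_exp) {
          g[idx] <- g[idx][sample.int(length(idx))]
        }
        mean(pool[g]) - mean(pool[!g])
      }, numeric(1))
    },
    experiment_permutation = {
      # reassign whole experiments to groups, keeping the number of
      # experiments per group fixed; statistic stays the cell-level mean diff
      exps <- c(experiments_a, experiments_b)
      pool <- c(values_a, values_b)
      by_exp <- split(pool, exps)
      k_a <- length(unique(experiments_a))
      e_names <- names(by_exp)
      vapply(seq_len(n_perm), function(i) {
        pick <- sample(e_names, k_a)
        va <- unlist(by_exp[pick], use.names = FALSE)
        vb <- unlist(by_exp[setdiff(e_names, pick)], use.names = FALSE)
        mean(va) - mean(vb)
      }, numeric(1))
    }
  )

  p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
  pd <- if (mean(values_b) > 0) {
    percent_difference(mean(values_a), mean(values_b))$percent
  } else {
    NA_real_
  }
  structure(
    list(
      statistic = obs, percent_difference = pd, p_value = p,
      method = method, n_perm = as.integer(n_perm),
      significant = p < alpha_display, alpha_display = alpha_display
    ),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf(
    "<pairwise_comparison> diff = %.4g (%.1f%%), p = %.4g [%s, B = %d]%s\n",
    x$statistic, x$percent_difference, x$p_value, x$method, x$n_perm,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Random-intercept model cross-check
#'
#' Optional cross-check of [compare_groups()] with a linear mixed model
#' (random intercept per experiment) when \pkg{lme4} is available. Not part
#' of the validated analysis surface.
#'
#' @inheritParams compare_groups
#' @return List with the fixed-effect group difference and its t value, or
#'   `NULL` when \pkg{lme4} is not installed.
#' @export
compare_groups_lmm <- function(values_a, values_b,
                               experiments_a, experiments_b) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    return(NULL)
  }
  df <- data.frame(
    value = c(values_a, values_b),
    group = rep(c("a", "b"), c(length(values_a), length(values_b))),
    experiment = c(experiments_a, experiments_b)
  )
  fit <- lme4::lmer(value ~ group + (1 | experiment), data = df)
  est <- lme4::fixef(fit)[["groupb"]]
  list(difference = -est,
       t_value = -stats::coef(summary(fit))["groupb", "t value"])
}
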