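#' Published MB Fpol group means for breast cell lines
#'
#' Reference group-mean fluorescence polarization of methylene blue (scaled
#' by 100) for two breast cancer lines (MDA-MB-231, MDA-MB-157) and two
#' normal breast epithelial lines (MCF-12A, MCF-10A), per compartment
#' (whole cell, nucleus-excluded, nucleus) and dye concentration, with
#' standard errors and cell counts. Used as the input for percent-difference
#' summaries between cancer and normal lines.
#'
#' @param mb_mg_per_ml Optional filter on dye concentration (0.05 or 0.01).
#' @return Data.frame with columns `cell_line`, `status`, `compartment`,
#'   `mb_mg_per_ml`, `mean_fpol_x100`, `se_fpol_x100`, `n_cells`.
#' @export
reference_fpol_means <- function(mb_mg_per_ml = NULL) {
  path <- system.file("extdata", "breast_fpol_reference.csv",
                      package = "fpolcell", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mb_mg_per_ml)) {
    df <- df[df$mb_mg_per_ml == mb_mg_per_ml, , drop = FALSE]
  }
  df
}

#' Published MB fluorescence lifetimes for breast cell lines
#'
#' Reference bi-exponential lifetime components (ns, with standard errors)
#' of methylene blue in the same four breast cell lines; the cancer lines
#' show shorter lifetimes than the normal lines, the basis of their higher
#' Fpol.
#'
#' @return Data.frame with `cell_line`, `status`, `tau1_ns`, `tau1_se_ns`,
#'   `tau2_ns`, `tau2_se_ns`.
#' @export
reference_lifetimes <- function() {
  path <- system.file("extdata", "breast_lifetime_reference.csv",
                      package = "fpolcell", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cancer-vs-normal percent differences from reference means
#'
#' Percent difference of every cancer line relative to every normal line
#' (normal mean as denominator) for one compartment and concentration of the
#' reference table.
#'
#' @param compartment `"whole_cell"`, `"excl_nucleus"` or `"nucleus"`.
#' @param mb_mg_per_ml Dye concentration (default 0.05).
#' @return Data.frame with `cancer`, `normal`, `percent`, `percent_display`.
#' @export
reference_percent_differences <- function(compartment = "whole_cell",
                                          mb_mg_per_ml = 0.05) {
  df <- reference_fpol_means(mb_mg_per_ml)
  df <- df[df$compartment == compartment, , drop = FALSE]
  cancers <- df[df$status == "cancer", , drop = FALSE]
  normals <- df[df$status == "normal", , drop = FALSE]
  out <- expand.grid(cancer = cancers$cell_line, normal = normals$cell_line,
                     stringsAsFactors = FALSE)
  pcts <- mapply(function(ca, no) {
    percent_difference(
      cancers$mean_fpol_x100[cancers$cell_line == ca],
      normals$mean_fpol_x100[normals$cell_line == no]
    )$percent
  }, out$cancer, out$normal)
  out$percent <- as.numeric(pcts)
  out$percent_display <- round_half_up(out$percent)
  out
}
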