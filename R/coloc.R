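#' Pearson correlation of two channels within an ROI
#'
#' Sample Pearson correlation of paired pixel intensities inside a region of
#' interest — the standard co-localization coefficient for two fluorescence
#' channels. Errors on degenerate input (empty/too-small ROI or a constant
#' channel, where the correlation is undefined) rather than returning a
#' silent value.
#'
#' @param channel_a,channel_b Numeric matrices of identical shape.
#' @param roi Logical (or 0/1) matrix selecting the ROI pixels.
#' @param min_pixels Minimum ROI size (default 20).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(channel_a, channel_b, roi, min_pixels = 20L) {
  channel_a <- as.matrix(channel_a)
  channel_b <- as.matrix(channel_b)
  if (!identical(dim(channel_a), dim(channel_b))) {
    stop("channels must have identical dimensions")
  }
  roi <- as.matrix(roi) > 0
  if (!identical(dim(roi), dim(channel_a))) {
    stop("roi must match the channel dimensions")
  }
  n <- sum(roi)
  if (n == 0) stop("empty ROI")
  if (n < min_pixels) {
    stop(sprintf("ROI has %d pixels, need >= %d", n, min_pixels))
  }
  a <- channel_a[roi]
  b <- channel_b[roi]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: constant channel within ROI")
  }
  stats::cor(a, b)
}

#' Per-cell co-localization table
#'
#' One Pearson correlation per (cell, organelle channel) pair. The ROI for a
#' cell is its whole-cell mask; cells whose ROI is too small or degenerate
#' are skipped with a warning.
#'
#' @param stack Named list of channel matrices; must contain the dye channel
#'   named by `mb_channel` plus each channel in `organelle_channels`.
#' @param labels A [segmentation_labels()].
#' @param organelle_channels Named character vector mapping organelle name to
#'   channel name in `stack`, e.g.
#'   `c(nucleus = "nucleus", mitochondria = "organelle")`.
#' @param mb_channel Name of the dye channel in `stack` (default `"mb"`).
#' @param min_pixels Minimum ROI pixels per cell.
#' @param exclude_border Drop cells touching the image border.
#' @return Data.frame with `cell_id`, `organelle`, `pearson_r`, `n_pixels`.
#' @export
coloc_table <- function(stack, labels, organelle_channels,
                        mb_channel = "mb", min_pixels = 20L,
                        exclude_border = TRUE) {
  stopifnot(inherits(labels, "segmentation_labels"),
            length(organelle_channels) >= 1)
  if (is.null(names(organelle_channels))) {
    names(organelle_channels) <- organelle_channels
  }
  missing_ch <- setdiff(c(mb_channel, unname(organelle_channels)),
                        names(stack))
  if (length(missing_ch) > 0) {
    stop("unmapped channel(s): ", paste(missing_ch, collapse = ", "))
  }
  mb <- as.matrix(stack[[mb_channel]])
  ids <- sort(unique(labels$cell_labels[labels$cell_labels > 0]))
  if (exclude_border) ids <- setdiff(ids, border_cells(labels$cell_labels))

  rows <- list()
  n_skipped <- 0L
  for (org in names(organelle_channels)) {
    ch <- as.matrix(stack[[organelle_channels[[org]]]])
    for (id in ids) {
      roi <- labels$cell_labels == id
      r <- tryCatch(pearson_r(mb, ch, roi, min_pixels = min_pixels),
                    error = function(e) NA_real_)
      if (is.na(r)) {
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, organelle = org, pearson_r = r, n_pixels = sum(roi)
      )
    }
  }
  if (n_skipped > 0) {
    warning(sprintf("%d (cell, organelle) record(s) skipped (degenerate ROI)",
                    n_skipped))
  }
  if (length(rows) == 0) {
    return(data.frame(cell_id = integer(), organelle = character(),
                      pearson_r = numeric(), n_pixels = integer()))
  }
  do.call(rbind, rows)
}
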