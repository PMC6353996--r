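#' Read / write 8-bit grayscale TIFF channels
#'
#' Images are held in R as numeric matrices on the 0--255 scale; on disk they
#' are single-channel 8-bit grayscale TIFFs.
#'
#' @param path File path.
#' @return `read_gray8_tiff()` returns a numeric matrix in `[0, 255]`.
#' @export
read_gray8_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) stop("expected a single-channel TIFF: ", path)
    img <- img[, , 1]
  }
  matrix(as.numeric(img), nrow(img))
}

#' @rdname read_gray8_tiff
#' @param image Numeric matrix in `[0, 255]`.
#' @export
write_gray8_tiff <- function(image, path) {
  stopifnot(min(image) >= 0, max(image) <= 255)
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' Read / write 16-bit integer label masks as TIFF
#'
#' @param path File path.
#' @return `read_labels_tiff()` returns an integer matrix.
#' @export
read_labels_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(round(img)), nrow(img))
}

#' @rdname read_labels_tiff
#' @param labels Integer matrix of non-negative labels (< 65536).
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(min(labels) >= 0, max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a polarized pair from one or two TIFF files
#'
#' Either two single-channel files (co, cross) or one two-channel file.
#'
#' @param co_path Path to the co-polarized channel, or to a two-channel TIFF
#'   when `cross_path` is `NULL` (channel 1 = co, channel 2 = cross).
#' @param cross_path Optional path to the cross-polarized channel.
#' @return A [polarized_pair()].
#' @export
read_polarized_pair <- function(co_path, cross_path = NULL) {
  if (is.null(cross_path)) {
    img <- tiff::readTIFF(co_path, as.is = TRUE)
    if (length(dim(img)) != 3L || dim(img)[3] < 2L) {
      stop("two-channel TIFF expected when cross_path is missing")
    }
    return(polarized_pair(img[, , 1], img[, , 2]))
  }
  polarized_pair(read_gray8_tiff(co_path), read_gray8_tiff(cross_path))
}

#' Write an Fpol map to disk
#'
#' Writes the floating-point Fpol values as a 32-bit TIFF (invalid pixels
#' stored as 0) and the pseudo-colour rendering as PNG.
#'
#' @param map An [fpol_map()].
#' @param tiff_path,png_path Output paths (`NULL` to skip either).
#' @param ... Passed to [render_fpol()].
#' @return Invisibly, the written paths.
#' @export
write_fpol_map <- function(map, tiff_path = NULL, png_path = NULL, ...) {
  stopifnot(inherits(map, "fpol_map"))
  if (!is.null(tiff_path)) {
    v <- map$fpol
    v[!map$valid_mask] <- 0
    tiff::writeTIFF(pmin(pmax(v, 0), 1), tiff_path, bits.per.sample = 32)
  }
  if (!is.null(png_path)) {
    png::writePNG(render_fpol(map, ...), png_path)
  }
  invisible(c(tiff_path, png_path))
}

#' Read / write decay histograms as CSV
#'
#' Plain-text exchange format: columns `bin_start_ns`, `counts` and
#' (optionally) `irf`.
#'
#' @param path File path.
#' @return `read_decay_csv()` returns a [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("bin_start_ns", "counts") %in% names(df)))
  dt <- stats::median(diff(df$bin_start_ns))
  decay_histogram(df$counts, bin_width_ns = dt, t0_ns = df$bin_start_ns[1],
                  irf = if ("irf" %in% names(df)) df$irf else NULL)
}

#' @rdname read_decay_csv
#' @param hist A [decay_histogram()].
#' @export
write_decay_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- data.frame(
    bin_start_ns = hist$t0_ns + (seq_along(hist$counts) - 1) * hist$bin_width_ns,
    counts = hist$counts
  )
  if (!is.null(hist$irf)) df$irf <- hist$irf
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write synthetic field specifications as YAML
#'
#' @param path YAML file path.
#' @return `read_spec_yaml()` returns the spec object of the class named in
#'   the file's `kind` field.
#' @export
read_spec_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  kind <- y$kind
  y$kind <- NULL
  switch(kind,
    cell_field = do.call(cell_field_spec, y),
    coloc_field = do.call(coloc_field_spec, y),
    decay = do.call(decay_spec, y),
    stop("unknown spec kind: ", kind)
  )
}

#' @rdname read_spec_yaml
#' @param spec A [cell_field_spec()], [coloc_field_spec()] or [decay_spec()].
#' @export
write_spec_yaml <- function(spec, path) {
  kind <- switch(class(spec)[1],
    cell_field_spec = "cell_field",
    coloc_field_spec = "coloc_field",
    decay_spec = "decay",
    stop("not a synthetic spec object")
  )
  yaml::write_yaml(c(list(kind = kind), unclass(spec)), path)
  invisible(path)
}
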