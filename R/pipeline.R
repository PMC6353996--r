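#' Write a complete synthetic fixture to disk
#'
#' Generates every input the analysis stages consume — a polarized image
#' pair, label masks, a co-localization stack and per-cell decay histograms —
#' from seeded specs and writes them under `out_dir` together with their
#' ground-truth tables and a manifest listing every file with its checksum.
#'
#' @param out_dir Output directory (created; errors if it exists and is
#'   non-empty unless `force = TRUE`).
#' @param field_spec A [cell_field_spec()].
#' @param coloc_spec A [coloc_field_spec()] (or `NULL` to skip).
#' @param decay_specs Named list of [decay_spec()]s, one per cell (or `NULL`
#'   to skip).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
simulate_fixture <- function(out_dir, field_spec,
                             coloc_spec = NULL, decay_specs = NULL,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(p) files <<- c(files, p)

  field <- generate_polarized_pair(field_spec)
  add(write_gray8_tiff(field$pair$co, file.path(out_dir, "co.tif")))
  add(write_gray8_tiff(field$pair$cross, file.path(out_dir, "cross.tif")))
  add(write_labels_tiff(field$labels$cell_labels,
                        file.path(out_dir, "cell_labels.tif")))
  add(write_labels_tiff(field$labels$nucleus_labels,
                        file.path(out_dir, "nucleus_labels.tif")))
  utils::write.csv(field$truth, file.path(out_dir, "fpol_truth.csv"),
                   row.names = FALSE)
  add(file.path(out_dir, "fpol_truth.csv"))
  add(write_spec_yaml(field_spec, file.path(out_dir, "field_spec.yaml")))

  if (!is.null(coloc_spec)) {
    cl <- generate_coloc_stack(coloc_spec)
    for (ch in names(cl$stack)) {
      add(write_gray8_tiff(cl$stack[[ch]],
                           file.path(out_dir, paste0("coloc_", ch, ".tif"))))
    }
    add(write_labels_tiff(cl$labels$cell_labels,
                          file.path(out_dir, "coloc_cell_labels.tif")))
    add(write_labels_tiff(cl$labels$nucleus_labels,
                          file.path(out_dir, "coloc_nucleus_labels.tif")))
    utils::write.csv(cl$truth, file.path(out_dir, "coloc_truth.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "coloc_truth.csv"))
    add(write_spec_yaml(coloc_spec, file.path(out_dir, "coloc_spec.yaml")))
  }

  if (!is.null(decay_specs)) {
    dir.create(file.path(out_dir, "decays"), showWarnings = FALSE)
    truth_rows <- list()
    for (nm in names(decay_specs)) {
      h <- generate_decay(decay_specs[[nm]])
      add(write_decay_csv(h, file.path(out_dir, "decays",
                                       paste0(nm, ".csv"))))
      sp <- decay_specs[[nm]]
      truth_rows[[nm]] <- data.frame(
        cell_id = nm, tau1_ns = sp$tau1, tau2_ns = sp$tau2,
        amp_ratio = sp$a1 / sp$a2, seed = sp$seed
      )
    }
    utils::write.csv(do.call(rbind, truth_rows),
                     file.path(out_dir, "decay_truth.csv"), row.names = FALSE)
    add(file.path(out_dir, "decay_truth.csv"))
  }

  manifest <- list(
    files = lapply(sort(files), function(p) {
      list(path = basename_rel(p, out_dir),
           md5 = unname(tools::md5sum(p)))
    }),
    seeds = list(
      field = field_spec$seed,
      coloc = if (!is.null(coloc_spec)) coloc_spec$seed,
      decays = if (!is.null(decay_specs)) {
        vapply(decay_specs, function(s) s$seed, integer(1))
      }
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

basename_rel <- function(path, root) {
  root <- sub("/+$", "", root)
  if (startsWith(path, root)) {
    sub("^/+", "", substring(path, nchar(root) + 1L))
  } else {
    path
  }
}

#' Run the Fpol stage on a fixture directory
#'
#' Reads the polarized pair and label masks, computes the pixel-wise Fpol
#' map and the per-cell per-compartment Fpol table, and writes
#' `fpol_map.tif`, `fpol_map.png` and `cell_fpol.csv` into `out_dir`.
#'
#' @param fixture_dir Directory produced by [simulate_fixture()] (or with the
#'   same file layout).
#' @param out_dir Output directory (default: the fixture directory).
#' @param g G-factor ([g_factor()] or number).
#' @param rule Threshold rule.
#' @param ... Passed to [cell_fpol_all()].
#' @return The per-cell data.frame, invisibly.
#' @export
run_fpol_pipeline <- function(fixture_dir, out_dir = fixture_dir, g = 0.75,
                              rule = threshold_rule(), ...) {
  need <- file.path(fixture_dir, c("co.tif", "cross.tif", "cell_labels.tif",
                                   "nucleus_labels.tif"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- read_polarized_pair(need[1], need[2])
  labels <- segmentation_labels(read_labels_tiff(need[3]),
                                read_labels_tiff(need[4]))
  map <- fpol_map(pair, g, rule)
  write_fpol_map(map, file.path(out_dir, "fpol_map.tif"),
                 file.path(out_dir, "fpol_map.png"))
  records <- suppressWarnings(cell_fpol_all(pair, labels, g, rule, ...))
  utils::write.csv(records, file.path(out_dir, "cell_fpol.csv"),
                   row.names = FALSE)
  invisible(records)
}

#' Run the co-localization stage on a fixture directory
#'
#' @inheritParams run_fpol_pipeline
#' @param organelle_channels Mapping organelle name -> channel name, as in
#'   [coloc_table()].
#' @return The co-localization data.frame, invisibly (also written as
#'   `coloc.csv`).
#' @export
run_coloc_pipeline <- function(fixture_dir, out_dir = fixture_dir,
                               organelle_channels = c(
                                 nucleus = "nucleus",
                                 mitochondria = "organelle"
                               )) {
  chans <- c("mb", "organelle", "nucleus")
  paths <- file.path(fixture_dir, paste0("coloc_", chans, ".tif"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  stack <- lapply(paths, read_gray8_tiff)
  names(stack) <- chans
  labels <- segmentation_labels(
    read_labels_tiff(file.path(fixture_dir, "coloc_cell_labels.tif")),
    read_labels_tiff(file.path(fixture_dir, "coloc_nucleus_labels.tif"))
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- suppressWarnings(
    coloc_table(stack, labels, organelle_channels)
  )
  utils::write.csv(records, file.path(out_dir, "coloc.csv"),
                   row.names = FALSE)
  invisible(records)
}

#' Run the FLIM stage on a fixture directory
#'
#' Fits every decay CSV under `decays/` and writes `flim_fits.csv`.
#'
#' @inheritParams run_fpol_pipeline
#' @param ... Passed to [fit_biexponential()].
#' @return The fits data.frame, invisibly.
#' @export
run_flim_pipeline <- function(fixture_dir, out_dir = fixture_dir, ...) {
  decay_dir <- file.path(fixture_dir, "decays")
  paths <- list.files(decay_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(paths) == 0) stop("no decay CSVs under ", decay_dir)
  decays <- lapply(paths, read_decay_csv)
  names(decays) <- sub("\\.csv$", "", basename(paths))
  fits <- fit_cell_decays(decays, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fits, file.path(out_dir, "flim_fits.csv"),
                   row.names = FALSE)
  invisible(fits)
}

#' Group report: summaries, percent differences and significance
#'
#' Aggregates per-cell records from two or more groups into the reporting
#' surface: per-group mean +/- SE (N), pairwise percent differences with the
#' first status level's groups against the second's, and hierarchical
#' permutation p-values.
#'
#' @param records Data.frame with columns `group`, `experiment_id`, `value`.
#' @param comparisons Data.frame with columns `group_a`, `group_b` naming the
#'   pairs to compare (default: all cross pairs of the groups present).
#' @param n_perm Permutations per comparison.
#' @param seed RNG seed for the permutation tests.
#' @param out_dir Optional directory to write `summary.csv`,
#'   `comparisons.csv` and `report.json`.
#' @return List with `summary` and `comparisons` data.frames.
#' @export
run_report <- function(records, comparisons = NULL, n_perm = 2000L,
                       seed = 1L, out_dir = NULL) {
  stopifnot(all(c("group", "experiment_id", "value") %in% names(records)))
  summ <- summarize_cells(records, "group", "value")
  groups <- summ$group
  if (is.null(comparisons)) {
    comparisons <- expand.grid(group_a = groups, group_b = groups,
                               stringsAsFactors = FALSE)
    comparisons <- comparisons[comparisons$group_a < comparisons$group_b, ]
  }
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    ga <- comparisons$group_a[i]
    gb <- comparisons$group_b[i]
    ra <- records[records$group == ga, ]
    rb <- records[records$group == gb, ]
    cmp <- suppressWarnings(compare_groups(
      ra$value, rb$value, ra$experiment_id, rb$experiment_id,
      n_perm = n_perm, seed = seed + i
    ))
    data.frame(
      group_a = ga, group_b = gb,
      percent_difference = cmp$percent_difference,
      percent_display = round_half_up(cmp$percent_difference),
      p_value = cmp$p_value, method = cmp$method
    )
  })
  cmp_df <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cmp_df, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summ, comparisons = cmp_df),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(summary = summ, comparisons = cmp_df)
}
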