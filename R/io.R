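# aggregate row-level validation errors into a single error with line numbers
raise_validation <- function(errors, what) {
  if (length(errors))
    stop("invalid ", what, ":\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
}

#' Read a microperimetry export table
#'
#' CSV schema: `eye_id, point_index, x_deg, y_deg, sensitivity_db, seen`.
#' Rows are validated strictly (finite coordinates, sensitivity within the
#' device range) and all offending line numbers are reported together.
#'
#' @param path CSV file path.
#' @param db_range device sensitivity range in dB.
#' @return validated data.frame.
#' @export
read_mp_export <- function(path, db_range = DEVICE_DB_RANGE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "point_index", "x_deg", "y_deg", "sensitivity_db", "seen")
  if (!all(need %in% names(d)))
    stop("MP export must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  errs <- character(0)
  for (i in seq_len(nrow(d))) {
    ln <- i + 1L  # header line is 1
    if (!is.finite(d$x_deg[i]) || !is.finite(d$y_deg[i]))
      errs <- c(errs, sprintf("line %d: non-finite position", ln))
    if (!is.finite(d$sensitivity_db[i]) ||
        d$sensitivity_db[i] < db_range[1] || d$sensitivity_db[i] > db_range[2])
      errs <- c(errs, sprintf("line %d: sensitivity %.1f outside [%g, %g] dB",
                              ln, d$sensitivity_db[i], db_range[1], db_range[2]))
  }
  raise_validation(errs, "MP export")
  d
}

#' Read per-B-scan lesion annotations
#'
#' CSV schema: `eye_id, scan_index, lesion_type, x_start_mm, x_end_mm`;
#' validation is delegated to [validate_annotations()] with row-level
#' reporting.
#'
#' @param path CSV file path.
#' @param oct an [oct_geometry()] defining valid scan indices and field.
#' @return validated (normalized) annotation data.frame.
#' @export
read_annotations <- function(path, oct = oct_geometry()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "scan_index", "lesion_type", "x_start_mm", "x_end_mm")
  if (!all(need %in% names(d)))
    stop("annotations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, lapply(split(d, d$eye_id), function(g) {
    v <- validate_annotations(g, oct)
    v$eye_id <- g$eye_id[1]
    v
  }))
  rownames(out) <- NULL
  out
}

#' Read a fixation track
#'
#' CSV schema: `eye_id, t_ms, x_mm, y_mm`.
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_fixation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "t_ms", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("fixation track must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  errs <- character(0)
  bad <- which(!is.finite(d$x_mm) | !is.finite(d$y_mm))
  if (length(bad))
    errs <- sprintf("line %d: non-finite sample", bad + 1L)
  raise_validation(errs, "fixation track")
  d
}

#' Write a simulated eye bundle to a directory
#'
#' Emits the interchange files of one eye: annotation CSV, NV polygon CSV
#' (when present), MP export CSV, fixation CSV, the IR image and the MP
#' fundus photo as PNG, and the ground-truth transform as a 4-field text
#' record.
#'
#' @param bundle an `eye_bundle`.
#' @param dir output directory (created if needed).
#' @param eye_id identifier written into the CSV files.
#' @return `dir`, invisibly.
#' @export
write_eye_bundle <- function(bundle, dir, eye_id = "eye") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- bundle$annotations
  utils::write.csv(cbind(eye_id = rep(eye_id, nrow(a)), a),
                   file.path(dir, "annotations.csv"), row.names = FALSE)
  if (!is.null(bundle$nv_polygon)) {
    p <- bundle$nv_polygon
    utils::write.csv(data.frame(eye_id = eye_id,
                                vertex_index = seq_len(nrow(p)) - 1L,
                                x_mm = p[, 1], y_mm = p[, 2]),
                     file.path(dir, "nv_polygon.csv"), row.names = FALSE)
  }
  utils::write.csv(cbind(eye_id = eye_id, bundle$mp_points),
                   file.path(dir, "mp_export.csv"), row.names = FALSE)
  utils::write.csv(cbind(eye_id = eye_id, bundle$fixation),
                   file.path(dir, "fixation.csv"), row.names = FALSE)
  png::writePNG(bundle$ir, file.path(dir, "ir.png"))
  png::writePNG(bundle$cfp, file.path(dir, "cfp.png"))
  write_transform(bundle$truth$transform, file.path(dir, "true_transform.tsv"))
  invisible(dir)
}

#' Serialize / read a similarity transform as a 4-field text record
#' @param t a [similarity_transform()].
#' @param path file path.
#' @export
write_transform <- function(t, path) {
  d <- data.frame(dx_px = t$dx_px, dy_px = t$dy_px,
                  rotation_deg = t$rotation_deg, scale = t$scale)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  d <- utils::read.delim(path)
  similarity_transform(d$dx_px, d$dy_px, d$rotation_deg, d$scale)
}

#' Write a pipeline results bundle
#'
#' Emits the cohort tables as CSV (group comparisons, fellow-eye
#' comparisons, zone MRS table, odds-ratio table when fitted), the forest
#' plot as PNG, the exclusion log, and a machine-readable run log (JSON)
#' carrying the seed and the pipeline constants for provenance.
#'
#' @param results a `pipeline_results` object from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(results$group_comparisons, "table1_group_comparisons.csv")
  wr(results$fellow_comparisons, "table2_fellow_comparisons.csv")
  wr(results$zone_table, "table3_zone_mrs.csv")
  wr(results$per_eye, "per_eye.csv")
  wr(results$exclusions, "exclusions.csv")
  if (!is.null(results$forest)) {
    wr(results$forest$table, "table4_odds_ratios.csv")
    grDevices::png(file.path(dir, "forest_plot.png"), width = 900, height = 600)
    print(results$forest$plot)
    grDevices::dev.off()
  }
  cfg <- results$config
  log <- list(schema_version = 1L, seed = cfg$seed,
              intersection_threshold = cfg$intersection_threshold,
              border_mm = cfg$border_mm,
              disc_diameter_deg = cfg$disc_diameter_deg,
              frame = cfg$frame[c("width_px", "height_px", "scale_um_per_px")],
              n_eyes_analyzed = nrow(results$per_eye),
              n_eyes_excluded = nrow(results$exclusions),
              not_seen_imputation = "device floor (0 dB)")
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
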