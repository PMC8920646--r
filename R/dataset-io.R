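# Plain-text RF dataset container: a directory with a JSON manifest and one
# CSV matrix per RF frame / ROI mask. The manifest is a declarative layout
# (field names -> roles) in the spirit of the public breast-RF releases that
# store two scans per lesion with paired ROI matrices and an integer class.

#' Write a list of lesion records to a directory container
#'
#' Layout: `manifest.json` lists every lesion (id, integer class with
#' 1 = malignant, scans with file names and acquisition metadata); each scan's
#' RF matrix and ROI mask are headerless CSV files. `load_rf_dataset` reads
#' the same dialect back; `load_rf_dataset(write_rf_dataset(x))` is an
#' identity on the records.
#'
#' @param lesions list of [lesion_record] objects
#' @param path directory to create/populate
#' @return `path`, invisibly
#' @export
write_rf_dataset <- function(lesions, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(lesions, function(les) {
    stopifnot(inherits(les, "lesion_record"))
    scans <- lapply(seq_along(les$scans), function(i) {
      s <- les$scans[[i]]
      rf_file <- sprintf("%s_scan%d_rf.csv", les$lesion_id, i)
      roi_file <- sprintf("%s_scan%d_roi.csv", les$lesion_id, i)
      utils::write.table(s$frame$samples, file.path(path, rf_file),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      utils::write.table(s$mask$mask * 1L, file.path(path, roi_file),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      list(rf = rf_file, roi = roi_file,
           sampling_frequency = s$frame$sampling_frequency,
           center_frequency = s$frame$center_frequency,
           sound_speed = s$frame$sound_speed,
           scan_label = s$frame$scan_label)
    })
    list(lesion_id = les$lesion_id,
         class = if (les$label == "malignant") 1L else 0L,
         scans = scans)
  })
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an RF dataset from a directory container
#'
#' @param path directory written by [write_rf_dataset] (or assembled by hand
#'   following the same layout)
#' @param layout named list mapping roles to manifest field names; the default
#'   names the conventional fields (`rf`, `roi`, `class`). A missing field in
#'   the manifest raises a structured error naming it.
#' @return list of [lesion_record] objects
#' @export
load_rf_dataset <- function(path,
                            layout = list(rf = "rf", roi = "roi", class = "class")) {
  mfile <- file.path(path, "manifest.json")
  if (!file.exists(mfile)) stopf("no manifest.json under '%s'", path)
  manifest <- jsonlite::read_json(mfile)
  lapply(manifest, function(entry) {
    if (is.null(entry$lesion_id)) stopf("manifest entry missing field 'lesion_id'")
    cls <- entry[[layout$class]]
    if (is.null(cls)) stopf("lesion '%s': missing field '%s'", entry$lesion_id, layout$class)
    label <- if (as.integer(cls) == 1L) "malignant" else "benign"
    scans <- lapply(entry$scans, function(sc) {
      for (role in c("rf", "roi")) {
        if (is.null(sc[[layout[[role]]]]))
          stopf("lesion '%s': scan missing field '%s'", entry$lesion_id, layout[[role]])
      }
      rf <- as.matrix(utils::read.table(file.path(path, sc[[layout$rf]]), sep = ","))
      roi <- as.matrix(utils::read.table(file.path(path, sc[[layout$roi]]), sep = ","))
      dimnames(rf) <- dimnames(roi) <- NULL
      if (!identical(dim(rf), dim(roi)))
        stopf("lesion '%s': ROI shape %s does not match RF shape %s",
              entry$lesion_id, paste(dim(roi), collapse = "x"),
              paste(dim(rf), collapse = "x"))
      list(frame = rf_frame(rf, sc$sampling_frequency, sc$center_frequency,
                            sound_speed = sc$sound_speed %||% 1540,
                            lesion_id = entry$lesion_id,
                            scan_label = sc$scan_label %||% ""),
           mask = roi_mask(roi == 1, "intratumoral"))
    })
    lesion_record(entry$lesion_id, label, scans)
  })
}
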