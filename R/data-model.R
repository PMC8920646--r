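# Core data types: RF frames, ROI masks, lesion records, feature tables.

#' Canonical names of the 16 QUS descriptors
#'
#' Fixed order used by every feature table in the package: six spectral
#' statistics (intratumoral mean and standard deviation of the midband fit,
#' spectral intercept and spectral slope parametric images), three
#' homodyned-K parameters (k, mu, h), three Nakagami parameters (m, Omega,
#' alpha), and four co-occurrence texture features.
#' @return character vector of length 16
#' @export
qus_feature_names <- function() {
  c("mbf_mean", "mbf_sd", "int_mean", "int_sd", "sl_mean", "sl_sd",
    "hk_k", "hk_mu", "hk_h",
    "nak_m", "nak_omega", "nak_alpha",
    "glcm_contrast", "glcm_correlation", "glcm_energy", "glcm_homogeneity")
}

#' Construct an RF frame
#'
#' A single ultrasound scan: a matrix of raw radiofrequency samples
#' (rows = axial sample index, columns = scan line) plus the acquisition
#' metadata needed downstream.
#'
#' @param samples numeric matrix, axial samples x scan lines
#' @param sampling_frequency sampling rate in Hz
#' @param center_frequency transducer center frequency in Hz
#' @param sound_speed assumed speed of sound in m/s (default 1540)
#' @param lesion_id,scan_label identifiers carried through the pipeline
#' @return an object of class `rf_frame`
#' @details A warning is raised when `sampling_frequency < 4 * center_frequency`:
#'   clinical systems sample at about four times the center frequency so the
#'   full pulse bandwidth clears Nyquist; below that margin (e.g. 20 MHz
#'   sampling of a 7.5 MHz carrier) part of the echo spectrum may be lost.
#' @export
rf_frame <- function(samples, sampling_frequency, center_frequency,
                     sound_speed = 1540, lesion_id = "", scan_label = "") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1L || ncol(samples) < 1L)
    stopf("`samples` must be a non-empty numeric matrix")
  if (!is.numeric(sampling_frequency) || sampling_frequency <= 0)
    stopf("`sampling_frequency` must be positive")
  if (!is.numeric(center_frequency) || center_frequency <= 0)
    stopf("`center_frequency` must be positive")
  if (sound_speed <= 0) stopf("`sound_speed` must be positive")
  if (sampling_frequency < 4 * center_frequency)
    warnf("sampling frequency (%.3g Hz) is below four times the center frequency (%.3g Hz); the RF signal may be undersampled",
          sampling_frequency, center_frequency)
  structure(
    list(samples = samples,
         sampling_frequency = sampling_frequency,
         center_frequency = center_frequency,
         sound_speed = sound_speed,
         lesion_id = as.character(lesion_id),
         scan_label = as.character(scan_label)),
    class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, fs=%.3g MHz, fc=%.3g MHz, lesion='%s' scan='%s'\n",
              nrow(x$samples), ncol(x$samples),
              x$sampling_frequency / 1e6, x$center_frequency / 1e6,
              x$lesion_id, x$scan_label))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical (or 0/1) matrix congruent with the image it targets
#' @param kind `"intratumoral"` (radiologist-drawn lesion region) or
#'   `"bounding_box"` (minimum bounding rectangle used for texture)
#' @return object of class `roi_mask`
#' @export
roi_mask <- function(mask, kind = c("intratumoral", "bounding_box")) {
  kind <- match.arg(kind)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stopf("ROI mask must not contain NA")
  if (!any(mask)) stopf("ROI mask must select at least one element")
  structure(list(mask = mask, kind = kind), class = "roi_mask")
}

#' Construct a lesion record
#'
#' Groups the scans (RF frame + ROI mask pairs) belonging to one lesion
#' together with its histological class label.
#'
#' @param lesion_id character id
#' @param label `"benign"` or `"malignant"` (malignant is the positive class)
#' @param scans list of `list(frame = rf_frame, mask = roi_mask)` pairs
#' @return object of class `lesion_record`
#' @export
lesion_record <- function(lesion_id, label, scans) {
  label <- match.arg(label, c("benign", "malignant"))
  if (!is.list(scans) || length(scans) < 1L)
    stopf("a lesion needs at least one scan")
  for (s in scans) {
    if (!inherits(s$frame, "rf_frame") || !inherits(s$mask, "roi_mask"))
      stopf("each scan must be a list(frame = rf_frame, mask = roi_mask)")
    if (!identical(dim(s$frame$samples), dim(s$mask$mask)))
      stopf("ROI mask shape %s does not match RF frame shape %s for lesion '%s'",
            paste(dim(s$mask$mask), collapse = "x"),
            paste(dim(s$frame$samples), collapse = "x"), lesion_id)
  }
  structure(list(lesion_id = as.character(lesion_id), label = label,
                 scans = scans),
            class = "lesion_record")
}

#' Assemble a QUS feature table
#'
#' A data.frame with one row per lesion (or per scan before aggregation),
#' the 16 canonical feature columns in fixed order, a binary label and a
#' provenance flag distinguishing original from resampler-synthesized rows.
#'
#' @param features numeric matrix or data.frame with the 16 canonical columns
#' @param label character/factor vector of `"benign"`/`"malignant"`
#' @param lesion_id optional row identifiers
#' @param scan_label optional per-scan labels (pre-aggregation tables)
#' @param provenance `"original"` or `"synthetic"` per row
#' @return data.frame of class `qus_feature_table`
#' @export
feature_table <- function(features, label, lesion_id = NULL,
                          scan_label = NULL, provenance = "original") {
  canon <- qus_feature_names()
  features <- as.data.frame(features)
  if (!setequal(names(features), canon) || ncol(features) != 16L)
    stopf("feature table must have exactly the 16 canonical feature columns; got [%s]",
          paste(names(features), collapse = ", "))
  features <- features[, canon]
  if (anyNA(features)) stopf("finalized feature table must not contain missing values")
  label <- as.character(label)
  if (!all(label %in% c("benign", "malignant")))
    stopf("labels must be 'benign' or 'malignant'")
  n <- nrow(features)
  out <- data.frame(
    lesion_id = as.character(lesion_id %||% sprintf("lesion_%03d", seq_len(n))),
    features,
    label = label,
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE)
  if (!is.null(scan_label))
    out <- cbind(out[1], scan_label = as.character(scan_label), out[-1])
  class(out) <- c("qus_feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' The CSV carries a header row with the canonical column names; reading
#' validates the 16 feature columns by name (any column order is accepted and
#' reordered to canonical) and round-trips values at full double precision.
#'
#' @param table a `qus_feature_table`
#' @param path file path
#' @return `read_feature_table` returns a `qus_feature_table`
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "qus_feature_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- qus_feature_names()
  missing_cols <- setdiff(canon, names(df))
  if (length(missing_cols))
    stopf("feature table at '%s' is missing columns: %s", path,
          paste(missing_cols, collapse = ", "))
  known <- c("lesion_id", "scan_label", canon, "label", "provenance")
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stopf("feature table at '%s' has unknown columns: %s", path,
          paste(unknown, collapse = ", "))
  feature_table(df[canon], df$label,
                lesion_id = df$lesion_id,
                scan_label = if ("scan_label" %in% names(df)) df$scan_label,
                provenance = df$provenance %||% "original")
}

#' Average per-scan features to one row per lesion
#'
#' Each lesion scanned in several planes contributes complementary
#' measurements; every feature is averaged arithmetically across that
#' lesion's scans to arrive at a single number per lesion. Labels must agree
#' within a lesion and are carried through. Aggregation is idempotent and
#' invariant to scan order.
#'
#' @param per_scan a `qus_feature_table` keyed by (lesion_id, scan)
#' @return a `qus_feature_table` keyed by lesion_id
#' @export
aggregate_scans <- function(per_scan) {
  stopifnot(inherits(per_scan, "qus_feature_table"))
  canon <- qus_feature_names()
  ids <- unique(per_scan$lesion_id)
  rows <- lapply(ids, function(id) {
    sub <- per_scan[per_scan$lesion_id == id, , drop = FALSE]
    if (length(unique(sub$label)) != 1L)
      stopf("conflicting labels within lesion '%s'", id)
    c(list(lesion_id = id), as.list(colMeans(sub[canon])),
      list(label = sub$label[1L],
           provenance = if (all(sub$provenance == "synthetic")) "synthetic" else "original"))
  })
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  feature_table(df[canon], df$label, lesion_id = df$lesion_id,
                provenance = df$provenance)
}
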