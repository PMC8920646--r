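test_that("rf_frame validates geometry and warns on undersampled RF", {
  m <- matrix(rnorm(64), 16, 4)
  fr <- rf_frame(m, 40e6, 10e6)
  expect_s3_class(fr, "rf_frame")
  expect_identical(dim(fr$samples), c(16L, 4L))
  # 20 MHz sampling of a 7.5 MHz carrier violates the 2x margin
  expect_warning(rf_frame(m, 20e6, 7.5e6), "undersampled")
  expect_error(rf_frame(m, -1, 10e6), "positive")
  expect_error(rf_frame(m, 40e6, 10e6, sound_speed = 0), "positive")
})

test_that("roi_mask and lesion_record enforce their invariants", {
  expect_error(roi_mask(matrix(FALSE, 2, 2)), "at least one")
  m <- matrix(rnorm(64), 16, 4)
  fr <- rf_frame(m, 40e6, 10e6, lesion_id = "L1")
  mk <- roi_mask(matrix(TRUE, 16, 4))
  expect_silent(lesion_record("L1", "malignant", list(list(frame = fr, mask = mk))))
  bad <- roi_mask(matrix(TRUE, 8, 4))
  expect_error(lesion_record("L1", "benign", list(list(frame = fr, mask = bad))),
               "does not match")
  expect_error(lesion_record("L1", "benign", list()), "at least one scan")
})

test_that("feature table round-trips through CSV at full precision", {
  ft <- toy_feature_table(3, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 0)
})

test_that("feature table readers reject malformed column sets", {
  ft <- toy_feature_table(3, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  df <- utils::read.csv(path)

  # dropping a feature column -> error naming it
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[setdiff(names(df), "hk_k")], p2, row.names = FALSE)
  expect_error(read_feature_table(p2), "hk_k")

  # unknown extra column -> error
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, mystery = 1), p3, row.names = FALSE)
  expect_error(read_feature_table(p3), "unknown")

  # arbitrary column order is accepted and canonicalized
  p4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[rev(names(df))], p4, row.names = FALSE)
  back <- read_feature_table(p4)
  expect_identical(names(back), names(ft))
  expect_equal(back$hk_k, ft$hk_k, tolerance = 1e-12)

  # 15 feature columns cannot form a table
  expect_error(feature_table(as.data.frame(ft)[qus_feature_names()[1:15]],
                             ft$label), "16")
})

test_that("aggregate_scans averages per lesion and is order-invariant", {
  canon <- qus_feature_names()
  base <- as.data.frame(toy_feature_table(1, 1))[1, canon]
  mk_row <- function(v) { r <- base; r[1, ] <- v; r }
  per_scan <- feature_table(rbind(mk_row(0.7), mk_row(0.9), mk_row(1), mk_row(2), mk_row(6)),
                            label = rep("benign", 5),
                            lesion_id = c("A", "A", "B", "B", "B"),
                            scan_label = c(1, 2, 1, 2, 3))
  agg <- aggregate_scans(per_scan)
  expect_equal(nrow(agg), 2L)
  expect_equal(unname(unlist(agg[agg$lesion_id == "A", canon])), rep(0.8, 16))
  expect_equal(unname(unlist(agg[agg$lesion_id == "B", canon])), rep(3, 16))

  # permutation invariance in scan order
  perm <- per_scan[c(4, 1, 5, 3, 2), ]
  class(perm) <- class(per_scan)
  agg2 <- aggregate_scans(perm)
  expect_equal(agg2[order(agg2$lesion_id), canon],
               agg[order(agg$lesion_id), canon], tolerance = 1e-12,
               ignore_attr = TRUE)

  # idempotent on already-aggregated tables; single-scan lesion untouched
  expect_equal(as.data.frame(aggregate_scans(agg)), as.data.frame(agg))

  # conflicting labels error
  bad <- per_scan
  bad$label[2] <- "malignant"
  expect_error(aggregate_scans(bad), "conflicting labels")
})

test_that("RF dataset container round-trips", {
  set.seed(11)
  mk_lesion <- function(id, label) {
    scans <- lapply(1:2, function(s) {
      m <- matrix(rnorm(32 * 6), 32, 6)
      msk <- matrix(FALSE, 32, 6); msk[8:24, 2:5] <- TRUE
      list(frame = rf_frame(m, 40e6, 10e6, lesion_id = id,
                            scan_label = c("longitudinal", "transverse")[s]),
           mask = roi_mask(msk))
    })
    lesion_record(id, label, scans)
  }
  lesions <- list(mk_lesion("les1", "malignant"), mk_lesion("les2", "benign"))
  dir <- withr::local_tempdir()
  write_rf_dataset(lesions, dir)
  back <- load_rf_dataset(dir)
  expect_length(back, 2)
  expect_identical(back[[1]]$label, "malignant")
  expect_identical(back[[2]]$label, "benign")
  for (i in 1:2) for (s in 1:2) {
    expect_equal(back[[i]]$scans[[s]]$frame$samples,
                 lesions[[i]]$scans[[s]]$frame$samples, tolerance = 1e-12)
    expect_identical(back[[i]]$scans[[s]]$mask$mask, lesions[[i]]$scans[[s]]$mask$mask)
    expect_identical(back[[i]]$scans[[s]]$frame$scan_label,
                     lesions[[i]]$scans[[s]]$frame$scan_label)
  }
  # structured error when the class field is missing under a custom layout
  expect_error(load_rf_dataset(dir, layout = list(rf = "rf", roi = "roi",
                                                  class = "grade")),
               "grade")
})
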