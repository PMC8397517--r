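test_that("lesion volumes round-trip through NIfTI bit-exactly", {
  set.seed(4)
  arr <- array(rbinom(8 * 10 * 6, 1, 0.3), c(8, 10, 6))
  aff <- rbind(c(2, 0, 0, -7), c(0, 2, 0, -9), c(0, 0, 2, -5), c(0, 0, 0, 1))
  v <- lesion_volume(arr, aff, "T01")
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_lesion_volume(v, p)
  v2 <- read_lesion_volume(p, patient_id = "T01")
  expect_identical(v2$grid, v$grid)
  expect_lt(max(abs(v2$affine - v$affine)), 1e-5)
  expect_equal(v2$voxel_size, c(2, 2, 2), tolerance = 1e-5)
})

test_that("reading binarises arbitrary nonzero values at > 0", {
  d <- c(6, 6, 6)
  arr <- array(sample(c(0, 255), prod(d), TRUE), d)
  p <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(arr), p)
  v <- read_lesion_volume(p)
  expect_true(all(v$grid %in% c(0L, 1L)))
  expect_identical(sum(v$grid), sum(arr > 0))   # independent nonzero count

  empty <- make_lesion(array(0, c(2, 2, 2)))
  expect_identical(sum(empty$grid), 0L)
})

test_that("lesion volume in cc is count times voxel volume / 1000", {
  arr <- array(0L, c(12, 12, 12)); arr[1:10, 1:10, 1:10] <- 1L
  expect_equal(lesion_volume_cc(make_lesion(arr, vox = 1)), 1.0)
  expect_equal(lesion_volume_cc(make_lesion(array(0, c(4, 4, 4)))), 0.0)
  arr2 <- array(0L, c(10, 10, 10)); arr2[seq_len(100)] <- 1L
  expect_equal(lesion_volume_cc(make_lesion(arr2, vox = 2)), 0.8)  # 100*8/1000
})

test_that("overlays count patients and conserve total lesion load", {
  arr <- array(rbinom(4^3, 1, 0.5), c(4, 4, 4))
  one <- compute_overlay(list(make_lesion(arr)))
  expect_identical(one$counts, array(as.integer(arr != 0), dim(arr)))
  two <- compute_overlay(list(make_lesion(arr, id = "a"),
                              make_lesion(arr, id = "b")))
  expect_identical(two$counts, 2L * one$counts)

  set.seed(11)
  vols <- lapply(1:10, function(i)
    make_lesion(array(rbinom(5^3, 1, 0.3), c(5, 5, 5)), id = paste0("r", i)))
  ov <- compute_overlay(vols)
  expect_identical(sum(ov$counts),
                   sum(vapply(vols, function(v) sum(v$grid), 0L)))

  small <- make_lesion(array(0, c(3, 3, 3)))
  expect_error(compute_overlay(list(vols[[1]], small)), "shape mismatch")
  shifted <- lesion_volume(arr, test_affine(2), "c")
  expect_error(compute_overlay(list(make_lesion(arr), shifted)),
               "affine mismatch")
})

test_that("coverage mask applies the minimum-overlap rule and is monotone", {
  counts <- array(0L, c(4, 4, 4))
  counts[1, 1, 1] <- 5L; counts[2, 2, 2] <- 4L; counts[3, 3, 3] <- 9L
  ov <- structure(list(counts = counts, affine = test_affine(), n_patients = 9L),
                  class = "lesion_overlay")
  m5 <- coverage_mask(ov, 5)
  expect_true(m5[1, 1, 1])       # exactly five patients is included
  expect_false(m5[2, 2, 2])
  expect_identical(unclass(coverage_mask(ov, 1))[seq_along(counts)],
                   as.logical(counts > 0))
  expect_identical(coverage_mask(array(0L, c(3, 3, 3)), 5),
                   array(FALSE, c(3, 3, 3)))
  for (k in 1:8) {
    expect_true(all(coverage_mask(ov, k + 1) <= coverage_mask(ov, k)))
  }
})

test_that("labelled-ROI lookup names the region containing a coordinate", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:3, 1:3, 1:3] <- 1L
  lab[4:6, 4:6, 4:6] <- 2L
  aff <- test_affine(2)
  got <- lookup_roi_label(lab, aff, rbind(c(0, 0, 0), c(8, 8, 8), c(50, 0, 0)),
                          names = c("1" = "anterior", "2" = "posterior"))
  expect_equal(got$code, c(1L, 2L, NA))
  expect_equal(got$region, c("anterior", "posterior", NA))
})

test_that("cohort tables are validated with row-level reports", {
  df <- toy_cohort(3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(df, p)
  got <- read_cohort_table(p)
  expect_equal(nrow(got), 3)
  expect_s3_class(got, "cohort_table")

  bad <- df; bad$score_yesno[2] <- 61
  bad$score_overall[2] <- (61 + bad$score_word[2] + bad$score_commands[2]) / 20
  expect_warning(out <- validate_cohort_table(bad), "rejected 1")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "rejected")$patient_id, df$patient_id[2])

  expect_error(validate_cohort_table(df[, -3]), "missing cohort columns")

  off <- df; off$score_overall[1] <- off$score_overall[1] + 0.2
  expect_warning(validate_cohort_table(off), "inconsistent")

  filled <- df; filled$score_overall[1] <- NA
  got2 <- validate_cohort_table(filled)
  expect_equal(got2$score_overall[1],
               (df$score_yesno[1] + df$score_word[1] + df$score_commands[1]) / 20)
})

test_that("longitudinal validation enforces ordering and score range", {
  df <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                   session_index = c(1, 2, 1, 2),
                   months_post_onset = c(2, 8, 1, 14),
                   comprehension_score = c(3, 5, 6, 8))
  got <- validate_longitudinal_table(df)
  expect_s3_class(got, "longitudinal_table")
  bad <- df; bad$comprehension_score[1] <- 11
  expect_error(validate_longitudinal_table(bad), "0, 10")
  dup <- df; dup$months_post_onset[2] <- 2
  expect_error(validate_longitudinal_table(dup), "strictly increasing")
})

test_that("recovery inclusion rules drop ceiling, single-session and
           close-session patients", {
  df <- data.frame(
    patient_id = c("ok", "ok", "ceiling", "ceiling", "single", "close", "close"),
    session_index = c(1, 2, 1, 2, 1, 1, 2),
    months_post_onset = c(3, 10, 2, 9, 5, 3, 3.5),
    comprehension_score = c(4, 6, 9.2, 9.5, 3, 5, 5.5))
  out <- filter_recovery_cohort(df)
  expect_identical(unique(out$patient_id), "ok")
  expect_equal(nrow(out), 2)
})
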