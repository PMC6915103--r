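make_truth <- function(nc = 12L) {
  M <- outer(seq_len(nc), seq_len(nc),
             function(i, j) 0.4 * exp(-abs(i - j) / 4))
  diag(M) <- NA_real_
  structure(M, amplitude_A = 50e-6, class = c("voltage_spread", "matrix"))
}

test_that("spread CSV round-trips bit-exactly with metadata and mask reasons", {
  truth <- make_truth()
  v <- unclass(truth)
  v[2L, 5L] <- NA; v[5L, 2L] <- NA
  reason <- matrix(NA_character_, 12L, 12L)
  reason[2L, 5L] <- reason[5L, 2L] <- "outlier-impedance"
  set <- measurement_set(v, subject = "EAR07", amplitude_uA = 50,
                         mask_reason = reason)
  path <- tempfile(fileext = ".csv")
  write_spread_csv(set, path)
  back <- read_spread_csv(path)
  expect_identical(back$values, set$values)
  expect_equal(back$subject, "EAR07")
  expect_equal(back$amplitude_uA, 50)
  expect_equal(back$mask_reason[2L, 5L], "outlier-impedance")
  # without the sidecar, NA cells default to 'deactivated'
  file.remove(paste0(path, ".json"))
  back2 <- read_spread_csv(path)
  expect_equal(back2$mask_reason[2L, 5L], "deactivated")
  unlink(path)
})

test_that("malformed spread CSVs fail with a line number", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("contact,1,2,3", "1,0.1,0.2,0.3", "2,0.2,0.1,0.4"), path)
  expect_error(read_spread_csv(path), "line 3")
  writeLines(c("x,1,2", "1,0.1,0.2", "2,0.2,0.1"), path)
  expect_error(read_spread_csv(path), "line 1")
  writeLines(c("contact,1,2", "1,0.1", "2,0.2,0.1"), path)
  expect_error(read_spread_csv(path), "line 2")
  unlink(path)
})

test_that("the noise-free cohort reproduces the truth and seeds are reproducible", {
  truth <- make_truth()
  clean <- simulate_measurements(truth, n_subjects = 3, noise_cv = 0,
                                 missing_policy = list(rate = 0), seed = 1)
  tv <- unclass(truth)
  attributes(tv) <- list(dim = dim(tv))
  for (m in clean) expect_identical(m$values, tv)
  a <- simulate_measurements(truth, n_subjects = 16, noise_cv = 0.3, seed = 11)
  b <- simulate_measurements(truth, n_subjects = 16, noise_cv = 0.3, seed = 11)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  expect_length(a, 16L)
  expect_equal(a[[1L]]$amplitude_uA, 50)
  expect_error(simulate_measurements(truth, n_subjects = 0), ">= 1")
  # missingness is biased toward the basal contacts
  many <- simulate_measurements(truth, n_subjects = 200, noise_cv = 0.1,
                                missing_policy = list(rate = 0.15,
                                                      basal_bias = 2,
                                                      p_outlier = 0.3),
                                seed = 5)
  miss_per_contact <- rowSums(sapply(many, function(m) {
    sapply(seq_len(12L), function(i) all(is.na(m$values[i, -i])))
  }))
  expect_gt(sum(miss_per_contact[1:3]), sum(miss_per_contact[10:12]))
})

test_that("comparison statistics behave at the identity and exclude the stimulating contact", {
  truth <- make_truth()
  # two subjects placed symmetrically around the simulation: mean == sim
  up <- measurement_set(unclass(truth) * 1.25, subject = "A")
  dn <- measurement_set(unclass(truth) * 0.75, subject = "B")
  cs <- compare_to_measurements(truth, list(up, dn), stim_pair = 4)
  expect_equal(cs$bias, 0, tolerance = 1e-12)
  expect_equal(cs$within_band_fraction, 1)
  expect_false(4L %in% cs$contacts)
  # a subject with nothing usable is skipped with a warning
  blank <- measurement_set(matrix(NA_real_, 12L, 12L), subject = "EMPTY")
  expect_warning(
    cs2 <- compare_to_measurements(truth, list(up, dn, blank), stim_pair = 4),
    "EMPTY"
  )
  expect_equal(cs2$n_subjects, 2L)
  # invariance to subject ordering
  cs3 <- compare_to_measurements(truth, list(dn, up), stim_pair = 4)
  expect_equal(cs3$mean, cs$mean)
  expect_equal(cs3$within_band_fraction, cs$within_band_fraction)
})
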