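test_that("parsing links demographics and encounters and preserves rows", {
  cohort <- toy_cohort()
  pat <- cohort$patients[1:2, ]
  enc <- cohort$encounters[c(1, 4, 5), ]
  enc$sdoh_codes <- vapply(enc$sdoh_codes, paste, character(1),
    collapse = ";")
  log <- parse_tracking_log(pat, enc)
  expect_equal(nrow(log$patients), 2)
  expect_equal(nrow(log$encounters), 3)
  expect_true(all(log$encounters$patient_id %in% log$patients$patient_id))
  expect_equal(log$patients$patient_id, pat$patient_id) # order preserved
})

test_that("empty cells normalise to the missing sentinel", {
  cohort <- toy_cohort()
  enc <- cohort$encounters[1:3, ]
  enc$sdoh_codes <- vapply(enc$sdoh_codes, paste, character(1),
    collapse = ";")
  enc$comments[2] <- ""
  enc$comments[3] <- "NA"
  log <- parse_tracking_log(cohort$patients, enc)
  expect_true(is.na(log$encounters$comments[2]))
  expect_true(is.na(log$encounters$comments[3]))
})

test_that("referential and schema errors name the offenders", {
  cohort <- toy_cohort()
  enc <- cohort$encounters[1:2, ]
  enc$sdoh_codes <- "language_interpreter"
  enc$patient_id[2] <- "P999"
  expect_error(
    parse_tracking_log(cohort$patients, enc),
    "P999"
  )
  pat_broken <- cohort$patients[, setdiff(names(cohort$patients), "age")]
  expect_error(
    parse_tracking_log(pat_broken, cohort$encounters),
    "age"
  )
  pat_extra <- cohort$patients
  pat_extra$shoe_size <- 7
  enc2 <- cohort$encounters
  enc2$sdoh_codes <- vapply(enc2$sdoh_codes, paste, character(1),
    collapse = ";")
  expect_warning(
    parse_tracking_log(pat_extra, enc2),
    "shoe_size"
  )
})

test_that("numeric imputation uses the mean, categorical the mode", {
  pat <- make_patients(c("P1", "P2", "P3"),
    age = c(40, 50, NA),
    marital_status = c("married", "married", NA)
  )
  pat2 <- make_patients("P4", age = 45, marital_status = "single")
  pat <- dplyr::bind_rows(pat, pat2)
  enc <- make_encounters(c("P1", "P2", "P3", "P4"),
    codes = list("fear", "fear", "fear", "fear")
  )
  out <- impute_missing(pat, enc)
  expect_equal(out$patients$age[3], 45)
  expect_equal(out$patients$marital_status[3], "married")
  expect_true(!anyNA(out$patients))
})

test_that("mode ties break to the lexicographically smallest value", {
  pat <- make_patients(c("P1", "P2", "P3"),
    occupation = c("service", "retired", NA)
  )
  enc <- make_encounters("P1", codes = list("fear"))
  out <- impute_missing(pat, enc)
  expect_equal(out$patients$occupation[3], "retired")
})

test_that("encounters without notes or codes are dropped, others untouched", {
  enc <- make_encounters(rep("P1", 4), codes = list(
    "fear", "housing", "fear", "fear"
  ))
  enc$comments[2] <- NA
  enc$sdoh_codes[3] <- list(NULL)
  out <- impute_missing(make_patients("P1"), enc)
  expect_equal(nrow(out$encounters), 2)
  expect_true(any(out$log$action == "drop_encounter"))
  # non-missing cells never change
  expect_identical(
    out$encounters$action_length,
    enc$action_length[c(1, 4)]
  )
})

test_that("an all-missing column is an imputation error naming it", {
  pat <- make_patients(c("P1", "P2"), occupation = c(NA, NA))
  enc <- make_encounters("P1", codes = list("fear"))
  expect_error(impute_missing(pat, enc), "occupation")
})

test_that("one-hot encoding is binary, complete, and invertible", {
  tbl <- tibble::tibble(x = c("A", "B", "A"))
  enc <- one_hot_encode(tbl, "x")
  expect_equal(unname(enc$matrix[, "x=A"]), c(1, 0, 1))
  expect_equal(unname(enc$matrix[, "x=B"]), c(0, 1, 0))

  tbl3 <- tibble::tibble(
    a = c("x", "y", "x", "y"),
    b = c("1", "2", "3", "1"),
    c = c("p", "q", "r", "s"),
    n = c(1.5, 2, 3, 4)
  )
  enc3 <- one_hot_encode(tbl3, c("a", "b", "c"))
  cat_part <- enc3$matrix[, setdiff(colnames(enc3$matrix), "n")]
  expect_equal(ncol(cat_part), 2 + 3 + 4)
  expect_equal(unname(rowSums(cat_part)), rep(3, 4))
  # each original column's segment sums to exactly 1 per row
  for (cl in c("a", "b", "c")) {
    seg <- enc3$matrix[, startsWith(colnames(enc3$matrix), paste0(cl, "="))]
    expect_equal(unname(rowSums(seg)), rep(1, 4))
  }
  dec <- one_hot_decode(enc3$matrix, enc3$dictionary)
  expect_equal(as.data.frame(dec), as.data.frame(tbl3))
})

test_that("unseen categories error by default, or yield zero segments", {
  train <- tibble::tibble(x = c("A", "B"))
  test <- tibble::tibble(x = c("A", "C"))
  d <- one_hot_encode(train, "x")$dictionary
  expect_error(one_hot_encode(test, "x", dictionary = d), "C")
  enc <- one_hot_encode(test, "x", dictionary = d, unseen = "zero")
  expect_equal(unname(enc$matrix[2, ]), c(0, 0))
})

test_that("missing categorical values are rejected by the encoder", {
  expect_error(
    one_hot_encode(tibble::tibble(x = c("A", NA)), "x"),
    "impute"
  )
})

test_that("a written log re-parses value-identically", {
  cohort <- toy_cohort()
  cohort$patients$age[2] <- NA
  cohort$encounters$comments[3] <- NA
  tmp_d <- withr::local_tempfile(fileext = ".csv")
  tmp_e <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(cohort, tmp_d, tmp_e)
  log <- parse_tracking_log(tmp_d, tmp_e)
  expect_equal(as.data.frame(log$patients), as.data.frame(cohort$patients))
  expect_equal(log$encounters$sdoh_codes, cohort$encounters$sdoh_codes)
  # write -> parse -> write -> parse is a fixed point
  tmp_d2 <- withr::local_tempfile(fileext = ".csv")
  tmp_e2 <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(log, tmp_d2, tmp_e2)
  log2 <- parse_tracking_log(tmp_d2, tmp_e2)
  expect_equal(log2, log)
})
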