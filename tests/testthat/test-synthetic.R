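test_that("the seed fully determines the generated cohort", {
  cfg <- cohort_config(n_patients = 25, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_patients = 25, seed = 8))
  expect_false(identical(a$patients, c$patients))
})

test_that("generated logs survive a write/parse round trip cleanly", {
  sim <- generate_cohort(cohort_config(n_patients = 15, seed = 3))
  tmp_d <- withr::local_tempfile(fileext = ".csv")
  tmp_e <- withr::local_tempfile(fileext = ".csv")
  write_tracking_log(sim, tmp_d, tmp_e)
  expect_no_warning(log <- parse_tracking_log(tmp_d, tmp_e))
  expect_equal(nrow(log$patients), 15)
  expect_setequal(
    unique(unlist(log$encounters$sdoh_codes)),
    unique(unlist(sim$encounters$sdoh_codes))
  )
})

test_that("with zero signal, code frequencies match the base rates", {
  cfg <- cohort_config(
    n_patients = 2000, signal_strength = 0,
    missingness = c(comments = 0), seed = 42
  )
  sim <- generate_cohort(cfg)
  counts <- table(unlist(sim$encounters$sdoh_codes))
  n_enc <- nrow(sim$encounters)
  for (code in names(cfg$sdoh_base_rates)) {
    p <- cfg$sdoh_base_rates[[code]]
    obs <- (counts[code] %||% 0) / n_enc
    tol <- 3 * sqrt(p * (1 - p) / n_enc)
    expect_lt(abs(obs - p), tol + 1e-12)
  }
})

test_that("a dominant base rate makes language the modal patient code", {
  rates <- navsdoh:::default_base_rates()
  rates["language_interpreter"] <- 0.8
  hits <- 0
  for (seed in 1:20) {
    cfg <- cohort_config(
      n_patients = 40, sdoh_base_rates = rates,
      signal_strength = 0, seed = seed
    )
    sim <- generate_cohort(cfg)
    modal_per_patient <- vapply(
      split(sim$encounters$sdoh_codes, sim$encounters$patient_id),
      function(codes) names(which.max(table(unlist(codes)))),
      character(1)
    )
    if (names(which.max(table(modal_per_patient))) ==
      "language_interpreter") {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 20, 0.95)
})

test_that("site B emits one generic/specific SDoH pair and no notes", {
  b <- generate_site_b(cohort_config(n_patients = 20, seed = 5))
  expect_false("comments" %in% names(b$encounters))
  expect_true(all(!is.na(b$encounters$sdoh_generic)))
  expect_true(all(
    b$patients$occupation %in% c("unemployed", "part_time", "full_time")
  ))
  # every emitted code resolves through the alias map
  raw <- ifelse(is.na(b$encounters$sdoh_specific),
    b$encounters$sdoh_generic, b$encounters$sdoh_specific
  )
  unified <- map_sdoh_code(raw)
  expect_true(all(unified %in% sdoh_labels()))
})

test_that("the ground-truth report recounts the raw log exactly", {
  expect_equal(
    nrow(ground_truth_report(tibble::tibble(
      patient_id = character(), true_sdoh = list(),
      n_encounters = integer(), topic_mixture = list()
    ))), 0
  )
  cfg <- cohort_config(
    n_patients = 5, missingness = c(comments = 0), seed = 9
  )
  sim <- generate_cohort(cfg)
  rep <- ground_truth_report(sim$ground_truth)
  expect_equal(nrow(rep), 5)
  for (i in seq_len(5)) {
    pid <- rep$patient_id[i]
    enc <- sim$encounters[sim$encounters$patient_id == pid, ]
    recount <- sort(unique(setdiff(unlist(enc$sdoh_codes), "none")))
    expect_equal(strsplit(rep$true_sdoh[i], ";")[[1]], recount)
    expect_equal(rep$n_encounters[i], nrow(enc))
  }
})

test_that("degenerate generator configurations are rejected", {
  expect_error(cohort_config(encounter_sd = 2), "overdispersed")
  expect_error(cohort_config(note_length_mean = 0), "degenerate")
  rates <- navsdoh:::default_base_rates()
  rates[1] <- 1.2
  expect_error(cohort_config(sdoh_base_rates = rates), "0, 1")
})

test_that("stronger demographic signal raises classifier accuracy", {
  acc_at <- function(sig, seed) {
    sim <- generate_cohort(cohort_config(
      n_patients = 150, signal_strength = sig, seed = seed
    ))
    imp <- impute_missing(sim$patients, sim$encounters)
    inst <- apply_strategy(imp$patients, imp$encounters, "s5")
    suppressWarnings(run_config_cv(
      inst, list(strategy = "s5", k = NA, algorithm = "random_forest"),
      folds = 5, seed = seed
    ))$mean_accuracy
  }
  means <- vapply(c(0, 2, 4), function(sig) {
    mean(vapply(1:5, function(seed) acc_at(sig, seed), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
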