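# Fixture builders shared across the suite. Everything is constructed
# in code; no data files.

make_patients <- function(ids, ...) {
  n <- length(ids)
  defaults <- tibble::tibble(
    patient_id = ids,
    age = rep(50, n),
    occupation = rep("homemaker", n),
    marital_status = rep("married", n),
    education_level = rep("high_school", n),
    year_arrived_us = rep(2000, n),
    english_level = rep("poor", n),
    origin = rep("china", n),
    zip_code = rep("60616", n),
    household_size = rep(3, n),
    born_in_us = rep("no", n),
    income_range = rep("under_25k", n),
    site = rep("A", n)
  )
  dots <- list(...)
  for (nm in names(dots)) defaults[[nm]] <- dots[[nm]]
  defaults
}

make_encounters <- function(pids, codes, comments = NULL, dates = NULL,
                            action_length = NULL) {
  n <- length(pids)
  if (is.null(comments)) comments <- sprintf("note %d about visit", seq_len(n))
  if (is.null(dates)) {
    dates <- as.character(as.Date("2015-01-01") + seq_len(n))
  }
  if (is.null(action_length)) action_length <- rep(15, n)
  tibble::tibble(
    patient_id = pids,
    encounter_date = dates,
    preferred_language = rep("cantonese", n),
    all_languages = rep("cantonese", n),
    service_type = rep("screening", n),
    channel = rep("phone", n),
    action_taken = rep("interpretation", n),
    action_length = action_length,
    comments = comments,
    sdoh_codes = codes,
    site = rep("A", n)
  )
}

# The three-patient toy cohort: two language-only patients, one whose
# second encounter raises fear.
toy_cohort <- function() {
  patients <- make_patients(c("P1", "P2", "P3"))
  encounters <- make_encounters(
    pids = c("P1", "P1", "P1", "P2", "P2", "P3", "P3"),
    codes = list(
      "language_interpreter", "language_interpreter",
      "language_interpreter", "language_interpreter",
      "language_interpreter", "language_interpreter", "fear"
    )
  )
  list(patients = patients, encounters = encounters)
}

# Random small cohorts for property tests: up to 10 patients, up to 5
# encounters each, codes from a small pool, occasional multi-code and
# wildcard-only encounters, occasional zero-encounter patients.
random_toy_cohort <- function(seed) {
  set.seed(seed)
  pool <- c(
    "language_interpreter", "fear", "transportation",
    "social_practical_support", "housing"
  )
  n_pat <- sample(2:10, 1)
  ids <- sprintf("P%02d", seq_len(n_pat))
  patients <- make_patients(ids,
    age = sample(30:80, n_pat, TRUE),
    occupation = sample(c("homemaker", "retired", "service"), n_pat, TRUE)
  )
  rows <- list()
  for (pid in ids) {
    k <- sample(0:5, 1)
    if (k == 0) next
    codes <- lapply(seq_len(k), function(i) {
      if (stats::runif(1) < 0.15) {
        return("none")
      }
      sample(pool, sample(1:3, 1))
    })
    rows[[pid]] <- make_encounters(rep(pid, k), codes,
      dates = as.character(as.Date("2015-01-01") + sample(1:300, k))
    )
  }
  encounters <- if (length(rows)) dplyr::bind_rows(rows) else
    make_encounters(character(0), list())
  list(patients = patients, encounters = encounters)
}
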