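# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so generation never perturbs user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

site_a_codebook <- function() {
  list(
    occupation = c("homemaker", "professional", "retired", "service",
                   "student", "unemployed"),
    marital_status = c("divorced", "married", "single", "widowed"),
    education_level = c("college", "high_school", "none", "primary"),
    english_level = c("fair", "good", "none", "poor"),
    origin = c("china", "hong_kong", "other", "us", "vietnam"),
    born_in_us = c("no", "yes"),
    income_range = c("25k_50k", "50k_75k", "chose_not_to_answer",
                     "over_75k", "under_25k"),
    zip_code = c("60608", "60609", "60616", "60632", "60653"),
    preferred_language = c("cantonese", "english", "mandarin", "toishanese"),
    all_languages = c("cantonese", "cantonese;english", "english",
                      "mandarin", "mandarin;english", "toishanese"),
    service_type = c("education", "follow_up", "referral", "screening"),
    channel = c("email", "in_person", "phone"),
    action_taken = c("education_provided", "insurance_assistance",
                     "interpretation", "referral_made",
                     "scheduled_appointment", "transport_arranged")
  )
}

default_topic_spec <- function() {
  list(
    interpreter = c("interpreter", "translate", "cantonese", "mandarin",
                    "language", "speak", "english", "form", "explain",
                    "accompany", "call", "clinic"),
    transport = c("bus", "ride", "drive", "car", "transit", "pickup",
                  "route", "far", "travel", "station", "arrange", "fare"),
    insurance = c("insurance", "coverage", "medicaid", "premium", "card",
                  "enroll", "application", "eligibility", "copay", "plan",
                  "renew", "paperwork"),
    fear = c("worried", "afraid", "anxious", "scared", "reassure",
             "nervous", "concern", "pain", "biopsy", "result", "comfort",
             "calm"),
    scheduling = c("appointment", "schedule", "reschedule", "reminder",
                   "clinic", "slot", "confirm", "followup", "date",
                   "calendar", "cancel", "visit"),
    family = c("daughter", "husband", "family", "support", "home",
               "childcare", "care", "alone", "neighbor", "help", "son",
               "household")
  )
}

# Each link attaches a barrier to one demographic level; links use
# mutually exclusive levels within an attribute so the induced label
# distribution stays multi-class (overlapping links would collapse
# onto the globally most frequent code through the salience rule).
default_signal_map <- function() {
  tibble::tribble(
    ~sdoh,                       ~attribute,        ~level,        ~coef,
    "fear",                      "english_level",   "none",        1,
    "communication_with_medical_personnel", "english_level", "poor", 1,
    "transportation",            "occupation",      "retired",     1,
    "financial_problems",        "occupation",      "unemployed",  1,
    "social_practical_support",  "occupation",      "homemaker",   1,
    "work_schedule_conflicts",   "occupation",      "service",     1,
    "insurance_uninsured",       "income_range",    "under_25k",   1,
    "perceptions_beliefs_tests_treatment", "education_level", "primary", 1
  )
}

default_topic_map <- function() {
  tibble::tribble(
    ~sdoh,                      ~topic,        ~coef,
    "transportation",           "transport",   1.5,
    "fear",                     "fear",        1.5,
    "insurance_uninsured",      "insurance",   1.5,
    "system_problems_scheduling", "scheduling", 1.5,
    "social_practical_support", "family",      1.5,
    "language_interpreter",     "interpreter", 1
  )
}

default_base_rates <- function(taxonomy = sdoh_taxonomy()) {
  rates <- stats::setNames(rep(0.01, length(taxonomy$codes)), taxonomy$codes)
  rates["language_interpreter"] <- 0.45
  rates["social_practical_support"] <- 0.10
  rates["fear"] <- 0.08
  rates["insurance_uninsured"] <- 0.06
  rates["financial_problems"] <- 0.05
  rates["transportation"] <- 0.05
  rates["perceptions_beliefs_tests_treatment"] <- 0.04
  rates["communication_with_medical_personnel"] <- 0.03
  rates["system_problems_scheduling"] <- 0.03
  rates["other"] <- 0.02
  rates
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the generating model for a synthetic two-site navigation
#' cohort: per-patient encounter counts are negative-binomial with the
#' published cohort mean 16.94 and SD 13.06; each encounter carries an
#' independent Bernoulli draw per SDoH category (so zero or more codes
#' per encounter, `"none"` when no category fires), with per-category
#' log-odds shifted by the patient's demographics and the encounter's
#' latent note-topic mixture; notes are bag-of-words samples from the
#' topic mixture (length ~ Poisson). One dominant category
#' (language/interpreter, base rate 0.45) mirrors the heavy class
#' imbalance of language-discordant navigation cohorts.
#'
#' @param n_patients Number of patients (default 330, a realistic
#'   single-study cohort size).
#' @param encounter_mean,encounter_sd Mean/SD of the per-patient
#'   encounter-count distribution (negative binomial; counts clipped to
#'   a minimum of 1).
#' @param sdoh_base_rates Named per-encounter firing probability for
#'   each taxonomy code.
#' @param signal_strength Scalar multiplier on the demographic and
#'   topic log-odds coefficient maps; 0 removes all signal.
#' @param signal_map Tibble (`sdoh`, `attribute`, `level`, `coef`) of
#'   demographic log-odds shifts.
#' @param topic_map Tibble (`sdoh`, `topic`, `coef`) of note-topic
#'   log-odds shifts (applied as `coef * topic_proportion`).
#' @param topic_spec Named list of per-topic word vectors for note
#'   generation.
#' @param note_length_mean Mean Poisson note length in tokens.
#' @param missingness Named per-column missingness rates.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 330,
                          encounter_mean = 16.94,
                          encounter_sd = 13.06,
                          sdoh_base_rates = default_base_rates(),
                          signal_strength = 1,
                          signal_map = default_signal_map(),
                          topic_map = default_topic_map(),
                          topic_spec = default_topic_spec(),
                          note_length_mean = 12,
                          missingness = c(
                            occupation = 0.03, marital_status = 0.03,
                            education_level = 0.03, income_range = 0.03,
                            comments = 0.05
                          ),
                          seed = 1L) {
  if (any(sdoh_base_rates < 0 | sdoh_base_rates > 1)) {
    stop("Config error: sdoh_base_rates must lie in [0, 1]", call. = FALSE)
  }
  if (encounter_sd^2 <= encounter_mean) {
    stop("Config error: encounter counts must be overdispersed ",
      "(sd^2 > mean) for the negative binomial",
      call. = FALSE
    )
  }
  if (note_length_mean <= 0 || n_patients < 1) {
    stop("Config error: degenerate distribution parameters", call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      encounter_mean = encounter_mean,
      encounter_sd = encounter_sd,
      sdoh_base_rates = sdoh_base_rates,
      signal_strength = signal_strength,
      signal_map = signal_map,
      topic_map = topic_map,
      topic_spec = topic_spec,
      note_length_mean = note_length_mean,
      missingness = missingness,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

sample_patients <- function(n, codebook, site = "A") {
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, 55, 11)), 21), 90),
    occupation = sample(codebook$occupation, n, TRUE,
      prob = c(0.25, 0.1, 0.2, 0.2, 0.05, 0.2)
    ),
    marital_status = sample(codebook$marital_status, n, TRUE,
      prob = c(0.08, 0.62, 0.15, 0.15)
    ),
    education_level = sample(codebook$education_level, n, TRUE,
      prob = c(0.15, 0.35, 0.15, 0.35)
    ),
    year_arrived_us = pmin(round(stats::rnorm(n, 1998, 9)), 2018),
    english_level = sample(codebook$english_level, n, TRUE,
      prob = c(0.3, 0.1, 0.35, 0.25)
    ),
    origin = sample(codebook$origin, n, TRUE,
      prob = c(0.6, 0.2, 0.05, 0.05, 0.1)
    ),
    zip_code = sample(codebook$zip_code, n, TRUE,
      prob = c(0.2, 0.15, 0.4, 0.15, 0.1)
    ),
    household_size = 1 + stats::rpois(n, 2),
    born_in_us = sample(codebook$born_in_us, n, TRUE, prob = c(0.92, 0.08)),
    income_range = sample(codebook$income_range, n, TRUE,
      prob = c(0.25, 0.1, 0.15, 0.05, 0.45)
    ),
    site = site
  )
}

demo_logit_shift <- function(patient_row, signal_map, signal_strength) {
  if (nrow(signal_map) == 0 || signal_strength == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  hits <- vapply(seq_len(nrow(signal_map)), function(i) {
    as.character(patient_row[[signal_map$attribute[i]]]) == signal_map$level[i]
  }, logical(1))
  shift <- tapply(
    signal_map$coef * hits * signal_strength, signal_map$sdoh, sum
  )
  stats::setNames(as.numeric(shift), names(shift))
}

sample_note <- function(theta, topic_spec, mean_len) {
  len <- stats::rpois(1, mean_len)
  if (len == 0) len <- 1
  topics <- sample(names(topic_spec), len, TRUE, prob = theta)
  words <- vapply(topics, function(tp) sample(topic_spec[[tp]], 1), character(1))
  paste(words, collapse = " ")
}

#' Generate a synthetic site-A navigation cohort
#'
#' Samples patients, their encounter histories (notes, coded SDoHs,
#' interaction metadata) and the generating ground truth from a
#' [cohort_config()]. The same config (including its seed) always yields
#' byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `patients`, `encounters`, and
#'   `ground_truth` (per-patient true SDoH set and per-encounter topic
#'   mixtures, with the generating coefficient maps attached as
#'   attributes).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  codebook <- site_a_codebook()
  taxonomy <- sdoh_taxonomy()
  topics <- names(config$topic_spec)
  mu <- config$encounter_mean
  size <- mu^2 / (config$encounter_sd^2 - mu)

  with_seed(config$seed, {
    patients <- sample_patients(config$n_patients, codebook, site = "A")
    n_enc <- pmax(1L, stats::rnbinom(config$n_patients, size = size, mu = mu))

    enc_rows <- vector("list", config$n_patients)
    gt_rows <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      p <- patients[i, ]
      shift <- demo_logit_shift(p, config$signal_map, config$signal_strength)
      k <- n_enc[i]
      start <- as.Date("2014-01-01") + sample.int(1200, 1)
      dates <- sort(start + sample.int(900, k, replace = TRUE))
      thetas <- matrix(0, k, length(topics), dimnames = list(NULL, topics))
      codes <- vector("list", k)
      notes <- character(k)
      for (j in seq_len(k)) {
        theta <- stats::setNames(rdirichlet1(rep(0.5, length(topics))), topics)
        thetas[j, ] <- theta
        logit <- stats::qlogis(config$sdoh_base_rates)
        if (length(shift)) {
          logit[names(shift)] <- logit[names(shift)] + shift
        }
        if (nrow(config$topic_map) > 0 && config$signal_strength != 0) {
          tshift <- config$topic_map$coef * config$signal_strength *
            theta[config$topic_map$topic]
          agg <- tapply(tshift, config$topic_map$sdoh, sum)
          logit[names(agg)] <- logit[names(agg)] + as.numeric(agg)
        }
        fired <- names(logit)[stats::runif(length(logit)) < stats::plogis(logit)]
        codes[[j]] <- if (length(fired) == 0) taxonomy$wildcard else fired
        notes[j] <- sample_note(theta, config$topic_spec,
          config$note_length_mean)
      }
      enc_rows[[i]] <- tibble::tibble(
        patient_id = p$patient_id,
        encounter_date = as.character(dates),
        preferred_language = sample(codebook$preferred_language, k, TRUE,
          prob = c(0.45, 0.1, 0.2, 0.25)
        ),
        all_languages = sample(codebook$all_languages, k, TRUE),
        service_type = sample(codebook$service_type, k, TRUE),
        channel = sample(codebook$channel, k, TRUE, prob = c(0.1, 0.4, 0.5)),
        action_taken = sample(codebook$action_taken, k, TRUE),
        action_length = pmax(2, round(stats::rgamma(k, shape = 4, scale = 6))),
        comments = notes,
        sdoh_codes = codes,
        site = "A"
      )
      gt_rows[[i]] <- tibble::tibble(
        patient_id = p$patient_id,
        true_sdoh = list(sort(unique(setdiff(
          unlist(codes), taxonomy$wildcard
        )))),
        n_encounters = k,
        topic_mixture = list(thetas)
      )
    }
    encounters <- dplyr::bind_rows(enc_rows)
    ground_truth <- dplyr::bind_rows(gt_rows)

    # Missingness injection, after ground truth is fixed.
    for (cl in names(config$missingness)) {
      rate <- config$missingness[[cl]]
      if (rate <= 0) next
      if (cl %in% names(patients)) {
        hit <- stats::runif(nrow(patients)) < rate
        patients[[cl]][hit] <- NA
      } else if (cl %in% names(encounters)) {
        hit <- stats::runif(nrow(encounters)) < rate
        if (cl == "sdoh_codes") {
          encounters$sdoh_codes[hit] <- list(NULL)
        } else {
          encounters[[cl]][hit] <- NA
        }
      }
    }

    attr(ground_truth, "signal_map") <- config$signal_map
    attr(ground_truth, "topic_map") <- config$topic_map
    attr(ground_truth, "signal_strength") <- config$signal_strength
    list(
      patients = patients, encounters = encounters,
      ground_truth = ground_truth
    )
  })
}

#' Generate a synthetic site-B navigation cohort
#'
#' Site B uses an incompatible codebook: employment collapses to 3
#' levels (`unemployed`, `part_time`, `full_time`), each encounter
#' records exactly one SDoH as a generic/specific code pair together
#' with an action, and no note text is kept.
#'
#' @param config A [cohort_config()].
#' @return A list with tibbles `patients` and `encounters`.
#' @export
generate_site_b <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  codebook <- site_a_codebook()
  alias <- default_alias_map()
  unified_of <- map_sdoh_code(alias$site_b_code, alias)

  # Preferred site-B code for each unified category: first specific
  # child if one exists, else the generic code.
  pick_code <- function(u) {
    cand <- alias$site_b_code[unified_of == u]
    if (length(cand) == 0) {
      return(NA_character_)
    }
    specific <- cand[!is.na(alias$generic_parent[match(cand, alias$site_b_code)])]
    if (length(specific) > 0) specific[1] else cand[1]
  }

  with_seed(config$seed + 1L, {
    patients <- sample_patients(config$n_patients, codebook, site = "B")
    patients$occupation <- sample(
      c("unemployed", "part_time", "full_time"),
      config$n_patients, TRUE,
      prob = c(0.35, 0.3, 0.35)
    )
    mu <- config$encounter_mean
    size <- mu^2 / (config$encounter_sd^2 - mu)
    n_enc <- pmax(1L, stats::rnbinom(config$n_patients, size = size, mu = mu))

    rows <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      p <- patients[i, ]
      shift <- demo_logit_shift(p, config$signal_map, config$signal_strength)
      k <- n_enc[i]
      logit <- stats::qlogis(config$sdoh_base_rates)
      if (length(shift)) {
        keep <- intersect(names(shift), names(logit))
        logit[keep] <- logit[keep] + shift[keep]
      }
      w <- c(stats::plogis(logit), none = 0.5)
      cats <- sample(names(w), k, TRUE, prob = w / sum(w))
      site_b <- vapply(cats, pick_code, character(1))
      site_b[is.na(site_b)] <- "case_management"
      parent <- alias$generic_parent[match(site_b, alias$site_b_code)]
      start <- as.Date("2009-06-01") + sample.int(900, 1)
      rows[[i]] <- tibble::tibble(
        patient_id = p$patient_id,
        encounter_date = as.character(sort(start + sample.int(700, k, TRUE))),
        preferred_language = sample(c("english", "spanish", "other"), k, TRUE,
          prob = c(0.4, 0.45, 0.15)
        ),
        all_languages = sample(c("english", "spanish", "spanish;english"),
          k, TRUE
        ),
        service_type = sample(codebook$service_type, k, TRUE),
        channel = sample(codebook$channel, k, TRUE),
        action_taken = sample(codebook$action_taken, k, TRUE),
        action_length = pmax(2, round(stats::rgamma(k, shape = 4, scale = 6))),
        sdoh_generic = ifelse(is.na(parent), site_b, parent),
        sdoh_specific = ifelse(is.na(parent), NA_character_, site_b),
        site = "B"
      )
    }
    list(patients = patients, encounters = dplyr::bind_rows(rows))
  })
}

#' Summarise generator ground truth
#'
#' @param ground_truth The `ground_truth` tibble from [generate_cohort()].
#' @return A tibble with one row per patient: `patient_id`, the
#'   `;`-joined true SDoH set, its size, and the encounter count.
#' @export
ground_truth_report <- function(ground_truth) {
  if (nrow(ground_truth) == 0) {
    return(tibble::tibble(
      patient_id = character(), true_sdoh = character(),
      n_true_sdoh = integer(), n_encounters = integer()
    ))
  }
  tibble::tibble(
    patient_id = ground_truth$patient_id,
    true_sdoh = vapply(ground_truth$true_sdoh, paste,
      character(1), collapse = ";"
    ),
    n_true_sdoh = vapply(ground_truth$true_sdoh, length, integer(1)),
    n_encounters = ground_truth$n_encounters
  )
}

#' Simulate multi-label data with planted boolean rules
#'
#' Benchmark generator for the multi-label network: three binary driver
#' features determine five class labels through fixed boolean rules
#' (every row has at most three active labels), embedded among noise
#' features. Because the rules are deterministic, a working classifier
#' should approach perfect per-class accuracy — this is the package's
#' planted-rule oracle for validating the network end to end.
#'
#' @param n Number of rows.
#' @param n_noise Number of additional uninformative binary features.
#' @param seed Integer seed.
#' @return A list with `X` (numeric matrix, drivers first), `Y` (0/1
#'   label matrix, 5 columns), and `rules` (text description).
#' @export
simulate_planted_multilabel <- function(n = 1500, n_noise = 17, seed = 1L) {
  with_seed(seed, {
    a <- stats::rbinom(n, 1, 0.5)
    b <- stats::rbinom(n, 1, 0.5)
    cc <- stats::rbinom(n, 1, 0.5)
    noise <- matrix(stats::rbinom(n * n_noise, 1, 0.5), n, n_noise)
    X <- cbind(a = a, b = b, c = cc, noise)
    colnames(X) <- c("a", "b", "c", paste0("z", seq_len(n_noise)))
    Y <- cbind(
      class_1 = a,
      class_2 = as.integer(b == 1 & a == 0),
      class_3 = cc,
      class_4 = as.integer(a == 1 & b == 1),
      class_5 = as.integer(b == 1 & cc == 0)
    )
    list(
      X = X, Y = Y,
      rules = c(
        "class_1 = a", "class_2 = b & !a", "class_3 = c",
        "class_4 = a & b", "class_5 = b & !c"
      )
    )
  })
}
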