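#' Corpus-wide SDoH code frequencies
#'
#' Counts every code occurrence across all retained encounters; used to
#' pick the most salient code when an encounter lists several.
#'
#' @param encounters Encounter tibble with a `sdoh_codes` list-column.
#' @param include_wildcard Count the wildcard `"none"`? Off by default:
#'   the single-label analysis predicts substantive barriers only.
#' @return Named integer vector of counts.
#' @export
corpus_frequencies <- function(encounters, include_wildcard = FALSE) {
  codes <- unlist(encounters$sdoh_codes)
  codes <- codes[!is.na(codes)]
  if (!include_wildcard) codes <- codes[codes != sdoh_taxonomy()$wildcard]
  tab <- table(codes)
  stats::setNames(as.integer(tab), names(tab))
}

# Encounters usable for single-label instance building: at least one
# substantive (non-wildcard) code. Visits whose only annotation is
# "none" carry no predictable barrier and are excluded, mirroring the
# exclusion of visits without a recorded SDoH.
retain_labelled_encounters <- function(encounters,
                                       wildcard = sdoh_taxonomy()$wildcard) {
  enc <- encounters
  enc$sdoh_codes <- lapply(enc$sdoh_codes, function(x) {
    x <- x[!is.na(x)]
    x[x != wildcard]
  })
  keep <- vapply(enc$sdoh_codes, length, integer(1)) > 0
  enc[keep, , drop = FALSE]
}

#' Most salient SDoH code of an encounter
#'
#' When a navigator records several codes on one encounter, the single
#' most salient one is the code with the highest corpus-wide frequency
#' of occurrence; ties break lexicographically.
#'
#' @param codes Character vector of the encounter's codes (length >= 1).
#' @param corpus_frequencies Named counts from [corpus_frequencies()].
#' @return A single code.
#' @examples
#' salient_sdoh(c("fear", "transportation"),
#'   c(fear = 40, transportation = 10))
#' @export
salient_sdoh <- function(codes, corpus_frequencies) {
  if (length(codes) == 0 || all(is.na(codes))) {
    stop("salient_sdoh: encounter has no SDoH codes ",
      "(such encounters are dropped upstream)",
      call. = FALSE
    )
  }
  codes <- unique(codes[!is.na(codes)])
  freq <- corpus_frequencies[codes]
  freq[is.na(freq)] <- 0L
  winners <- codes[freq == max(freq)]
  sort(winners)[1]
}

order_encounters <- function(encounters) {
  if ("encounter_date" %in% names(encounters)) {
    encounters[order(as.Date(encounters$encounter_date),
      seq_len(nrow(encounters))
    ), , drop = FALSE]
  } else {
    encounters
  }
}

#' Aggregate a window of encounters into one feature bundle
#'
#' Numeric fields are averaged, categorical fields take the most common
#' value (lexicographic tie-break), and notes are concatenated in order
#' into a single text for topic inference.
#'
#' @param encounters Encounter tibble (>= 1 row), already in
#'   chronological order.
#' @return One-row tibble of aggregated encounter features.
#' @export
aggregate_encounter_features <- function(encounters) {
  stopifnot(nrow(encounters) >= 1)
  cat_cols <- c(
    "preferred_language", "all_languages", "service_type",
    "channel", "action_taken"
  )
  cat_cols <- intersect(cat_cols, names(encounters))
  out <- lapply(cat_cols, function(cl) stat_mode(encounters[[cl]]))
  names(out) <- cat_cols
  if ("action_length" %in% names(encounters)) {
    out$action_length <- mean(encounters$action_length, na.rm = TRUE)
  }
  if ("comments" %in% names(encounters)) {
    txt <- encounters$comments[!is.na(encounters$comments)]
    out$comments <- paste(txt, collapse = " ")
  }
  tibble::as_tibble(out)
}

# Strategy-1 labelling of one patient: scan encounters chronologically;
# the first encounter whose salient code is not the dominant
# language/interpreter code sets the label, and encounters up to and
# including it form the aggregation window. If every encounter is
# language/interpreter, the label is language/interpreter and only the
# first encounter is used.
label_patient_s1_idx <- function(salients, dominant) {
  j <- which(salients != dominant)
  if (length(j) == 0) {
    list(label = dominant, window = 1L)
  } else {
    list(label = salients[j[1]], window = seq_len(j[1]))
  }
}

#' Label one patient under preparation strategy 1
#'
#' @param patient One-row patient tibble.
#' @param encounters That patient's retained encounters.
#' @param corpus_frequencies Named counts from [corpus_frequencies()]
#'   over the whole dataset.
#' @param taxonomy An [sdoh_taxonomy()].
#' @return A one-row tibble: patient demographics, aggregated encounter
#'   features, `label`, and provenance columns `n_encounters_used` /
#'   `source_rows`.
#' @export
label_patient_s1 <- function(patient, encounters, corpus_frequencies,
                             taxonomy = sdoh_taxonomy()) {
  if (nrow(encounters) == 0) {
    stop("label_patient_s1: patient has no retained encounters", call. = FALSE)
  }
  encounters <- order_encounters(encounters)
  salients <- vapply(
    encounters$sdoh_codes, salient_sdoh, character(1),
    corpus_frequencies = corpus_frequencies
  )
  res <- label_patient_s1_idx(salients, taxonomy$dominant)
  window <- encounters[res$window, , drop = FALSE]
  feats <- aggregate_encounter_features(window)
  dplyr::bind_cols(
    patient[, setdiff(names(patient), "site"), drop = FALSE],
    feats,
    tibble::tibble(
      label = res$label,
      n_encounters_used = length(res$window),
      source_rows = paste(res$window, collapse = ";")
    )
  )
}

#' Build labelled instances under one of the six preparation strategies
#'
#' Turns a cohort's patients and encounters into single-label training
#' instances:
#' * **s1** — each patient is one instance; encounters are aggregated up
#'   to (and including) the first encounter whose salient SDoH is not
#'   language/interpreter, which supplies the label; all-language
#'   patients keep the language label and only their first encounter.
#' * **s2** — s1 minus instances labelled language/interpreter.
#' * **s3** — each encounter is one instance (demographics repeated);
#'   the label is that encounter's salient SDoH.
#' * **s4** — s3 minus language-labelled instances.
#' * **s5** — s1 labels with all encounter-derived features removed.
#' * **s6** — s2 labels with all encounter-derived features removed.
#'
#' Retained encounters are those carrying at least one substantive
#' SDoH code: visits annotated only with the wildcard `"none"` are
#' excluded (they carry no predictable barrier), as are patients with
#' zero retained encounters (recorded in the `skipped` attribute).
#'
#' @param patients,encounters Imputed tibbles from [impute_missing()].
#' @param strategy One of `"s1"`..`"s6"`.
#' @param taxonomy An [sdoh_taxonomy()].
#' @return A tibble of labelled instances with columns `instance_id`,
#'   demographics, (for s1–s4) encounter features incl. `comments`,
#'   `label`, and provenance.
#' @export
apply_strategy <- function(patients, encounters, strategy,
                           taxonomy = sdoh_taxonomy()) {
  strategy <- tolower(strategy)
  if (!strategy %in% paste0("s", 1:6)) {
    stop("Unknown strategy: ", strategy, call. = FALSE)
  }
  encounters <- retain_labelled_encounters(encounters, taxonomy$wildcard)
  freqs <- corpus_frequencies(encounters)
  enc_by_patient <- split(encounters, encounters$patient_id)
  skipped <- setdiff(patients$patient_id, names(enc_by_patient))

  demo_cols <- setdiff(names(patients), "site")

  if (strategy %in% c("s1", "s2", "s5", "s6")) {
    rows <- lapply(seq_len(nrow(patients)), function(i) {
      pid <- patients$patient_id[i]
      enc <- enc_by_patient[[pid]]
      if (is.null(enc) || nrow(enc) == 0) {
        return(NULL)
      }
      label_patient_s1(patients[i, ], enc, freqs, taxonomy)
    })
    out <- dplyr::bind_rows(rows)
    if (strategy %in% c("s2", "s6")) {
      out <- out[out$label != taxonomy$dominant, , drop = FALSE]
    }
    if (strategy %in% c("s5", "s6")) {
      out <- out[, c(demo_cols, "label", "n_encounters_used", "source_rows"),
        drop = FALSE
      ]
    }
  } else {
    enc <- order_encounters(encounters)
    keep <- enc$patient_id %in% patients$patient_id
    enc <- enc[keep, , drop = FALSE]
    salients <- vapply(
      enc$sdoh_codes, salient_sdoh, character(1),
      corpus_frequencies = freqs
    )
    demo <- patients[match(enc$patient_id, patients$patient_id),
      demo_cols,
      drop = FALSE
    ]
    feat_cols <- intersect(
      c(
        "preferred_language", "all_languages", "service_type", "channel",
        "action_taken", "action_length", "comments"
      ),
      names(enc)
    )
    out <- dplyr::bind_cols(
      demo,
      enc[, feat_cols, drop = FALSE],
      tibble::tibble(
        label = salients,
        n_encounters_used = 1L,
        source_rows = as.character(seq_len(nrow(enc)))
      )
    )
    if (strategy == "s4") {
      out <- out[out$label != taxonomy$dominant, , drop = FALSE]
    }
  }
  out <- dplyr::mutate(out,
    instance_id = sprintf("%s_%04d", strategy, dplyr::row_number()),
    .before = 1
  )
  attr(out, "strategy") <- strategy
  attr(out, "skipped") <- skipped
  out
}

#' Feature columns of an instance table
#'
#' Splits an [apply_strategy()] output into categorical, numeric and
#' text feature column names (excluding identifiers, label and
#' provenance).
#'
#' @param instances Instance tibble.
#' @return List with `categorical`, `numeric`, `text` character vectors.
#' @export
instance_feature_columns <- function(instances) {
  drop <- c(
    "instance_id", "patient_id", "label", "n_encounters_used",
    "source_rows", "site"
  )
  cols <- setdiff(names(instances), drop)
  numeric <- cols[vapply(instances[cols], is.numeric, logical(1))]
  text <- intersect("comments", cols)
  list(
    categorical = setdiff(cols, c(numeric, text)),
    numeric = numeric,
    text = text
  )
}
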