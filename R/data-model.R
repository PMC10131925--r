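#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib navsdoh, .registration = TRUE
NULL

# Column schemas for the two tracking-log tables. Site B drops the
# note column and records one generic/specific SDoH pair per encounter.
patient_schema <- function() {
  list(
    required = c(
      "patient_id", "age", "occupation", "marital_status", "education_level",
      "year_arrived_us", "english_level", "origin", "zip_code",
      "household_size", "born_in_us", "income_range"
    ),
    optional = "site",
    numeric = c("age", "year_arrived_us", "household_size")
  )
}

encounter_schema <- function(site = c("A", "B")) {
  site <- match.arg(site)
  if (site == "A") {
    list(
      required = c(
        "patient_id", "encounter_date", "preferred_language",
        "all_languages", "service_type", "channel", "action_taken",
        "action_length", "comments", "sdoh_codes"
      ),
      optional = "site",
      numeric = "action_length"
    )
  } else {
    list(
      required = c(
        "patient_id", "encounter_date", "preferred_language",
        "all_languages", "service_type", "channel", "action_taken",
        "action_length", "sdoh_generic", "sdoh_specific"
      ),
      optional = "site",
      numeric = "action_length"
    )
  }
}

# Tokens normalised to NA on read; NA is the package's missing sentinel.
missing_tokens <- function() c("", "NA", "N/A", "na", "missing", "unknown")

normalize_missing <- function(x) {
  if (is.character(x)) {
    x[trimws(x) %in% missing_tokens()] <- NA_character_
    x <- trimws(x)
    x[x == ""] <- NA_character_
  }
  x
}

check_schema <- function(tbl, schema, what) {
  miss <- setdiff(schema$required, names(tbl))
  if (length(miss) > 0) {
    stop(
      "Schema error in ", what, ": missing mandatory column(s) ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(tbl), c(schema$required, schema$optional))
  if (length(extra) > 0) {
    warning(
      "Ignoring unknown column(s) in ", what, ": ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
    tbl <- tbl[, setdiff(names(tbl), extra), drop = FALSE]
  }
  tbl
}

#' Parse a patient-navigation tracking log
#'
#' Reads the demographics and encounter tables of a navigation tracking
#' log (CSV files or data frames), validates their schemas, normalises
#' declared missing-value tokens and empty cells to `NA`, and checks
#' referential integrity of `patient_id`. Multi-valued SDoH codes are
#' stored as a list-column (`sdoh_codes`), written as `;`-separated
#' strings on disk. No imputation happens here: see [impute_missing()].
#'
#' @param demographics CSV path or data frame with the per-patient
#'   demographic attributes.
#' @param encounters CSV path or data frame with per-encounter records.
#' @param taxonomy An [sdoh_taxonomy()]; encounter codes outside
#'   `sdoh_labels(taxonomy)` raise an error.
#' @param site `"A"` (notes + multi-code encounters) or `"B"`
#'   (generic/specific single-code encounters, no notes).
#' @return A list with tibbles `patients` and `encounters`, row order
#'   preserved.
#' @export
parse_tracking_log <- function(demographics, encounters,
                               taxonomy = sdoh_taxonomy(),
                               site = c("A", "B")) {
  site <- match.arg(site)
  read_tbl <- function(x) {
    if (is.character(x)) {
      readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE, show_col_types = FALSE, comment = "#"
      )
    } else {
      dplyr::mutate(tibble::as_tibble(x), dplyr::across(dplyr::everything(), as.character))
    }
  }
  pat <- read_tbl(demographics)
  enc <- read_tbl(encounters)

  ps <- patient_schema()
  es <- encounter_schema(site)
  pat <- check_schema(pat, ps, "demographics")
  enc <- check_schema(enc, es, "encounters")

  pat <- dplyr::mutate(pat, dplyr::across(dplyr::everything(), normalize_missing))
  enc <- dplyr::mutate(enc, dplyr::across(dplyr::everything(), normalize_missing))

  for (cl in ps$numeric) pat[[cl]] <- as.numeric(pat[[cl]])
  for (cl in es$numeric) enc[[cl]] <- as.numeric(enc[[cl]])
  if (!"site" %in% names(pat)) pat$site <- site
  if (!"site" %in% names(enc)) enc$site <- site

  bad_age <- which(!is.na(pat$age) & pat$age < 0)
  if (length(bad_age) > 0) {
    stop("Invalid negative age in demographics row(s) ",
      paste(bad_age, collapse = ", "),
      call. = FALSE
    )
  }

  unknown <- setdiff(unique(enc$patient_id), pat$patient_id)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown) > 0) {
    stop(
      "Referential error: encounter patient_id(s) absent from demographics: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  if (site == "A") {
    enc$sdoh_codes <- lapply(
      strsplit(ifelse(is.na(enc$sdoh_codes), "", enc$sdoh_codes), ";",
        fixed = TRUE
      ),
      function(x) {
        x <- trimws(x[x != ""])
        if (length(x) == 0) NULL else x
      }
    )
    all_codes <- unique(unlist(enc$sdoh_codes))
    bad <- setdiff(all_codes, sdoh_labels(taxonomy))
    if (length(bad) > 0) {
      stop("Unknown SDoH code(s) in encounters: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }

  list(patients = pat, encounters = enc)
}

#' Write a tracking log back to CSV
#'
#' Inverse of [parse_tracking_log()]: the written files re-parse to
#' value-identical tables.
#'
#' @param log A list with `patients` and `encounters` tibbles.
#' @param demographics_path,encounters_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_tracking_log <- function(log, demographics_path, encounters_path) {
  enc <- log$encounters
  if (is.list(enc$sdoh_codes) && !is.character(enc$sdoh_codes)) {
    enc$sdoh_codes <- vapply(
      enc$sdoh_codes,
      function(x) if (is.null(x)) NA_character_ else paste(x, collapse = ";"),
      character(1)
    )
  }
  readr::write_csv(log$patients, demographics_path, na = "", progress = FALSE)
  readr::write_csv(enc, encounters_path, na = "", progress = FALSE)
  invisible(c(demographics_path, encounters_path))
}

# Most common value; ties broken lexicographically (deterministic,
# seed-free).
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(NA_character_)
  }
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Impute missing tracking-log values
#'
#' Missing numeric cells become the arithmetic mean of the observed
#' values in that column; missing categorical cells become the most
#' common observed value (ties broken lexicographically). Encounters
#' with a missing note or no recorded SDoH code are dropped — those
#' visits carry no usable label or text — before any encounter-side
#' imputation. An all-missing column is an error.
#'
#' @param patients,encounters Tibbles from [parse_tracking_log()].
#' @param drop_encounters Should encounters missing `comments` or
#'   `sdoh_codes` be dropped (the site-A rule)? Ignored for tables
#'   without those columns.
#' @return A list with `patients`, `encounters`, and a `log` tibble
#'   recording every imputation and drop (`column`, `action`, `n`).
#' @export
impute_missing <- function(patients, encounters, drop_encounters = TRUE) {
  events <- list()
  note <- function(column, action, n) {
    events[[length(events) + 1]] <<- tibble::tibble(
      column = column, action = action, n = n
    )
  }

  impute_tbl <- function(tbl, numeric_cols, skip = character()) {
    for (cl in setdiff(names(tbl), skip)) {
      x <- tbl[[cl]]
      if (is.list(x)) next
      n_miss <- sum(is.na(x))
      if (n_miss == 0) next
      if (n_miss == length(x)) {
        stop("Imputation error: column '", cl, "' is entirely missing",
          call. = FALSE
        )
      }
      if (cl %in% numeric_cols) {
        fill <- mean(x, na.rm = TRUE)
      } else {
        fill <- stat_mode(x)
      }
      x[is.na(x)] <- fill
      tbl[[cl]] <- x
      note(cl, if (cl %in% numeric_cols) "mean" else "mode", n_miss)
    }
    tbl
  }

  patients <- impute_tbl(patients, patient_schema()$numeric, skip = "patient_id")

  if (drop_encounters && "comments" %in% names(encounters)) {
    drop <- is.na(encounters$comments)
    if ("sdoh_codes" %in% names(encounters)) {
      no_code <- vapply(
        encounters$sdoh_codes,
        function(x) is.null(x) || length(x) == 0 ||
          (length(x) == 1 && is.na(x)),
        logical(1)
      )
      drop <- drop | no_code
    }
    if (any(drop)) note("comments/sdoh_codes", "drop_encounter", sum(drop))
    encounters <- encounters[!drop, , drop = FALSE]
  }
  encounters <- impute_tbl(
    encounters, encounter_schema(encounters$site[1] %||% "A")$numeric,
    skip = c("patient_id", "comments", "sdoh_codes", "encounter_date")
  )

  list(
    patients = patients,
    encounters = encounters,
    log = if (length(events)) dplyr::bind_rows(events) else
      tibble::tibble(column = character(), action = character(), n = integer())
  )
}

#' One-hot encode categorical columns
#'
#' Each categorical value becomes its own 0/1 column (`col=value`);
#' numeric columns pass through unchanged. The returned dictionary
#' allows exact decoding and re-encoding of new data on the same
#' columns.
#'
#' @param tbl A data frame with no missing values in
#'   `categorical_columns`.
#' @param categorical_columns Character vector of columns to expand.
#' @param dictionary Optional dictionary from a previous call, to encode
#'   new data against the same column layout.
#' @param unseen What to do with a category absent from the dictionary:
#'   `"error"` (default) or `"zero"` (all-zero segment).
#' @return A list with `matrix` (numeric matrix) and `dictionary`
#'   (named list: column -> character vector of levels; numeric
#'   passthrough columns map to `NULL`).
#' @examples
#' enc <- one_hot_encode(data.frame(x = c("A", "B", "A")), "x")
#' enc$matrix
#' @export
one_hot_encode <- function(tbl, categorical_columns,
                           dictionary = NULL,
                           unseen = c("error", "zero")) {
  unseen <- match.arg(unseen)
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(categorical_columns %in% names(tbl)))
  if (anyNA(tbl[categorical_columns])) {
    stop("Missing values remain in categorical columns; impute first",
      call. = FALSE
    )
  }
  if (is.null(dictionary)) {
    dictionary <- stats::setNames(
      lapply(names(tbl), function(cl) {
        if (cl %in% categorical_columns) {
          sort(unique(as.character(tbl[[cl]])))
        } else {
          NULL
        }
      }),
      names(tbl)
    )
  }
  blocks <- lapply(names(dictionary), function(cl) {
    levs <- dictionary[[cl]]
    if (is.null(levs)) {
      m <- matrix(as.numeric(tbl[[cl]]), ncol = 1)
      colnames(m) <- cl
      return(m)
    }
    vals <- as.character(tbl[[cl]])
    new <- setdiff(unique(vals), levs)
    if (length(new) > 0 && unseen == "error") {
      stop(
        "Unseen category in column '", cl, "': ",
        paste(new, collapse = ", "),
        call. = FALSE
      )
    }
    m <- matrix(0, nrow = nrow(tbl), ncol = length(levs))
    colnames(m) <- paste0(cl, "=", levs)
    hit <- match(vals, levs)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    m
  })
  list(matrix = do.call(cbind, blocks), dictionary = dictionary)
}

#' Invert a one-hot encoding
#'
#' @param matrix Matrix produced by [one_hot_encode()].
#' @param dictionary The accompanying dictionary.
#' @return A tibble with the original columns (categorical columns as
#'   character, passthrough columns numeric).
#' @export
one_hot_decode <- function(matrix, dictionary) {
  cols <- lapply(names(dictionary), function(cl) {
    levs <- dictionary[[cl]]
    if (is.null(levs)) {
      return(as.numeric(matrix[, cl]))
    }
    seg <- matrix[, paste0(cl, "=", levs), drop = FALSE]
    levs[max.col(seg, ties.method = "first")]
  })
  stats::setNames(tibble::as_tibble(cols, .name_repair = "minimal"), names(dictionary))
}

#' Write a one-hot dictionary as JSON
#'
#' Emitted beside every encoded matrix so encodings are reproducible and
#' reversible outside R.
#'
#' @param dictionary Dictionary from [one_hot_encode()].
#' @param path Output path.
#' @export
write_encoding_dictionary <- function(dictionary, path) {
  jsonlite::write_json(dictionary, path, auto_unbox = FALSE, null = "null")
  invisible(path)
}
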