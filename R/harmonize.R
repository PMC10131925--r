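#' Top-k codes by frequency
#'
#' Orders a patient's compiled code list by descending frequency; ties
#' break by first occurrence, then lexicographically. Fewer than `k`
#' distinct codes leave the remaining slots `NA`.
#'
#' @param codes Character vector (may be empty).
#' @param k Number of slots (default 3).
#' @return Character vector of length `k`.
#' @examples
#' top_k_labels(c(rep("lang", 5), rep("none", 3), rep("fear", 2), "transport"))
#' @export
top_k_labels <- function(codes, k = 3) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) {
    return(rep(NA_character_, k))
  }
  first_seen <- match(unique(codes), codes)
  u <- unique(codes)
  freq <- vapply(u, function(x) sum(codes == x), integer(1))
  ord <- order(-freq, first_seen, u)
  out <- u[ord]
  length(out) <- k
  out
}

# Recodes the 3-level site-B employment codebook toward the richer
# site-A occupation categories.
recode_site_b_employment <- function(x) {
  map <- c(
    unemployed = "unemployed",
    part_time = "service",
    full_time = "professional",
    "part-time" = "service",
    "full time" = "professional"
  )
  out <- unname(map[x])
  ifelse(is.na(out), x, out)
}

# Values outside the unified codebook: anything written in a foreign
# script becomes "none"; otherwise fall back to "chose_not_to_answer"
# or "other" where the attribute offers them, else "none".
sanitize_value <- function(x, allowed) {
  fix_one <- function(v) {
    if (is.na(v) || v %in% allowed) {
      return(v)
    }
    if (grepl("[^\\x01-\\x7F]", v, perl = TRUE)) {
      return("none")
    }
    if ("chose_not_to_answer" %in% allowed) {
      return("chose_not_to_answer")
    }
    if ("other" %in% allowed) {
      return("other")
    }
    "none"
  }
  vapply(x, fix_one, character(1), USE.NAMES = FALSE)
}

#' Consolidate two site cohorts into unified patient records
#'
#' Retains the demographic attributes shared by both sites, recodes
#' site-B values toward the richer site-A codebook (3-level employment
#' expands onto site-A occupation categories), maps site-B SDoH codes
#' through the alias map, compiles each patient's codes and actions
#' across encounters, and fills `barrier_1..3` / `intervention_1..3`
#' with the three most frequent of each. Patients without navigation
#' encounters are excluded; missing numeric cells take the column mean.
#'
#' @param site_a Parsed+imputed site-A log (list with `patients`,
#'   `encounters`; encounters need `sdoh_codes`).
#' @param site_b Parsed site-B log (encounters with
#'   `sdoh_generic`/`sdoh_specific`).
#' @param alias_map Site-B code correspondence, see
#'   [default_alias_map()].
#' @param shared_attributes Demographic columns kept in the unified
#'   schema (must exist at both sites).
#' @return A tibble of unified patient records: shared demographics,
#'   `barrier_1..3`, `intervention_1..3`, `encounter_count`, `site`.
#' @export
harmonize <- function(site_a, site_b, alias_map = default_alias_map(),
                      shared_attributes = c(
                        "age", "occupation", "marital_status",
                        "education_level", "origin", "zip_code",
                        "income_range"
                      )) {
  for (attrb in shared_attributes) {
    if (!attrb %in% names(site_a$patients) ||
      !attrb %in% names(site_b$patients)) {
      stop("Configuration error: shared attribute '", attrb,
        "' absent from a site",
        call. = FALSE
      )
    }
  }
  tax <- sdoh_taxonomy()
  allowed <- c(sdoh_labels(tax), site_a_codebook()$income_range)

  one_site <- function(patients, encounters, codes_fn, site_tag) {
    per_patient <- split(encounters, encounters$patient_id)
    rows <- lapply(names(per_patient), function(pid) {
      enc <- per_patient[[pid]]
      p <- patients[patients$patient_id == pid, , drop = FALSE]
      if (nrow(p) == 0) {
        return(NULL)
      }
      codes <- codes_fn(enc)
      barriers <- top_k_labels(codes, 3)
      interventions <- top_k_labels(enc$action_taken, 3)
      demo <- p[, shared_attributes, drop = FALSE]
      tibble::tibble(
        patient_id = paste0(site_tag, "_", pid),
        demo,
        barrier_1 = barriers[1], barrier_2 = barriers[2],
        barrier_3 = barriers[3],
        intervention_1 = interventions[1],
        intervention_2 = interventions[2],
        intervention_3 = interventions[3],
        encounter_count = nrow(enc),
        site = site_tag
      )
    })
    dplyr::bind_rows(rows)
  }

  rec_a <- one_site(
    site_a$patients, site_a$encounters,
    function(enc) unlist(enc$sdoh_codes), "A"
  )
  pb <- site_b$patients
  pb$occupation <- recode_site_b_employment(pb$occupation)
  rec_b <- one_site(
    pb, site_b$encounters,
    function(enc) {
      raw <- ifelse(is.na(enc$sdoh_specific), enc$sdoh_generic,
        enc$sdoh_specific
      )
      map_sdoh_code(raw, alias_map)
    }, "B"
  )

  out <- dplyr::bind_rows(rec_a, rec_b)

  cat_cols <- shared_attributes[!vapply(out[shared_attributes], is.numeric,
    logical(1)
  )]
  for (cl in cat_cols) {
    out[[cl]] <- sanitize_value(out[[cl]], unique(c(
      allowed, site_a_codebook()[[cl]]
    )))
  }
  num_cols <- shared_attributes[vapply(out[shared_attributes], is.numeric,
    logical(1)
  )]
  for (cl in num_cols) {
    x <- out[[cl]]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    out[[cl]] <- x
  }
  out
}

#' Encounter-intensity bins
#'
#' The fixed reference thresholds: counts below 3 are low (`L`),
#' 3–15 medium (`M`), 16–29 high (`H`), above 29 very high (`VH`).
#'
#' @return An `intensity_bins` object (list with `thresholds`
#'   `c(low = 3, mid = 16, high = 29)` and the generating `mean`/`sd`
#'   when derived from data).
#' @export
fixed_bins <- function() {
  structure(
    list(thresholds = c(low = 3, mid = 16, high = 29),
      mean = NA_real_, sd = NA_real_, mode = "fixed"),
    class = "intensity_bins"
  )
}

#' Derive intensity bins from a cohort's encounter counts
#'
#' Thresholds anchor to the count distribution the way the fixed
#' scheme anchors to its reference cohort (mean 16.94, SD 13.06):
#' the lower threshold at `mean - sd`, the middle at the mean, the
#' upper at `mean + sd`, each rounded to an integer.
#'
#' @param counts Nonempty vector of per-patient encounter counts.
#' @return An `intensity_bins` object.
#' @export
derive_bins <- function(counts) {
  stopifnot(length(counts) > 0)
  m <- mean(counts)
  s <- stats::sd(counts)
  if (is.na(s) || s == 0) {
    stop("Degenerate encounter counts (sd = 0): cannot derive bins; ",
      "use fixed_bins() or supply a varied cohort",
      call. = FALSE
    )
  }
  th <- round(c(low = m - s, mid = m, high = m + s))
  if (any(diff(th) <= 0)) {
    stop("Derived thresholds are not strictly increasing; ",
      "use fixed_bins()",
      call. = FALSE
    )
  }
  structure(
    list(thresholds = th, mean = m, sd = s, mode = "derived"),
    class = "intensity_bins"
  )
}

#' @export
print.intensity_bins <- function(x, ...) {
  cat("<intensity_bins> L < ", x$thresholds["low"],
    " <= M < ", x$thresholds["mid"],
    " <= H <= ", x$thresholds["high"],
    " < VH (", x$mode, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Assign encounter counts to intensity bins
#'
#' `L` below the low threshold, `M` from the low threshold up to (not
#' including) the middle one, `H` from the middle threshold through the
#' high one inclusive, `VH` above it — i.e. with the fixed scheme,
#' counts <3 are L, 3–15 M, 16–29 H, >29 VH. The bins partition the
#' nonnegative integers.
#'
#' @param count Vector of nonnegative encounter counts.
#' @param bins An `intensity_bins` object ([fixed_bins()] or
#'   [derive_bins()]).
#' @return Character vector in `{"L","M","H","VH"}`.
#' @examples
#' intensity_bin(c(2, 3, 16, 29, 30))
#' @export
intensity_bin <- function(count, bins = fixed_bins()) {
  if (any(count < 0)) stop("Negative encounter count", call. = FALSE)
  th <- bins$thresholds
  dplyr::case_when(
    count < th["low"] ~ "L",
    count < th["mid"] ~ "M",
    count <= th["high"] ~ "H",
    TRUE ~ "VH"
  )
}

#' Travel providers: zip-code to nearest-hospital lookups
#'
#' A travel provider maps a zip code to the nearest hospital, its
#' distance, the driving time, and (where available) the public
#' transit time. Live map services sit behind this interface; the
#' package ships two offline providers: a fixture provider backed by a
#' CSV table, and a synthetic provider computing great-circle
#' (haversine) distances between synthetic zip-code centroids and
#' hospital coordinates, with travel times derived from distance at
#' fixed average speeds.
#'
#' @param path CSV with columns `zip`, `hospital_id`, `distance_km`,
#'   `drive_minutes`, `transit_minutes` (empty = unavailable). Defaults
#'   to the fixture shipped with the package.
#' @return A function `zip -> tibble(hospital_id, distance_km,
#'   drive_minutes, transit_minutes)`; unknown zips yield an all-`NA`
#'   row. Deterministic per zip within a run.
#' @export
travel_provider_fixture <- function(path = system.file("extdata",
                                      "travel_fixture.csv",
                                      package = "navsdoh")) {
  tbl <- readr::read_csv(path,
    col_types = readr::cols(
      zip = readr::col_character(),
      hospital_id = readr::col_character(),
      distance_km = readr::col_double(),
      drive_minutes = readr::col_double(),
      transit_minutes = readr::col_double()
    ), progress = FALSE, show_col_types = FALSE
  )
  function(zip) {
    hit <- tbl[match(as.character(zip), tbl$zip), ]
    tibble::tibble(
      hospital_id = hit$hospital_id,
      distance_km = hit$distance_km,
      drive_minutes = hit$drive_minutes,
      transit_minutes = hit$transit_minutes
    )
  }
}

#' @rdname travel_provider_fixture
#' @param zip_coords Tibble (`zip`, `lon`, `lat`) of synthetic zip-code
#'   centroids; defaults to centroids for the synthetic site-A zips.
#' @param hospitals Tibble (`hospital_id`, `lon`, `lat`).
#' @param drive_kmh,transit_kmh Assumed average speeds; transit adds a
#'   10-minute access constant.
#' @export
travel_provider_synthetic <- function(zip_coords = default_zip_coords(),
                                      hospitals = default_hospitals(),
                                      drive_kmh = 40, transit_kmh = 20) {
  function(zip) {
    idx <- match(as.character(zip), zip_coords$zip)
    out <- lapply(idx, function(i) {
      if (is.na(i)) {
        return(tibble::tibble(
          hospital_id = NA_character_, distance_km = NA_real_,
          drive_minutes = NA_real_, transit_minutes = NA_real_
        ))
      }
      d <- geosphere::distHaversine(
        c(zip_coords$lon[i], zip_coords$lat[i]),
        cbind(hospitals$lon, hospitals$lat)
      ) / 1000
      j <- which.min(d)
      tibble::tibble(
        hospital_id = hospitals$hospital_id[j],
        distance_km = d[j],
        drive_minutes = 60 * d[j] / drive_kmh,
        transit_minutes = 10 + 60 * d[j] / transit_kmh
      )
    })
    dplyr::bind_rows(out)
  }
}

#' @rdname travel_provider_fixture
#' @export
default_zip_coords <- function() {
  tibble::tribble(
    ~zip,    ~lon,     ~lat,
    "60608", -87.671,  41.851,
    "60609", -87.652,  41.812,
    "60616", -87.627,  41.847,
    "60632", -87.713,  41.810,
    "60653", -87.613,  41.820
  )
}

#' @rdname travel_provider_fixture
#' @export
default_hospitals <- function() {
  tibble::tribble(
    ~hospital_id, ~lon,     ~lat,
    "HOSP_01",    -87.621,  41.858,
    "HOSP_02",    -87.670,  41.790,
    "HOSP_03",    -87.605,  41.837
  )
}

#' Augment unified records with travel information
#'
#' Fills `nearest_hospital_id`, `distance_km`, `drive_minutes` and
#' `transit_minutes` from a travel provider. Transit times the provider
#' cannot supply are imputed with the mean of the observed transit
#' times; if no transit time is observed at all this is an error
#' (supply a default instead).
#'
#' @param records Unified record tibble with a `zip_code` column.
#' @param provider A travel provider function, e.g.
#'   [travel_provider_fixture()].
#' @return `records` with the four travel columns appended.
#' @export
travel_augment <- function(records, provider = travel_provider_synthetic()) {
  lookup <- provider(records$zip_code)
  if (all(is.na(lookup$transit_minutes))) {
    stop("No transit time available for any record: provide a provider ",
      "with transit coverage or impute a default transit time",
      call. = FALSE
    )
  }
  tm <- lookup$transit_minutes
  tm[is.na(tm)] <- mean(tm, na.rm = TRUE)
  dplyr::mutate(records,
    nearest_hospital_id = lookup$hospital_id,
    distance_km = lookup$distance_km,
    drive_minutes = lookup$drive_minutes,
    transit_minutes = tm
  )
}

#' Binarize unified records for the multi-label model
#'
#' One-hot encodes every string attribute of the unified record table
#' (via the shared encoder) and builds the 0/1 multi-label target
#' matrix: one column per SDoH code, 1 for each of the patient's top-3
#' barriers, so row sums are at most 3.
#'
#' @param records Unified record tibble (from [harmonize()], optionally
#'   [travel_augment()]ed, with an `encounter_range` column if
#'   intensity was added).
#' @param taxonomy An [sdoh_taxonomy()].
#' @return A list with `X` (feature matrix), `dictionary`, `Y` (0/1
#'   target matrix over `sdoh_labels(taxonomy)`), and `classes`.
#' @export
binarize_strings <- function(records, taxonomy = sdoh_taxonomy()) {
  target_cols <- c("barrier_1", "barrier_2", "barrier_3")
  feat <- records[, setdiff(
    names(records),
    c("patient_id", target_cols)
  ), drop = FALSE]
  cat_cols <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  for (cl in cat_cols) {
    # unfilled top-3 slots and other empty cells are a real level
    feat[[cl]][is.na(feat[[cl]])] <- "none"
  }
  enc <- one_hot_encode(feat, cat_cols)
  classes <- sdoh_labels(taxonomy)
  Y <- matrix(0L, nrow(records), length(classes),
    dimnames = list(NULL, classes)
  )
  for (cl in target_cols) {
    hit <- match(records[[cl]], classes)
    ok <- !is.na(hit)
    Y[cbind(which(ok), hit[ok])] <- 1L
  }
  list(X = enc$matrix, dictionary = enc$dictionary, Y = Y, classes = classes)
}
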