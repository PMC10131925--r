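#' SDoH taxonomy for patient-navigation tracking logs
#'
#' The 22 coded social-determinant-of-health (SDoH) barrier categories used
#' by the site-A navigation codebook (including the write-in category
#' `"other"`), plus the wildcard `"none"` recorded when an encounter raised
#' no new barrier. Site B records barriers as generic/specific code pairs;
#' its codebook and correspondence to the unified codes live in the alias
#' map (see [default_alias_map()]).
#'
#' @return An object of class `sdoh_taxonomy`: a list with elements
#'   `codes` (character vector of the 22 category codes), `wildcard`
#'   (`"none"`), `write_in` (`"other"`), and `dominant` (the
#'   language/interpreter code, by far the most frequent barrier in
#'   language-discordant navigation cohorts).
#' @examples
#' tax <- sdoh_taxonomy()
#' length(tax$codes)
#' @export
sdoh_taxonomy <- function() {
  codes <- c(
    "transportation",
    "housing",
    "social_practical_support",
    "language_interpreter",
    "literacy",
    "childcare_issues",
    "adult_care_issues",
    "family_community_issues",
    "distance_from_facility",
    "insurance_uninsured",
    "financial_problems",
    "work_schedule_conflicts",
    "communication_with_medical_personnel",
    "fear",
    "medical_mental_comorbidity",
    "patient_disability",
    "out_of_town_country",
    "perceptions_beliefs_tests_treatment",
    "system_problems_scheduling",
    "attitudes_toward_providers",
    "citizenship",
    "other"
  )
  structure(
    list(
      codes = codes,
      wildcard = "none",
      write_in = "other",
      dominant = "language_interpreter"
    ),
    class = "sdoh_taxonomy"
  )
}

#' @export
print.sdoh_taxonomy <- function(x, ...) {
  cat("<sdoh_taxonomy> ", length(x$codes), " categories + wildcard '",
    x$wildcard, "'\n",
    sep = ""
  )
  invisible(x)
}

#' All labels a tracking-log encounter may carry
#'
#' @param taxonomy An [sdoh_taxonomy()].
#' @return Character vector: the category codes plus the wildcard.
#' @export
sdoh_labels <- function(taxonomy = sdoh_taxonomy()) {
  c(taxonomy$codes, taxonomy$wildcard)
}

#' Default site-B alias map
#'
#' Site B codes each barrier as a generic code with an optional more
#' specific child code. The alias map gives, for every site-B code, its
#' generic parent and (where one exists) the corresponding unified
#' (site-A) category. Specific codes without a direct correspondence fall
#' back to their generic parent's correspondence; codes absent from the
#' map resolve to `"other"` (see [map_sdoh_code()]). The exact
#' correspondence used by the original two-site consolidation is not
#' public, so this map is illustrative and user-replaceable: supply your
#' own via [read_alias_map()].
#'
#' @return A tibble with columns `site_b_code`, `generic_parent`
#'   (`NA` for generic codes themselves) and `unified_code` (`NA` when no
#'   direct correspondence exists).
#' @export
default_alias_map <- function() {
  tibble::tribble(
    ~site_b_code,          ~generic_parent, ~unified_code,
    "transport",           NA,              "transportation",
    "transport_no_vehicle","transport",     "transportation",
    "transport_cost",      "transport",     NA,
    "language",            NA,              "language_interpreter",
    "language_interpreter_needed", "language", "language_interpreter",
    "language_forms",      "language",      NA,
    "finance",             NA,              "financial_problems",
    "finance_copay",       "finance",       NA,
    "finance_income_loss", "finance",       "financial_problems",
    "insurance",           NA,              "insurance_uninsured",
    "insurance_lapsed",    "insurance",     "insurance_uninsured",
    "insurance_underinsured", "insurance",  NA,
    "support",             NA,              "social_practical_support",
    "support_no_family_near", "support",    NA,
    "childcare",           NA,              "childcare_issues",
    "eldercare",           NA,              "adult_care_issues",
    "fear_anxiety",        NA,              "fear",
    "scheduling",          NA,              "system_problems_scheduling",
    "scheduling_work",     "scheduling",    "work_schedule_conflicts",
    "beliefs",             NA,              "perceptions_beliefs_tests_treatment",
    "case_management",     NA,              NA,
    "none",                NA,              "none"
  )
}

#' Map a site-B SDoH code onto the unified codebook
#'
#' Specific codes with a direct correspondence map to it; specific codes
#' without one fall back to their generic parent's correspondence; codes
#' absent from the alias map (or whose chain resolves nowhere) map to
#' `"other"`.
#'
#' @param code Character vector of site-B codes.
#' @param alias_map Alias-map tibble, see [default_alias_map()].
#' @return Character vector of unified codes, same length as `code`.
#' @examples
#' map_sdoh_code(c("transport_no_vehicle", "transport_cost", "unknown_code"))
#' @export
map_sdoh_code <- function(code, alias_map = default_alias_map()) {
  one <- function(cd) {
    row <- alias_map[alias_map$site_b_code == cd, ]
    if (nrow(row) == 0) {
      return("other")
    }
    if (!is.na(row$unified_code[1])) {
      return(row$unified_code[1])
    }
    parent <- row$generic_parent[1]
    if (is.na(parent)) {
      return("other")
    }
    prow <- alias_map[alias_map$site_b_code == parent, ]
    if (nrow(prow) > 0 && !is.na(prow$unified_code[1])) {
      return(prow$unified_code[1])
    }
    "other"
  }
  vapply(code, one, character(1), USE.NAMES = FALSE)
}

#' Read or write an alias map as YAML
#'
#' @param path File path.
#' @return `read_alias_map()` returns the alias-map tibble;
#'   `write_alias_map()` invisibly returns `path`.
#' @export
read_alias_map <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, function(x) {
    tibble::tibble(
      site_b_code = x$code,
      generic_parent = x$parent %||% NA_character_,
      unified_code = x$unified %||% NA_character_
    )
  })
}

#' @rdname read_alias_map
#' @param alias_map Alias-map tibble.
#' @export
write_alias_map <- function(alias_map, path) {
  entries <- purrr::pmap(alias_map, function(site_b_code, generic_parent,
                                             unified_code) {
    x <- list(code = site_b_code)
    if (!is.na(generic_parent)) x$parent <- generic_parent
    if (!is.na(unified_code)) x$unified <- unified_code
    x
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
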