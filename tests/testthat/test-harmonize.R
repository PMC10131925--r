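test_that("site-B codes map directly, via generic parent, or to other", {
  expect_equal(map_sdoh_code("transport_no_vehicle"), "transportation")
  expect_equal(map_sdoh_code("transport_cost"), "transportation") # parent
  expect_equal(map_sdoh_code("never_seen_code"), "other")
  expect_equal(map_sdoh_code("case_management"), "other") # unmatched generic
  expect_equal(
    map_sdoh_code(c("language_forms", "insurance_lapsed")),
    c("language_interpreter", "insurance_uninsured")
  )
})

test_that("alias maps survive a YAML round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_alias_map(default_alias_map(), path)
  back <- read_alias_map(path)
  expect_equal(as.data.frame(back), as.data.frame(default_alias_map()))
})

test_that("top-k labels order by frequency, then first occurrence", {
  codes <- c(
    rep("lang", 5), rep("none", 3), rep("fear", 2), "transport"
  )
  expect_equal(top_k_labels(codes), c("lang", "none", "fear"))
  expect_equal(top_k_labels(c("fear", "fear")), c("fear", NA, NA))
  expect_equal(top_k_labels(c("b", "a", "b", "a")), c("b", "a", NA))
  expect_equal(top_k_labels(character(0)), rep(NA_character_, 3))
})

test_that("top-k frequencies match a brute-force counter", {
  set.seed(8)
  for (i in 1:25) {
    codes <- sample(letters[1:6], sample(1:30, 1), TRUE)
    got <- top_k_labels(codes, k = 3)
    tab <- sort(table(codes), decreasing = TRUE)
    got_real <- got[!is.na(got)]
    expect_equal(unname(tab[got_real]), sort(unname(tab), decreasing = TRUE)[seq_along(got_real)])
  }
})

test_that("intensity bins follow the fixed reference thresholds", {
  expect_equal(intensity_bin(2), "L")
  expect_equal(intensity_bin(3), "M")
  expect_equal(intensity_bin(15), "M")
  expect_equal(intensity_bin(16), "H")
  expect_equal(intensity_bin(29), "H")
  expect_equal(intensity_bin(30), "VH")
  expect_error(intensity_bin(-1), "Negative")
})

test_that("intensity bins partition any count vector", {
  counts <- 0:60
  bins <- intensity_bin(counts)
  expect_true(all(bins %in% c("L", "M", "H", "VH")))
  expect_equal(sum(table(bins)), length(counts))
  # monotone: bin boundaries never interleave
  ord <- c(L = 1, M = 2, H = 3, VH = 4)
  expect_true(all(diff(ord[bins]) >= 0))
})

test_that("derived bins anchor to mean and standard deviation", {
  b <- derive_bins(c(4, 17, 30)) # mean 17, sd 13
  expect_equal(unname(b$thresholds), c(4, 17, 30))
  expect_true(all(diff(b$thresholds) > 0))
  expect_error(derive_bins(rep(5, 10)), "sd = 0")
})

test_that("the fixture travel provider returns its table verbatim", {
  prov <- travel_provider_fixture()
  hit <- prov("60616")
  expect_equal(hit$hospital_id, "HOSP_01")
  expect_equal(hit$distance_km, 1.4)
  expect_equal(hit$drive_minutes, 4.0)
  expect_equal(hit$transit_minutes, 12.0)
})

test_that("missing transit times take the mean of observed ones", {
  recs <- tibble::tibble(
    patient_id = c("A_1", "A_2", "A_3"),
    zip_code = c("60608", "60632", "60653")
  )
  out <- travel_augment(recs, travel_provider_fixture())
  # 60632 has no transit in the fixture; mean of 26 and 15 fills it
  expect_equal(out$transit_minutes[2], mean(c(26, 15)))
  expect_false(anyNA(out$drive_minutes))

  all_na_provider <- function(zip) {
    tibble::tibble(
      hospital_id = "H", distance_km = 1,
      drive_minutes = 2, transit_minutes = NA_real_
    )[rep(1, length(zip)), ]
  }
  expect_error(travel_augment(recs, all_na_provider), "transit")
})

test_that("the synthetic travel provider is deterministic per zip", {
  prov <- travel_provider_synthetic()
  a <- prov(c("60616", "60608"))
  b <- prov(c("60616", "60608"))
  expect_identical(a, b)
  expect_true(all(a$distance_km > 0))
  expect_true(all(a$transit_minutes > a$drive_minutes))
})

make_two_site_fixture <- function(seed = 11, n = 25) {
  cfg <- cohort_config(n_patients = n, seed = seed)
  a <- generate_cohort(cfg)
  imp <- impute_missing(a$patients, a$encounters)
  list(
    a = list(patients = imp$patients, encounters = imp$encounters),
    b = generate_site_b(cfg)
  )
}

test_that("harmonized records share one schema across sites", {
  two <- make_two_site_fixture()
  rec <- harmonize(two$a, two$b)
  expect_true(all(c("A", "B") %in% rec$site))
  expect_equal(
    names(rec[rec$site == "A", ]),
    names(rec[rec$site == "B", ])
  )
  # site-B employment recoded onto the richer codebook
  expect_false(any(rec$occupation %in% c("full_time", "part_time")))
  # every barrier is a unified code
  barriers <- stats::na.omit(c(rec$barrier_1, rec$barrier_2, rec$barrier_3))
  expect_true(all(barriers %in% sdoh_labels()))
  expect_true(all(rec$encounter_count >= 1))
})

test_that("patients without encounters are excluded from harmonization", {
  two <- make_two_site_fixture(seed = 12, n = 10)
  extra <- two$a$patients[1, ]
  extra$patient_id <- "P9999"
  two$a$patients <- dplyr::bind_rows(two$a$patients, extra)
  rec <- harmonize(two$a, two$b)
  expect_false("A_P9999" %in% rec$patient_id)
})

test_that("missing shared attributes raise a configuration error", {
  two <- make_two_site_fixture(seed = 13, n = 8)
  expect_error(
    harmonize(two$a, two$b, shared_attributes = c("age", "shoe_size")),
    "shoe_size"
  )
})

test_that("binarized targets mark at most three barriers per patient", {
  two <- make_two_site_fixture(seed = 14, n = 20)
  rec <- harmonize(two$a, two$b)
  rec$encounter_range <- intensity_bin(rec$encounter_count)
  bz <- binarize_strings(rec)
  expect_true(all(rowSums(bz$Y) <= 3))
  expect_true(all(rowSums(bz$Y) >= 1))
  expect_equal(ncol(bz$Y), length(sdoh_labels()))
  expect_equal(nrow(bz$X), nrow(rec))
  # feature segments are exact one-hot blocks
  seg <- bz$X[, startsWith(colnames(bz$X), "occupation="), drop = FALSE]
  expect_equal(unname(rowSums(seg)), rep(1, nrow(rec)))
})
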