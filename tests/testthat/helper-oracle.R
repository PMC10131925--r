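# Independent brute-force re-implementation of the six preparation
# strategies, written with plain loops and its own arithmetic so it
# shares no code path with apply_strategy(). Returns per-instance
# (patient_id, label) pairs.

brute_strategies <- function(patients, encounters) {
  # drop wildcard-only / code-free encounters
  keep <- logical(nrow(encounters))
  codes <- vector("list", nrow(encounters))
  for (i in seq_len(nrow(encounters))) {
    cs <- encounters$sdoh_codes[[i]]
    cs <- cs[!is.na(cs)]
    cs <- cs[cs != "none"]
    codes[[i]] <- cs
    keep[i] <- length(cs) > 0
  }
  enc <- encounters[keep, , drop = FALSE]
  codes <- codes[keep]

  # corpus frequencies by hand
  freq <- list()
  for (cs in codes) {
    for (cd in cs) freq[[cd]] <- (freq[[cd]] %||% 0) + 1
  }
  salient_of <- function(cs) {
    best <- NULL
    best_f <- -1
    for (cd in sort(unique(cs))) {
      f <- freq[[cd]] %||% 0
      if (f > best_f) {
        best <- cd
        best_f <- f
      }
    }
    best
  }

  per_patient <- list()
  for (pid in unique(patients$patient_id)) {
    idx <- which(enc$patient_id == pid)
    if (length(idx) == 0) next
    idx <- idx[order(as.Date(enc$encounter_date[idx]), idx)]
    per_patient[[pid]] <- vapply(idx, function(i) salient_of(codes[[i]]),
      character(1))
  }

  s1 <- character(0)
  s1_ids <- character(0)
  for (pid in names(per_patient)) {
    sal <- per_patient[[pid]]
    lab <- "language_interpreter"
    for (s in sal) {
      if (s != "language_interpreter") {
        lab <- s
        break
      }
    }
    s1 <- c(s1, lab)
    s1_ids <- c(s1_ids, pid)
  }
  s3 <- unlist(per_patient, use.names = FALSE)
  s3_ids <- rep(names(per_patient), vapply(per_patient, length, integer(1)))

  list(
    s1 = data.frame(patient_id = s1_ids, label = s1),
    s2 = data.frame(patient_id = s1_ids, label = s1)[
      s1 != "language_interpreter", , drop = FALSE],
    s3 = data.frame(patient_id = s3_ids, label = s3),
    s4 = data.frame(patient_id = s3_ids, label = s3)[
      s3 != "language_interpreter", , drop = FALSE],
    s5 = data.frame(patient_id = s1_ids, label = s1),
    s6 = data.frame(patient_id = s1_ids, label = s1)[
      s1 != "language_interpreter", , drop = FALSE]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_same_labelling <- function(got, want) {
  g <- sort(paste(got$patient_id, got$label))
  w <- sort(paste(want$patient_id, want$label))
  expect_identical(g, w)
}
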