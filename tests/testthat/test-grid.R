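test_that("the default grid enumerates 130 configurations", {
  cfgs <- enumerate_configs()
  expect_equal(nrow(cfgs), 130)
  expect_true(all(is.na(cfgs$k[cfgs$strategy %in% c("s5", "s6")])))
  expect_true(all(!is.na(cfgs$k[cfgs$strategy %in% c("s1", "s2", "s3", "s4")])))
})

test_that("grid size follows the product-plus-sum rule", {
  expect_equal(nrow(enumerate_configs("s1", 5, "random_forest")), 1)
  expect_equal(
    nrow(enumerate_configs(c("s1", "s3", "s5"), c(5, 10, 15),
      c("random_forest", "support_vector_machine"))),
    2 * 3 * 2 + 1 * 2
  )
  expect_equal(nrow(enumerate_configs(c("s5", "s6"))), 10)
})

# Instances where one categorical feature determines the label, plus a
# noise column: any competent classifier separates them.
separable_instances <- function(n = 120, seed = 1) {
  set.seed(seed)
  grp <- sample(c("alpha", "beta"), n, TRUE)
  tibble::tibble(
    instance_id = sprintf("i%03d", seq_len(n)),
    patient_id = sprintf("p%03d", seq_len(n)),
    group = grp,
    noise = stats::rnorm(n),
    label = ifelse(grp == "alpha", "fear", "transportation")
  )
}

test_that("cross-validation recovers a separable rule", {
  inst <- separable_instances()
  cv <- run_config_cv(
    inst, list(strategy = "s5", k = NA, algorithm = "random_forest"),
    folds = 10, seed = 1
  )
  expect_gte(cv$mean_accuracy, 0.95)
  expect_equal(nrow(cv$predictions), nrow(inst))
})

test_that("shuffled labels score near the majority-class rate", {
  inst <- separable_instances(n = 200, seed = 2)
  set.seed(99)
  inst$label <- sample(inst$label)
  cv <- run_config_cv(
    inst, list(strategy = "s5", k = NA, algorithm = "random_forest"),
    folds = 10, seed = 1
  )
  maj <- max(table(inst$label)) / nrow(inst)
  se <- sqrt(maj * (1 - maj) / nrow(inst))
  expect_lt(abs(cv$mean_accuracy - maj), 3 * se + 0.05)
})

test_that("cross-validation is deterministic under a fixed seed", {
  inst <- separable_instances(n = 60, seed = 3)
  cfg <- list(strategy = "s5", k = NA, algorithm = "random_forest")
  a <- run_config_cv(inst, cfg, folds = 5, seed = 21)
  b <- run_config_cv(inst, cfg, folds = 5, seed = 21)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$predictions, b$predictions)
})

test_that("all five algorithms run and produce sane accuracies", {
  inst <- separable_instances(n = 80, seed = 4)
  for (alg in classifier_algorithms()) {
    cv <- run_config_cv(
      inst, list(strategy = "s5", k = NA, algorithm = alg),
      folds = 4, seed = 1
    )
    expect_true(cv$mean_accuracy >= 0 && cv$mean_accuracy <= 1)
    expect_gte(cv$mean_accuracy, 0.8) # separable rule
  }
})

test_that("confusion summaries count pooled predictions exactly", {
  preds <- tibble::tibble(
    predicted = c("a", "a", "b"),
    truth = c("a", "b", "b")
  )
  cs <- confusion_summary(preds)
  expect_equal(cs$matrix["a", "a"], 1)
  expect_equal(cs$matrix["a", "b"], 1)
  expect_equal(cs$matrix["b", "b"], 1)
  expect_equal(cs$matrix["b", "a"], 0)
  expect_equal(sum(cs$matrix), nrow(preds))

  perfect <- tibble::tibble(
    predicted = c("a", "b", "c"), truth = c("a", "b", "c")
  )
  mp <- confusion_summary(perfect)$matrix
  expect_true(all(mp[upper.tri(mp) | lower.tri(mp)] == 0))
})

test_that("confusion summaries match a brute-force recount", {
  set.seed(5)
  preds <- tibble::tibble(
    predicted = sample(letters[1:4], 200, TRUE),
    truth = sample(letters[1:4], 200, TRUE)
  )
  cs <- confusion_summary(preds)
  for (p in letters[1:4]) {
    for (t in letters[1:4]) {
      expect_equal(
        cs$matrix[p, t],
        sum(preds$predicted == p & preds$truth == t)
      )
    }
  }
})

test_that("row composition sorts by count and sums to 100", {
  row <- c(a = 10, b = 30, c = 5)
  comp <- row_composition(row, "a")
  expect_equal(comp$class, c("b", "a", "c"))
  expect_equal(sum(comp$percent), 100)
  single <- row_composition(c(z = 7), "z")
  expect_equal(single$percent, 100)
  expect_error(row_composition(c(a = 0, b = 0), "a"), "Empty")
})

test_that("grouped confidence is nondecreasing and exhaustive at full m", {
  row <- c(a = 12, b = 9, c = 4, d = 1)
  pcts <- vapply(
    1:4,
    function(m) grouped_confidence(row, "a", m)$percent,
    numeric(1)
  )
  expect_true(all(diff(pcts) >= 0))
  expect_equal(pcts[4], 100)
  # the predicted class is always in the group even when small
  g <- grouped_confidence(row, "d", 1)
  expect_equal(g$count, 1)
})

test_that("heat-map tables carry one row per result and the arg-max", {
  inst <- separable_instances(n = 60, seed = 6)
  res <- lapply(c("random_forest", "gaussian_naive_bayes"), function(alg) {
    run_config_cv(inst, list(strategy = "s5", k = NA, algorithm = alg),
      folds = 4, seed = 1)
  })
  tbl <- heatmap_table(res)
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$mean_accuracy >= 0 & tbl$mean_accuracy <= 1))
  best <- attr(tbl, "best")
  expect_equal(best$mean_accuracy, max(tbl$mean_accuracy))
  p <- ggplot2::autoplot(tbl)
  expect_s3_class(p, "ggplot")
})

test_that("encounter-level strategies group folds by patient", {
  # 30 patients x 4 encounters; fold ids must be constant per patient
  inst <- tibble::tibble(
    instance_id = sprintf("i%03d", 1:120),
    patient_id = rep(sprintf("p%02d", 1:30), each = 4),
    group = rep(sample(c("x", "y"), 30, TRUE), each = 4),
    noise = stats::rnorm(120),
    label = rep(sample(c("fear", "housing"), 30, TRUE), each = 4)
  )
  attr(inst, "strategy") <- "s3"
  cv <- run_config_cv(
    inst, list(strategy = "s3", k = NA, algorithm = "random_forest"),
    folds = 5, seed = 2
  )
  fold_of <- tapply(
    cv$predictions$fold,
    inst$patient_id[match(cv$predictions$instance_id, inst$instance_id)],
    function(x) length(unique(x))
  )
  expect_true(all(fold_of == 1))
})
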