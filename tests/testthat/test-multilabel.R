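test_that("the network audit lists the nine specified layers in order", {
  net <- build_network(40, 22)
  audit <- network_audit(net)
  expect_equal(nrow(audit), 9)
  expect_equal(
    audit$type,
    c("conv1d", "maxpool1d", "flatten", "dropout", "dense",
      "dropout", "dense", "dropout", "dense")
  )
  dense_widths <- audit$output_units[audit$type == "dense"]
  expect_equal(dense_widths, c(66, 44, 22)) # 3C, 2C, C
  expect_true(all(grepl("0.25", audit$detail[audit$type == "dropout"])))
  expect_true(grepl("10 filters, kernel 3", audit$detail[1]))
  expect_true(grepl("pool 2, stride 2", audit$detail[2]))
  expect_true(grepl("sigmoid", audit$detail[9]))
  expect_equal(net$loss, "binary_crossentropy")
})

test_that("inputs narrower than the kernel are rejected", {
  expect_error(build_network(2, 5), "kernel")
})

test_that("untrained outputs are valid per-class probabilities", {
  net <- build_network(12, 6, config = list(seed = 3))
  X <- matrix(stats::rnorm(8 * 12), 8, 12)
  p <- predict(net, X)
  expect_equal(dim(p), c(8, 6))
  expect_true(all(p > 0 & p < 1))
})

test_that("outputs are per-class independent under final-layer permutation", {
  net <- build_network(10, 4, config = list(seed = 5))
  X <- matrix(stats::rnorm(6 * 10), 6, 10)
  base <- predict(net, X)
  perm <- c(3, 1, 4, 2)
  net_p <- net
  net_p$params$W3 <- net$params$W3[, perm]
  net_p$params$b3 <- net$params$b3[perm]
  expect_equal(unname(predict(net_p, X)), unname(base[, perm]))
})

test_that("training drives probabilities below 0.5 on all-zero targets", {
  set.seed(6)
  X <- matrix(stats::rnorm(60 * 8), 60, 8)
  Y <- matrix(0L, 60, 3)
  net <- build_network(8, 3, config = list(epochs = 60, seed = 1))
  net <- train_network(net, X, Y, seed = 1)
  expect_true(all(predict(net, X) < 0.5))
})

test_that("per-class correct plus incorrect counts conserve n", {
  d <- simulate_planted_multilabel(n = 200, seed = 2)
  rep <- train_eval_multilabel(d$X, d$Y, folds = 4, seed = 1,
    config = list(epochs = 10))
  tab <- tidy(rep)
  expect_true(all(tab$correct + tab$incorrect == 200))
  expect_equal(glance(rep)$n, 200)
})

test_that("evaluation is deterministic under a fixed seed", {
  d <- simulate_planted_multilabel(n = 150, seed = 4)
  r1 <- train_eval_multilabel(d$X, d$Y, folds = 3, seed = 9,
    config = list(epochs = 5))
  r2 <- train_eval_multilabel(d$X, d$Y, folds = 3, seed = 9,
    config = list(epochs = 5))
  expect_identical(tidy(r1), tidy(r2))
})

test_that("planted-rule labels are learned well above their base rates", {
  d <- simulate_planted_multilabel(n = 600, seed = 7)
  rep <- train_eval_multilabel(d$X, d$Y, folds = 5, seed = 1,
    config = list(epochs = 60))
  tab <- tidy(rep)
  base_rate_guess <- pmax(tab$prevalence, 1 - tab$prevalence)
  expect_gte(mean(tab$accuracy - base_rate_guess), 0.15)
})

test_that("the planted-rule generator respects its own contract", {
  d <- simulate_planted_multilabel(n = 500, seed = 1)
  expect_true(all(rowSums(d$Y) <= 3))
  d2 <- simulate_planted_multilabel(n = 500, seed = 1)
  expect_identical(d, d2)
  # rules hold exactly
  expect_equal(d$Y[, "class_1"], unname(d$X[, "a"]))
  expect_equal(
    d$Y[, "class_4"],
    as.integer(d$X[, "a"] == 1 & d$X[, "b"] == 1)
  )
})

test_that("intensity classification recovers a planted demographic rule", {
  set.seed(10)
  n <- 300
  hh <- sample(1:8, n, TRUE)
  feats <- tibble::tibble(
    household_size = hh,
    occupation = sample(c("retired", "service"), n, TRUE)
  )
  labels <- c("L", "M", "H", "VH")[pmin(4, ceiling(hh / 2))]
  cv <- intensity_classifier(feats, labels, folds = 5, seed = 1)
  expect_gte(cv$mean_accuracy, 0.9)

  set.seed(11)
  shuffled <- sample(labels)
  cv_null <- intensity_classifier(feats, shuffled, folds = 5, seed = 1)
  maj <- max(table(shuffled)) / n
  expect_lt(abs(cv_null$mean_accuracy - maj), 0.1)
  expect_error(intensity_classifier(feats, rep("L", n)), "2 intensity bins")
})

test_that("attribute correlations match hand-computed Pearson values", {
  tbl <- tibble::tibble(
    x = c(0, 0, 1, 1),
    x_copy = c(0, 0, 1, 1),
    x_flip = c(1, 1, 0, 0),
    flat = c(1, 1, 1, 1),
    y = c(0, 1, 1, 1)
  )
  out <- attribute_correlations(tbl, sdoh_columns = "y")
  r_of <- function(a) out$r[out$attribute == a]
  expect_equal(r_of("x"), 0.577, tolerance = 1e-3)
  expect_true(is.na(r_of("flat")))
  corr2 <- attribute_correlations(
    tibble::tibble(a = c(0, 1, 0, 1), b = c(1, 0, 1, 0), s = c(0, 1, 0, 1)),
    sdoh_columns = "s"
  )
  expect_equal(corr2$r[corr2$attribute == "a"], 1)
  expect_equal(corr2$r[corr2$attribute == "b"], -1)
  # sorted by magnitude, undefined last
  expect_true(is.na(utils::tail(out$r, 1)))
  expect_equal(out$r[1], max(abs(out$r), na.rm = TRUE))
})
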