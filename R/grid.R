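#' The five classification algorithms of the comparison grid
#'
#' @return Character vector of algorithm identifiers.
#' @export
classifier_algorithms <- function() {
  c(
    "logistic_regression", "random_forest", "support_vector_machine",
    "artificial_neural_network", "gaussian_naive_bayes"
  )
}

#' Enumerate the model-configuration grid
#'
#' Note-using strategies (s1–s4) cross with every topic count and
#' algorithm; demographics-only strategies (s5, s6) cross with the
#' algorithms alone (topic features do not apply). Under the default
#' grids this yields 4 x 6 x 5 + 2 x 5 = 130 configurations.
#'
#' @param strategies Strategy ids (subset of `"s1"`..`"s6"`).
#' @param k_grid Topic counts for the note strategies.
#' @param algorithms Algorithm identifiers.
#' @return A tibble (`strategy`, `k`, `algorithm`); `k` is `NA` for
#'   demographics-only strategies. Deterministic order.
#' @examples
#' nrow(enumerate_configs())
#' @export
enumerate_configs <- function(strategies = paste0("s", 1:6),
                              k_grid = c(5, 10, 15, 20, 25, 30),
                              algorithms = classifier_algorithms()) {
  stopifnot(length(strategies) > 0, length(algorithms) > 0)
  note_strats <- intersect(strategies, c("s1", "s2", "s3", "s4"))
  demo_strats <- intersect(strategies, c("s5", "s6"))
  note_part <- if (length(note_strats) > 0 && length(k_grid) > 0) {
    tidyr::expand_grid(
      strategy = note_strats, k = as.integer(k_grid), algorithm = algorithms
    )
  } else {
    tibble::tibble(
      strategy = character(), k = integer(), algorithm = character()
    )
  }
  demo_part <- tidyr::expand_grid(
    strategy = demo_strats, k = NA_integer_, algorithm = algorithms
  )
  dplyr::bind_rows(note_part, demo_part)
}

# Fold assignment: stratified by label where class counts permit
# (downgraded with a warning otherwise), or grouped so that all
# instances of one patient land in the same fold (used for
# encounter-level strategies, where repeated demographics would
# otherwise leak across folds).
make_folds <- function(y, folds, groups = NULL, seed = 1L) {
  n <- length(y)
  with_seed(seed, {
    if (!is.null(groups)) {
      gl <- sample(unique(groups))
      gfold <- stats::setNames(rep_len(seq_len(folds), length(gl)), gl)
      return(as.integer(gfold[as.character(groups)]))
    }
    counts <- table(y)
    if (min(counts) < folds) {
      warning("Class with fewer than ", folds,
        " members; using unstratified folds",
        call. = FALSE
      )
      return(sample(rep_len(seq_len(folds), n)))
    }
    fold <- integer(n)
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

fit_algorithm <- function(algorithm, X, y, seed = 1L) {
  df <- as.data.frame(X)
  names(df) <- make.names(names(df), unique = TRUE)
  feature_names <- names(df)
  y <- droplevels(factor(y))
  model <- with_seed(seed, switch(algorithm,
    logistic_regression = {
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, trace = FALSE, MaxNWts = 1e5,
        maxit = 200)
    },
    random_forest = ranger::ranger(
      x = df, y = y, num.trees = 300, seed = seed,
      num.threads = 1
    ),
    support_vector_machine = e1071::svm(
      x = as.matrix(df), y = y, kernel = "radial", scale = FALSE
    ),
    artificial_neural_network = {
      Yind <- nnet::class.ind(y)
      nnet::nnet(as.matrix(df), Yind,
        size = 8, decay = 0.01, maxit = 200,
        MaxNWts = 1e5, trace = FALSE, softmax = TRUE
      )
    },
    gaussian_naive_bayes = e1071::naiveBayes(x = df, y = y),
    stop("Unknown algorithm: ", algorithm, call. = FALSE)
  ))
  structure(list(algorithm = algorithm, model = model, levels = levels(y),
    feature_names = feature_names), class = "sdoh_classifier")
}

predict_algorithm <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- fit$feature_names
  out <- switch(fit$algorithm,
    logistic_regression = as.character(stats::predict(fit$model,
      newdata = df, type = "class")),
    random_forest = as.character(stats::predict(fit$model,
      data = df)$predictions),
    support_vector_machine = as.character(stats::predict(fit$model,
      as.matrix(df))),
    artificial_neural_network = {
      pr <- stats::predict(fit$model, as.matrix(df))
      if (is.null(colnames(pr))) colnames(pr) <- fit$levels
      colnames(pr)[max.col(pr, ties.method = "first")]
    },
    gaussian_naive_bayes = as.character(stats::predict(fit$model, df,
      type = "class", eps = 1e-9, threshold = 1e-9))
  )
  out
}

# Design matrix for one train/test split: one-hot categorical columns
# (dictionary from the training rows; categories unseen in training get
# all-zero segments), numeric passthrough standardised by training
# mean/sd, and, when a topic count applies, LDA topic probabilities
# from a model fitted on the training notes only (full-corpus fitting
# selectable for fidelity to pipelines that fit once up front).
build_design <- function(instances, tr, te, k = NA, seed = 1L,
                         lda_iter = 200, lda_full_corpus = FALSE) {
  feats <- instance_feature_columns(instances)
  tbl <- instances[, c(feats$categorical, feats$numeric), drop = FALSE]
  enc_tr <- one_hot_encode(tbl[tr, , drop = FALSE], feats$categorical)
  enc_all <- one_hot_encode(tbl, feats$categorical,
    dictionary = enc_tr$dictionary, unseen = "zero"
  )
  X <- enc_all$matrix
  num_cols <- feats$numeric
  if (length(num_cols) > 0) {
    mu <- colMeans(X[tr, num_cols, drop = FALSE])
    sd <- apply(X[tr, num_cols, drop = FALSE], 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    X[, num_cols] <- sweep(sweep(X[, num_cols, drop = FALSE], 2, mu), 2, sd, "/")
  }
  if (!is.na(k) && length(feats$text) > 0) {
    notes <- instances$comments
    fit_on <- if (lda_full_corpus) notes else notes[tr]
    model <- fit_topics(fit_on, k = k, n_iter = lda_iter, seed = seed)
    X <- cbind(X, notes_to_matrix(model, notes))
  }
  list(train = X[tr, , drop = FALSE], test = X[te, , drop = FALSE])
}

#' Cross-validate one model configuration
#'
#' Runs k-fold cross-validation of one (strategy, topic count,
#' algorithm) configuration on a labelled instance table: folds are
#' stratified by label where class counts permit (grouped by patient
#' for encounter-level strategies s3/s4, whose repeated demographics
#' would otherwise leak), topic models are fitted within each training
#' fold, and held-out predictions are pooled.
#'
#' @param instances Instance tibble from [apply_strategy()].
#' @param config One-row tibble or list with `strategy`, `k`,
#'   `algorithm` (see [enumerate_configs()]).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed governing folds, topic models and
#'   classifier fits.
#' @param grouped Force patient-grouped folds (`TRUE`/`FALSE`); default
#'   `NULL` groups for s3/s4 only.
#' @param lda_iter Gibbs sweeps per fold-level topic model.
#' @param lda_full_corpus Fit the topic model on the full corpus
#'   instead of the training fold only (optimistic; off by default).
#' @return A `cv_result`: list with `config`, `fold_accuracy`,
#'   `mean_accuracy`, and pooled `predictions`
#'   (`instance_id`, `fold`, `truth`, `predicted`).
#' @export
run_config_cv <- function(instances, config, folds = 10, seed = 1L,
                          grouped = NULL, lda_iter = 200,
                          lda_full_corpus = FALSE) {
  config <- as.list(config)
  if (is.null(config$k)) config$k <- NA_integer_
  if (nrow(instances) < folds) {
    stop("Fewer instances (", nrow(instances), ") than folds (", folds, ")",
      call. = FALSE
    )
  }
  y <- instances$label
  if (length(unique(y)) < 2) {
    stop("Need at least 2 classes present", call. = FALSE)
  }
  if (is.null(grouped)) {
    grouped <- isTRUE(attr(instances, "strategy") %in% c("s3", "s4"))
  }
  groups <- if (grouped) instances$patient_id else NULL
  fold_id <- make_folds(y, folds, groups = groups, seed = seed)

  preds <- vector("list", folds)
  acc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    if (length(te) == 0 || length(unique(y[tr])) < 2) next
    d <- build_design(instances, tr, te,
      k = config$k, seed = seed + f,
      lda_iter = lda_iter, lda_full_corpus = lda_full_corpus
    )
    fit <- fit_algorithm(config$algorithm, d$train, y[tr], seed = seed + f)
    p <- predict_algorithm(fit, d$test)
    acc[f] <- mean(p == y[te])
    preds[[f]] <- tibble::tibble(
      instance_id = instances$instance_id[te],
      fold = f, truth = y[te], predicted = p
    )
  }
  structure(
    list(
      config = config,
      fold_accuracy = acc,
      mean_accuracy = mean(acc, na.rm = TRUE),
      predictions = dplyr::bind_rows(preds)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(
    "<cv_result> ", x$config$strategy,
    if (!is.na(x$config$k)) paste0(" k=", x$config$k) else "",
    " ", x$config$algorithm,
    ": mean accuracy ", sprintf("%.3f", x$mean_accuracy),
    " over ", sum(!is.na(x$fold_accuracy)), " folds\n",
    sep = ""
  )
  invisible(x)
}

#' Confusion summary of pooled cross-validation predictions
#'
#' Counts (predicted, true) pairs over the pooled held-out predictions.
#' Rows index the predicted class and columns the true class, so each
#' row describes the composition of everything the model called that
#' class.
#'
#' @param x A `cv_result`, or a data frame with `predicted` and `truth`
#'   columns.
#' @return A `confusion_summary`: list with square count `matrix` and
#'   `row_totals`.
#' @export
confusion_summary <- function(x) {
  preds <- if (inherits(x, "cv_result")) x$predictions else x
  classes <- sort(unique(c(preds$predicted, preds$truth)))
  m <- table(
    factor(preds$predicted, levels = classes),
    factor(preds$truth, levels = classes)
  )
  m <- matrix(as.integer(m), nrow = length(classes),
    dimnames = list(predicted = classes, true = classes)
  )
  structure(
    list(matrix = m, row_totals = rowSums(m)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> ", nrow(x$matrix), " classes, ",
    sum(x$matrix), " predictions\n",
    sep = ""
  )
  invisible(x)
}

confusion_row <- function(cs, predicted_class) {
  if (inherits(cs, "confusion_summary")) {
    if (!predicted_class %in% rownames(cs$matrix)) {
      stop("No such predicted class: ", predicted_class, call. = FALSE)
    }
    cs$matrix[predicted_class, ]
  } else if (is.numeric(cs) && !is.null(names(cs))) {
    cs
  } else {
    stop("Expected a confusion_summary or a named count vector",
      call. = FALSE
    )
  }
}

#' Composition of one predicted-class row
#'
#' For everything a model labelled `predicted_class`, tabulates which
#' true classes those predictions actually were: counts and row
#' percentages, sorted by descending count (ties lexicographic).
#'
#' @param cs A [confusion_summary()], or a named count vector giving
#'   one row directly.
#' @param predicted_class Row to describe.
#' @return A tibble (`predicted`, `class`, `count`, `percent`);
#'   percents are exact (`100 * count / row_total`).
#' @export
row_composition <- function(cs, predicted_class) {
  row <- confusion_row(cs, predicted_class)
  row <- row[row > 0]
  total <- sum(row)
  if (total == 0) {
    stop("Empty confusion row for class ", predicted_class, call. = FALSE)
  }
  ord <- order(-row, names(row))
  tibble::tibble(
    predicted = predicted_class,
    class = names(row)[ord],
    count = as.integer(row[ord]),
    percent = 100 * as.integer(row[ord]) / total
  )
}

#' Grouped confidence over the top-m true classes of a prediction row
#'
#' The cumulative share of a predicted-class row covered by its `m`
#' most frequent true classes, always including the predicted class
#' itself. This is the device for spotting clusters of co-confused
#' SDoHs: a model may be only moderately confident in the single label
#' yet highly confident the truth lies in a small related group.
#'
#' @inheritParams row_composition
#' @param m Number of true classes in the group (1 to the number of
#'   classes in the row).
#' @return One-row tibble (`predicted`, `m`, `count`, `row_total`,
#'   `percent`, `classes` as `;`-joined group members).
#' @export
grouped_confidence <- function(cs, predicted_class, m) {
  row <- confusion_row(cs, predicted_class)
  total <- sum(row)
  if (total == 0) {
    stop("Empty confusion row for class ", predicted_class, call. = FALSE)
  }
  row <- row[row > 0 | names(row) == predicted_class]
  stopifnot(m >= 1, m <= length(row))
  others <- row[names(row) != predicted_class]
  others <- others[order(-others, names(others))]
  take <- c(
    row[names(row) == predicted_class],
    utils::head(others, m - 1)
  )
  tibble::tibble(
    predicted = predicted_class,
    m = as.integer(m),
    count = as.integer(sum(take)),
    row_total = as.integer(total),
    percent = 100 * sum(take) / total,
    classes = paste(names(take), collapse = ";")
  )
}

#' Long-format accuracy table over a set of cross-validation results
#'
#' @param results A list of `cv_result` objects.
#' @return A tibble (`strategy`, `k`, `algorithm`, `mean_accuracy`)
#'   with the arg-max configuration attached as attribute `best` (also
#'   a one-row tibble).
#' @export
heatmap_table <- function(results) {
  stopifnot(length(results) >= 1)
  tbl <- purrr::map_dfr(results, function(r) {
    tibble::tibble(
      strategy = r$config$strategy,
      k = r$config$k,
      algorithm = r$config$algorithm,
      mean_accuracy = r$mean_accuracy
    )
  })
  attr(tbl, "best") <- tbl[which.max(tbl$mean_accuracy), ]
  class(tbl) <- c("sdoh_heatmap", class(tbl))
  tbl
}

#' Example pooled confusion-matrix rows from an SDoH classifier
#'
#' Realistic pooled prediction-row compositions for four SDoH classes of
#' a patient-level random-forest model (173 language/interpreter
#' predictions, 22 fear, 59 social/practical support, 34 insurance).
#' The named counts reproduce the row-composition and
#' grouped-confidence arithmetic discussed in the package vignette;
#' counts not individually reported are spread over plausible minor
#' classes (each below the smallest reported count, so top-m group
#' membership is unaffected).
#'
#' @return Named list of named integer count vectors, one per
#'   predicted class.
#' @export
example_confusion_rows <- function() {
  list(
    language_interpreter = c(
      language_interpreter = 137L, social_practical_support = 22L,
      fear = 6L, perceptions_beliefs_tests_treatment = 3L,
      insurance_uninsured = 3L, other = 2L
    ),
    fear = c(
      fear = 14L, language_interpreter = 3L,
      perceptions_beliefs_tests_treatment = 2L,
      social_practical_support = 2L, financial_problems = 1L
    ),
    social_practical_support = c(
      social_practical_support = 37L, insurance_uninsured = 6L,
      fear = 5L, other = 4L, transportation = 3L,
      perceptions_beliefs_tests_treatment = 2L,
      communication_with_medical_personnel = 2L
    ),
    insurance_uninsured = c(
      insurance_uninsured = 19L, other = 4L,
      communication_with_medical_personnel = 2L,
      financial_problems = 2L, social_practical_support = 2L,
      transportation = 2L, fear = 2L, housing = 1L
    )
  )
}
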