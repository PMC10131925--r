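#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One row per fold: `fold`, `accuracy`, plus the config
#'   columns.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    strategy = x$config$strategy,
    k = x$config$k,
    algorithm = x$config$algorithm,
    fold = seq_along(x$fold_accuracy),
    accuracy = x$fold_accuracy
  )
}

#' @rdname tidy.cv_result
#' @return `glance()`: a one-row summary with the mean accuracy, its
#'   standard error over folds, and the prediction count.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  acc <- x$fold_accuracy[!is.na(x$fold_accuracy)]
  tibble::tibble(
    strategy = x$config$strategy,
    k = x$config$k,
    algorithm = x$config$algorithm,
    mean_accuracy = x$mean_accuracy,
    se_accuracy = stats::sd(acc) / sqrt(length(acc)),
    n_folds = length(acc),
    n_predictions = nrow(x$predictions)
  )
}

#' Tidy a confusion summary into long format
#'
#' @param x A `confusion_summary`.
#' @param ... Unused.
#' @return Tibble (`predicted`, `true`, `count`).
#' @method tidy confusion_summary
#' @export
tidy.confusion_summary <- function(x, ...) {
  df <- as.data.frame.table(x$matrix, stringsAsFactors = FALSE)
  names(df) <- c("predicted", "true", "count")
  tibble::as_tibble(df)
}

#' Tidy a per-class multi-label report
#'
#' @param x A `perclass_report`.
#' @param ... Unused.
#' @return The per-class tibble (`class`, `correct`, `incorrect`,
#'   `accuracy`, `prevalence`, `seen_in_training`).
#' @method tidy perclass_report
#' @export
tidy.perclass_report <- function(x, ...) {
  x$report
}

#' @rdname tidy.perclass_report
#' @method glance perclass_report
#' @export
glance.perclass_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    folds = x$folds,
    mean_per_class_accuracy = mean(x$report$accuracy),
    min_per_class_accuracy = min(x$report$accuracy),
    n_classes = nrow(x$report)
  )
}
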