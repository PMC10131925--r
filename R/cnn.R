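# Multi-label 1D convolutional network, implemented directly with
# vectorised matrix operations (forward, backprop, Adam). The
# architecture is small and fixed — see build_network() — so a
# framework dependency is unnecessary.

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build the 9-layer multi-label 1D convolutional network
#'
#' Architecture (in order): 1D convolution (10 filters, kernel width 3,
#' rectified-linear activation) over the feature sequence with one
#' channel; max-pooling (pool size 2, stride 2); flatten; then three
#' (dropout 0.25, dense) pairs with dense widths 3C, 2C and C for C
#' classes — the final dense layer uses a sigmoid activation so each
#' class probability is independent, paired with a binary cross-entropy
#' loss for multi-label prediction.
#'
#' @param n_features Input width (>= 3, the kernel width).
#' @param n_classes Number of classes C (>= 1).
#' @param config Training configuration: `epochs` (default 100),
#'   `batch_size` (32), `lr` (Adam step size, default 0.003 — the small
#'   dense widths tolerate and benefit from a step above the usual
#'   0.001), `seed` (1).
#' @return An object of class `sdoh_cnn` holding the initialised
#'   parameters, the layer audit, and the config.
#' @export
build_network <- function(n_features, n_classes, config = list()) {
  if (n_features < 3) {
    stop("n_features must be at least the kernel width (3)", call. = FALSE)
  }
  stopifnot(n_classes >= 1)
  cfg <- utils::modifyList(
    list(epochs = 100, batch_size = 32, lr = 3e-3, dropout = 0.25,
      filters = 10L, kernel = 3L, pool = 2L, seed = 1L),
    config
  )
  C <- as.integer(n_classes)
  conv_out <- n_features - cfg$kernel + 1L
  pooled <- conv_out %/% cfg$pool
  if (pooled < 1) stop("Too few features after pooling", call. = FALSE)
  flat <- pooled * cfg$filters

  init <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  params <- with_seed(cfg$seed, list(
    Wc = init(cfg$kernel, cfg$filters, cfg$kernel),
    bc = rep(0, cfg$filters),
    W1 = init(flat, 3L * C, flat), b1 = rep(0, 3L * C),
    W2 = init(3L * C, 2L * C, 3L * C), b2 = rep(0, 2L * C),
    W3 = init(2L * C, C, 2L * C), b3 = rep(0, C)
  ))

  audit <- tibble::tibble(
    layer = 1:9,
    type = c(
      "conv1d", "maxpool1d", "flatten", "dropout", "dense",
      "dropout", "dense", "dropout", "dense"
    ),
    output_units = c(
      conv_out * cfg$filters, flat, flat, flat, 3L * C,
      3L * C, 2L * C, 2L * C, C
    ),
    detail = c(
      sprintf("%d filters, kernel %d", cfg$filters, cfg$kernel),
      sprintf("pool %d, stride %d", cfg$pool, cfg$pool),
      "", sprintf("rate %.2f", cfg$dropout),
      sprintf("%d units, relu", 3L * C),
      sprintf("rate %.2f", cfg$dropout),
      sprintf("%d units, relu", 2L * C),
      sprintf("rate %.2f", cfg$dropout),
      sprintf("%d units, sigmoid", C)
    )
  )

  structure(
    list(
      n_features = as.integer(n_features), n_classes = C,
      conv_out = conv_out, pooled = pooled, flat = flat,
      params = params, config = cfg, audit = audit,
      loss = "binary_crossentropy"
    ),
    class = "sdoh_cnn"
  )
}

#' @export
print.sdoh_cnn <- function(x, ...) {
  cat("<sdoh_cnn> ", nrow(x$audit), " layers, ", x$n_features,
    " features -> ", x$n_classes, " sigmoid outputs\n",
    sep = ""
  )
  invisible(x)
}

#' Architecture audit of a built network
#'
#' @param net An [build_network()] object.
#' @return Tibble with one row per layer (`layer`, `type`,
#'   `output_units`, `detail`).
#' @export
network_audit <- function(net) {
  stopifnot(inherits(net, "sdoh_cnn"))
  net$audit
}

# im2col for kernel width 3: rows index (sample, position) in
# column-major order, columns the kernel offsets.
conv_patches <- function(X, conv_out, kernel) {
  B <- nrow(X)
  M <- matrix(0, B * conv_out, kernel)
  for (o in seq_len(kernel)) {
    M[, o] <- as.vector(X[, o:(conv_out + o - 1), drop = FALSE])
  }
  M
}

cnn_forward <- function(net, X, train = FALSE) {
  p <- net$params
  cfg <- net$config
  B <- nrow(X)
  P <- net$pooled

  M <- conv_patches(X, net$conv_out, cfg$kernel)
  Zc_pre <- sweep(M %*% p$Wc, 2, p$bc, "+")
  Zc <- relu(Zc_pre)

  idx1 <- as.vector(outer(seq_len(B), (seq_len(P) * 2 - 2) * B, "+"))
  idx2 <- idx1 + B
  Z1 <- Zc[idx1, , drop = FALSE]
  Z2 <- Zc[idx2, , drop = FALSE]
  mask_pool <- Z1 >= Z2
  Pool <- pmax(Z1, Z2)
  Flat <- matrix(as.vector(Pool), B, net$flat)

  drop_mask <- function(nr, nc) {
    if (!train || cfg$dropout <= 0) {
      return(NULL)
    }
    matrix(stats::runif(nr * nc) >= cfg$dropout, nr, nc) / (1 - cfg$dropout)
  }
  D1 <- drop_mask(B, net$flat)
  H0 <- if (is.null(D1)) Flat else Flat * D1
  A1_pre <- sweep(H0 %*% p$W1, 2, p$b1, "+")
  A1 <- relu(A1_pre)
  D2 <- drop_mask(B, ncol(A1))
  H1 <- if (is.null(D2)) A1 else A1 * D2
  A2_pre <- sweep(H1 %*% p$W2, 2, p$b2, "+")
  A2 <- relu(A2_pre)
  D3 <- drop_mask(B, ncol(A2))
  H2 <- if (is.null(D3)) A2 else A2 * D3
  Out <- sigmoid(sweep(H2 %*% p$W3, 2, p$b3, "+"))

  list(
    M = M, Zc_pre = Zc_pre, idx1 = idx1, idx2 = idx2,
    mask_pool = mask_pool, Flat = Flat,
    D1 = D1, H0 = H0, A1_pre = A1_pre, A1 = A1, D2 = D2, H1 = H1,
    A2_pre = A2_pre, A2 = A2, D3 = D3, H2 = H2, Out = Out, B = B
  )
}

cnn_backward <- function(net, fw, Y) {
  p <- net$params
  B <- fw$B
  dOut <- (fw$Out - Y) / B # sigmoid + BCE

  dW3 <- crossprod(fw$H2, dOut)
  db3 <- colSums(dOut)
  dH2 <- dOut %*% t(p$W3)
  dA2 <- if (is.null(fw$D3)) dH2 else dH2 * fw$D3
  dA2 <- dA2 * (fw$A2_pre > 0)

  dW2 <- crossprod(fw$H1, dA2)
  db2 <- colSums(dA2)
  dH1 <- dA2 %*% t(p$W2)
  dA1 <- if (is.null(fw$D2)) dH1 else dH1 * fw$D2
  dA1 <- dA1 * (fw$A1_pre > 0)

  dW1 <- crossprod(fw$H0, dA1)
  db1 <- colSums(dA1)
  dH0 <- dA1 %*% t(p$W1)
  dFlat <- if (is.null(fw$D1)) dH0 else dH0 * fw$D1

  dPool <- matrix(as.vector(dFlat), B * net$pooled, net$config$filters)
  dZc <- matrix(0, nrow(fw$Zc_pre), net$config$filters)
  dZc[fw$idx1, ] <- dPool * fw$mask_pool
  dZc[fw$idx2, ] <- dZc[fw$idx2, ] + dPool * (!fw$mask_pool)
  dZc <- dZc * (fw$Zc_pre > 0)
  dWc <- crossprod(fw$M, dZc)
  dbc <- colSums(dZc)

  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
    W3 = dW3, b3 = db3)
}

#' Train the network on one data set
#'
#' Minibatch Adam on binary cross-entropy. Used internally by
#' [train_eval_multilabel()]; exported for direct experimentation.
#'
#' @param net An [build_network()] object.
#' @param X Numeric feature matrix.
#' @param Y 0/1 label matrix with `net$n_classes` columns.
#' @param seed Seed for shuffling and dropout.
#' @return The network with trained parameters.
#' @export
train_network <- function(net, X, Y, seed = net$config$seed) {
  stopifnot(inherits(net, "sdoh_cnn"), ncol(Y) == net$n_classes)
  cfg <- net$config
  p <- net$params
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0
  with_seed(seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(X))
      starts <- seq(1, length(ord), by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        if (length(idx) < 2) next
        net$params <- p
        fw <- cnn_forward(net, X[idx, , drop = FALSE], train = TRUE)
        gr <- cnn_backward(net, fw, Y[idx, , drop = FALSE])
        t <- t + 1
        for (nm in names(p)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^t)
          vhat <- v[[nm]] / (1 - b2^t)
          p[[nm]] <- p[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
  })
  net$params <- p
  net$trained <- TRUE
  net
}

#' Predict class probabilities
#'
#' @param object A (trained) `sdoh_cnn`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Matrix of per-class sigmoid probabilities in (0, 1).
#' @export
predict.sdoh_cnn <- function(object, newdata, ...) {
  out <- cnn_forward(object, as.matrix(newdata), train = FALSE)$Out
  colnames(out) <- paste0("class_", seq_len(object$n_classes))
  out
}

#' Cross-validated multi-label evaluation of the network
#'
#' Trains and evaluates the 9-layer network under k-fold
#' cross-validation: per fold, sigmoid outputs are thresholded at 0.5
#' and per-class correct/incorrect decisions accumulate over the
#' held-out folds.
#'
#' @param X Feature matrix.
#' @param Y 0/1 label matrix (rows with at most 3 active labels under
#'   the top-3 construction).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (folds, initialisation, shuffling).
#' @param config Passed to [build_network()] (epochs, batch size, lr).
#' @param threshold Decision threshold on the sigmoid outputs
#'   (default 0.5).
#' @return A `perclass_report`: list with `report` (tibble: `class`,
#'   `correct`, `incorrect`, `accuracy`, `prevalence`, `seen_in_training`),
#'   `n`, `folds`, `config`.
#' @export
train_eval_multilabel <- function(X, Y, folds = 10, seed = 1L,
                                  config = list(), threshold = 0.5) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= folds)
  if (is.null(colnames(Y))) {
    colnames(Y) <- paste0("class_", seq_len(ncol(Y)))
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  correct <- stats::setNames(rep(0L, ncol(Y)), colnames(Y))
  incorrect <- correct
  flagged <- stats::setNames(rep(FALSE, ncol(Y)), colnames(Y))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    absent <- colSums(Y[tr, , drop = FALSE]) == 0
    if (any(absent)) {
      warning("Class(es) never present in training fold ", f, ": ",
        paste(colnames(Y)[absent], collapse = ", "),
        call. = FALSE
      )
      flagged <- flagged | absent
    }
    net <- build_network(ncol(X), ncol(Y),
      config = utils::modifyList(config, list(seed = seed + f))
    )
    net <- train_network(net, X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
      seed = seed + f
    )
    prob <- predict(net, X[te, , drop = FALSE])
    pred <- (prob >= threshold) * 1L
    hits <- pred == Y[te, , drop = FALSE]
    correct <- correct + colSums(hits)
    incorrect <- incorrect + colSums(!hits)
  }
  report <- tibble::tibble(
    class = colnames(Y),
    correct = as.integer(correct),
    incorrect = as.integer(incorrect),
    accuracy = correct / (correct + incorrect),
    prevalence = colMeans(Y),
    seen_in_training = !flagged
  )
  structure(
    list(
      report = report, n = nrow(X), folds = folds,
      config = utils::modifyList(
        list(epochs = 100, batch_size = 32, lr = 3e-3, threshold = threshold),
        config
      )
    ),
    class = "perclass_report"
  )
}

#' @export
print.perclass_report <- function(x, ...) {
  cat("<perclass_report> ", x$n, " instances, ", x$folds, " folds\n",
    sep = ""
  )
  print(x$report)
  invisible(x)
}

#' Cross-validated intensity classification from demographics
#'
#' Predicts the encounter-intensity bin (`L`/`M`/`H`/`VH`) from
#' demographic features with a support-vector classifier under k-fold
#' cross-validation.
#'
#' @param features Data frame of demographic attributes (categoricals
#'   are one-hot encoded internally) or a numeric matrix.
#' @param labels Intensity bin per row.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return A `cv_result` (see [run_config_cv()]).
#' @export
intensity_classifier <- function(features, labels, folds = 10, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("Need at least 2 intensity bins present", call. = FALSE)
  }
  if (is.data.frame(features)) {
    cat_cols <- names(features)[!vapply(features, is.numeric, logical(1))]
    X <- one_hot_encode(features, cat_cols)$matrix
  } else {
    X <- as.matrix(features)
  }
  fold_id <- make_folds(labels, folds, seed = seed)
  acc <- rep(NA_real_, folds)
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    if (length(te) == 0 || length(unique(labels[tr])) < 2) next
    fit <- fit_algorithm("support_vector_machine", X[tr, , drop = FALSE],
      labels[tr],
      seed = seed + f
    )
    p <- predict_algorithm(fit, X[te, , drop = FALSE])
    acc[f] <- mean(p == labels[te])
    preds[[f]] <- tibble::tibble(
      instance_id = as.character(te), fold = f,
      truth = labels[te], predicted = p
    )
  }
  structure(
    list(
      config = list(strategy = "intensity", k = NA_integer_,
        algorithm = "support_vector_machine"),
      fold_accuracy = acc,
      mean_accuracy = mean(acc, na.rm = TRUE),
      predictions = dplyr::bind_rows(preds)
    ),
    class = "cv_result"
  )
}

#' Pairwise attribute–SDoH Pearson correlations
#'
#' Pearson product-moment correlation between every attribute column
#' and every SDoH indicator column (for 0/1 pairs this coincides with
#' the phi / point-biserial coefficient). Zero-variance columns yield
#' `NA` (undefined), reported as such.
#'
#' @param tbl Data frame or matrix of numeric/binary columns.
#' @param sdoh_columns Names of the SDoH indicator columns in `tbl`.
#' @return Tibble (`attribute`, `sdoh`, `r`) sorted by decreasing
#'   `|r|`, undefined pairs last.
#' @export
attribute_correlations <- function(tbl, sdoh_columns) {
  m <- as.matrix(tbl)
  stopifnot(all(sdoh_columns %in% colnames(m)))
  attrs <- setdiff(colnames(m), sdoh_columns)
  out <- tidyr::expand_grid(attribute = attrs, sdoh = sdoh_columns)
  out$r <- purrr::map2_dbl(out$attribute, out$sdoh, function(a, s) {
    x <- m[, a]
    y <- m[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  })
  out[order(-abs(out$r), out$attribute, na.last = TRUE), ]
}
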