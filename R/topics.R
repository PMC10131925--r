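#' Tokenize a navigator note
#'
#' Lowercases, strips punctuation, and splits on whitespace. Empty or
#' missing text yields an empty token vector.
#'
#' @param text Character vector of notes.
#' @return For a single note, a character vector of tokens; for several,
#'   a list of token vectors.
#' @examples
#' tokenize("recommended pt to see GYN doctor")
#' @export
tokenize <- function(text) {
  one <- function(x) {
    if (is.na(x) || x == "") {
      return(character(0))
    }
    x <- stringr::str_to_lower(x)
    x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
    toks <- stringr::str_split_1(stringr::str_trim(x), "\\s+")
    toks[toks != ""]
  }
  if (length(text) == 1) one(text) else lapply(text, one)
}

#' Fit a latent Dirichlet allocation topic model on navigator notes
#'
#' Fits LDA by collapsed Gibbs sampling with symmetric priors, so that
#' each note becomes a length-`k` vector of topic probabilities.
#' Document vectors (including the stored training-document vectors)
#' are computed by a deterministic fixed-point inference given the
#' fitted topic-word distribution, so re-inferring a training note
#' reproduces its stored vector.
#'
#' @param notes Character vector of note texts.
#' @param k Number of topics (>= 2).
#' @param alpha,beta Symmetric Dirichlet priors (defaults `1 / k` and
#'   0.1, suited to short navigator notes where a heavy document prior
#'   would swamp the token evidence).
#' @param n_iter Gibbs sweeps (default 500).
#' @param seed Integer seed for the sampler.
#' @return An object of class `sdoh_topic_model` with elements `phi`
#'   (k x V topic-word matrix), `vocab`, `k`, and `doc_topics` (n x k
#'   matrix of training-document vectors).
#' @export
fit_topics <- function(notes, k, alpha = 1 / k, beta = 0.1,
                       n_iter = 500, seed = 1L) {
  stopifnot(k >= 2)
  token_lists <- lapply(notes, function(x) tokenize(x[1]))
  nonempty <- sum(vapply(token_lists, length, integer(1)) > 0)
  if (nonempty < k) {
    stop("fit_topics: need at least k = ", k, " non-empty documents, got ",
      nonempty,
      call. = FALSE
    )
  }
  vocab <- sort(unique(unlist(token_lists)))
  docs <- lapply(token_lists, function(t) match(t, vocab) - 1L)
  fit <- with_seed(seed, {
    lda_gibbs(docs, length(vocab), as.integer(k), alpha, beta,
      as.integer(n_iter))
  })
  phi <- (fit$nkw + beta) / (fit$nk + length(vocab) * beta)
  colnames(phi) <- vocab
  model <- structure(
    list(
      phi = phi, vocab = vocab, k = as.integer(k),
      alpha = alpha, beta = beta, n_iter = n_iter, seed = seed
    ),
    class = "sdoh_topic_model"
  )
  model$doc_topics <- t(vapply(
    token_lists,
    function(t) infer_theta(model, t),
    numeric(k)
  ))
  model
}

#' @export
print.sdoh_topic_model <- function(x, ...) {
  cat("<sdoh_topic_model> k =", x$k, "topics over", length(x$vocab),
    "terms\n")
  invisible(x)
}

# Deterministic topic-mixture inference with phi fixed: iterate the
# EM fixed point theta_k <- (alpha + sum_i p(z_i = k)) / (k*alpha + N)
# from a uniform start. Out-of-vocabulary tokens are ignored.
infer_theta <- function(model, tokens, max_iter = 200, tol = 1e-12) {
  ids <- match(tokens, model$vocab)
  ids <- ids[!is.na(ids)]
  k <- model$k
  if (length(ids) == 0) {
    return(rep(1 / k, k))
  }
  phi_w <- model$phi[, ids, drop = FALSE]
  theta <- rep(1 / k, k)
  a <- model$alpha
  for (i in seq_len(max_iter)) {
    post <- phi_w * theta
    post <- sweep(post, 2, colSums(post), "/")
    theta_new <- (a + rowSums(post)) / (k * a + length(ids))
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  as.numeric(theta / sum(theta))
}

#' Convert a note into its topic-probability vector
#'
#' @param model A fitted [fit_topics()] model.
#' @param note A single note text (may be empty: empty notes map to the
#'   uniform vector, carrying no topical information).
#' @return Numeric vector of length `k`, nonnegative, summing to 1.
#' @export
note_to_vector <- function(model, note) {
  stopifnot(inherits(model, "sdoh_topic_model"))
  infer_theta(model, tokenize(note))
}

#' Topic-feature matrix for a set of notes
#'
#' @param model A fitted [fit_topics()] model.
#' @param notes Character vector of notes.
#' @return An `n x k` matrix with columns `topic_1..topic_k`.
#' @export
notes_to_matrix <- function(model, notes) {
  m <- t(vapply(notes, function(x) note_to_vector(model, x),
    numeric(model$k),
    USE.NAMES = FALSE
  ))
  colnames(m) <- paste0("topic_", seq_len(model$k))
  m
}
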