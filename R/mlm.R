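#' Fit a smoothed unigram masked language model
#'
#' The reference masked-LM backend: a context-free unigram model with
#' additive smoothing, `p(t) = (count(t) + alpha) / (N + alpha * V)`. It
#' implements the masked-LM contract — `conditional_prob(token, left, right)`
#' returning a probability in (0, 1] — and exists so that pseudo-perplexity
#' scoring and the whole active-learning loop run at desk scale.
#' Transformer-scale masked LMs plug in behind the same contract.
#'
#' @param corpus Tokens to train on: a character vector, a list of token
#'   vectors, or a sentence pool tibble with a `tokens` list-column.
#' @param smoothing Additive smoothing constant `alpha >= 0` (default 1).
#' @return An object of class `masked_lm` with elements `conditional_prob`
#'   (function), `vocab_size`, `n_tokens`, and `fingerprint` (stable hash of
#'   the trained state).
#' @export
fit_unigram_mlm <- function(corpus, smoothing = 1) {
  tokens <- corpus_tokens(corpus)
  if (!is.numeric(smoothing) || smoothing < 0) {
    abort("smoothing must be a non-negative number",
          class = "alextract_param_error")
  }
  if (!length(tokens) && smoothing == 0) {
    abort("cannot fit an unsmoothed unigram model on an empty corpus",
          class = "alextract_param_error")
  }
  counts <- table(tokens)
  vocab <- names(counts)
  n <- length(tokens)
  v <- length(vocab)
  denom <- n + smoothing * v
  probs <- (as.numeric(counts) + smoothing) / denom
  prob_env <- list2env(as.list(setNames(probs, vocab)),
                       parent = emptyenv())
  p_unseen <- if (denom > 0) smoothing / denom else NA_real_
  fingerprint <- rlang::hash(list("unigram", as.integer(counts), vocab,
                                  smoothing))
  structure(
    list(
      type = "unigram",
      conditional_prob = function(token, left = character(),
                                  right = character()) {
        p <- get0(token, envir = prob_env, ifnotfound = p_unseen)
        if (!is.finite(p) || p <= 0) {
          abort(sprintf("model assigns no probability to token '%s'", token),
                class = "alextract_mlm_error")
        }
        p
      },
      vocab_size = v,
      n_tokens = n,
      smoothing = smoothing,
      fingerprint = fingerprint
    ),
    class = "masked_lm"
  )
}

# normalize the accepted corpus representations to one token vector
corpus_tokens <- function(corpus) {
  if (is.character(corpus)) {
    return(corpus)
  }
  if (is.data.frame(corpus) && "tokens" %in% names(corpus)) {
    return(unlist(map(corpus$tokens,
                      function(t) if (is.data.frame(t)) t$surface else t),
                  use.names = FALSE))
  }
  if (is.list(corpus)) {
    return(unlist(corpus, use.names = FALSE))
  }
  abort("unsupported corpus representation", class = "alextract_param_error")
}

#' Build a masked LM from an explicit probability function
#'
#' Convenience wrapper for tests and custom backends.
#'
#' @param conditional_prob Function `(token, left, right) -> probability`.
#' @param fingerprint Stable identifier of the model state.
#' @return A `masked_lm` object.
#' @export
masked_lm <- function(conditional_prob, fingerprint = rlang::hash(body(conditional_prob))) {
  structure(
    list(type = "custom", conditional_prob = conditional_prob,
         fingerprint = fingerprint),
    class = "masked_lm"
  )
}

#' Pseudo-perplexity of a token sequence under a masked language model
#'
#' Each token is masked out in turn and scored given the remaining tokens;
#' the pseudo-perplexity is `exp(-mean(log p))` over those conditional
#' probabilities (natural logarithm). Probabilities are floored at `eps`
#' before the log, since the quantity is undefined at p = 0. A perfectly
#' predicted sentence scores 1; rarer, more surprising content scores
#' higher.
#'
#' @param mlm A `masked_lm`.
#' @param tokens Character vector of at least one token.
#' @param eps Probability floor (default 1e-12).
#' @return A single positive number.
#' @examples
#' m <- fit_unigram_mlm(c("a", "a", "b", "a"), smoothing = 0)
#' pseudo_perplexity(m, c("a", "b"))  # (0.75 * 0.25)^(-1/2)
#' @export
pseudo_perplexity <- function(mlm, tokens, eps = 1e-12) {
  stopifnot(inherits(mlm, "masked_lm"))
  n <- length(tokens)
  if (n < 1) {
    abort("cannot score an empty token sequence",
          class = "alextract_param_error")
  }
  logs <- vapply(seq_len(n), function(i) {
    p <- mlm$conditional_prob(tokens[i], tokens[seq_len(i - 1)],
                              tokens[seq_len(n) > i])
    if (!is.finite(p)) {
      abort(sprintf("non-finite probability for token '%s'", tokens[i]),
            class = "alextract_mlm_error")
    }
    log(max(p, eps))
  }, numeric(1))
  exp(-mean(logs))
}

#' Score a pool of sentences with pseudo-perplexity
#'
#' One `(length, ppl)` acquisition score per sentence, in input order.
#' Scores are cached per (model fingerprint, token content), so rescoring an
#' unchanged pool under the same model is free — the masked LM used for
#' acquisition is typically fixed across active-learning iterations.
#'
#' @param mlm A `masked_lm`.
#' @param sentences Sentences to score: a named list of token vectors, or a
#'   pool tibble with `sent_id` and a `tokens` list-column.
#' @param eps Probability floor passed to [pseudo_perplexity()].
#' @return A tibble with columns `sent_id`, `length`, `ppl`.
#' @export
score_pool <- function(mlm, sentences, eps = 1e-12) {
  stopifnot(inherits(mlm, "masked_lm"))
  if (is.data.frame(sentences)) {
    ids <- sentences$sent_id
    toks <- map(sentences$tokens,
                function(t) if (is.data.frame(t)) t$surface else t)
  } else {
    ids <- names(sentences) %||% paste0("s", seq_along(sentences))
    toks <- sentences
  }
  ppl <- map_dbl(seq_along(ids), function(i) {
    key <- paste0(mlm$fingerprint, "|", rlang::hash(toks[[i]]))
    hit <- get0(key, envir = the$score_cache, ifnotfound = NULL)
    if (!is.null(hit)) {
      return(hit)
    }
    val <- tryCatch(
      pseudo_perplexity(mlm, toks[[i]], eps = eps),
      error = function(e) {
        abort(sprintf("scoring failed for sentence '%s': %s",
                      ids[i], conditionMessage(e)),
              class = "alextract_mlm_error")
      }
    )
    assign(key, val, envir = the$score_cache)
    val
  })
  tibble(sent_id = unname(ids), length = unname(map_int(toks, length)),
         ppl = unname(ppl))
}

#' Generate masked-LM training pairs by random masking
#'
#' For each sentence, `ceiling(rate * n)` token positions are replaced by
#' the mask symbol and the original tokens recorded as prediction targets.
#' Mask positions are drawn uniformly without replacement under the seed.
#'
#' @param sentences A list of token vectors (or a pool tibble with a
#'   `tokens` list-column).
#' @param rate Masking rate in (0, 1); default 0.15.
#' @param seed Integer seed.
#' @param mask_symbol Replacement token (default `"[MASK]"`).
#' @return A tibble with list-columns `masked` (tokens with masks applied),
#'   `targets` (original tokens at masked positions) and `positions`.
#' @export
mask_tokens <- function(sentences, rate = 0.15, seed = 1L,
                        mask_symbol = "[MASK]") {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate >= 1) {
    abort("masking rate must lie strictly between 0 and 1",
          class = "alextract_param_error")
  }
  if (is.data.frame(sentences)) {
    sentences <- map(sentences$tokens,
                     function(t) if (is.data.frame(t)) t$surface else t)
  }
  withr::with_seed(seed, {
    rows <- map(sentences, function(toks) {
      n <- length(toks)
      k <- ceiling(rate * n)
      pos <- sort(sample.int(n, k))
      masked <- toks
      masked[pos] <- mask_symbol
      list(masked = masked, targets = toks[pos], positions = pos)
    })
  })
  tibble(
    masked = map(rows, "masked"),
    targets = map(rows, "targets"),
    positions = map(rows, "positions")
  )
}
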