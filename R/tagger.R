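#' Reference sequence tagger
#'
#' A deliberately simple, fully deterministic per-token classifier over
#' window features — the token surface (lowercased), the previous and next
#' surfaces, and a casing/digit shape — combined naive-Bayes style with
#' additive smoothing. It implements the sequence-tagger contract
#' (`fit`/`predict` over IOB sequences) so the active-learning loop runs at
#' desk scale; transformer taggers plug in behind the same contract and make
#' no appearance in the tests.
#'
#' Warm starts are supported by count pooling: `init` supplies a previously
#' fitted tagger whose feature counts are added to the new training counts,
#' which is how source-domain knowledge is carried into a target-domain
#' fine-tune.
#'
#' @param iob Training data: tibble with columns `sent_id`, `surface`,
#'   `tag` (as from [encode_iob()]); at least one sequence.
#' @param seed Integer seed (kept for the backend contract; this backend's
#'   fit is closed-form and uses no randomness).
#' @param init Optional previously fitted `ref_tagger` to warm-start from.
#' @param alpha Additive smoothing for the per-feature likelihoods.
#' @return An object of class `ref_tagger`.
#' @export
fit_reference_tagger <- function(iob, seed = 0L, init = NULL, alpha = 0.5) {
  if (!nrow(iob)) {
    abort("cannot fit a tagger on an empty training set",
          class = "alextract_param_error")
  }
  feats <- token_features(iob)
  counts <- feats |>
    tidyr::pivot_longer(c("f_surface", "f_prev", "f_next", "f_shape"),
                        names_to = "feature", values_to = "value") |>
    count(.data$feature, .data$value, .data$tag, name = "n")
  priors <- count(feats, .data$tag, name = "n")
  if (!is.null(init)) {
    stopifnot(inherits(init, "ref_tagger"))
    counts <- bind_rows(init$counts, counts) |>
      group_by(.data$feature, .data$value, .data$tag) |>
      summarise(n = sum(.data$n), .groups = "drop")
    priors <- bind_rows(init$priors, priors) |>
      group_by(.data$tag) |>
      summarise(n = sum(.data$n), .groups = "drop")
  }
  build_nb_model(counts, priors, alpha, class = "ref_tagger")
}

# shared naive-Bayes scaffolding for the reference backends ------------------

build_nb_model <- function(counts, priors, alpha, class) {
  counts <- arrange(counts, .data$feature, .data$value, .data$tag)
  priors <- arrange(priors, .data$tag)
  tags <- priors$tag
  prior_n <- setNames(priors$n, tags)
  n_values <- counts |>
    distinct(.data$feature, .data$value) |>
    count(.data$feature, name = "v")
  v_f <- setNames(n_values$v, n_values$feature)
  cnt_env <- list2env(
    as.list(setNames(counts$n,
                     paste0(counts$feature, "\r", counts$value, "\r",
                            counts$tag))),
    parent = emptyenv())
  # which tags were ever seen with a given (feature, value)
  seen <- counts |>
    group_by(.data$feature, .data$value) |>
    summarise(tags = list(.data$tag), .groups = "drop")
  seen_env <- list2env(
    as.list(setNames(seen$tags, paste0(seen$feature, "\r", seen$value))),
    parent = emptyenv())
  structure(
    list(counts = counts, priors = priors, tags = tags, prior_n = prior_n,
         v_f = v_f, cnt_env = cnt_env, seen_env = seen_env, alpha = alpha,
         fingerprint = rlang::hash(list(class, counts, priors, alpha))),
    class = c(class, "nb_backend")
  )
}

# log-score `cand` tags for one instance; features = named list
# feature_type -> character vector of observed values (possibly several)
nb_score <- function(model, features, cand = model$tags) {
  alpha <- model$alpha
  total <- sum(model$prior_n)
  k <- length(model$tags)
  scores <- log((model$prior_n[cand] + alpha) / (total + alpha * k))
  env <- model$cnt_env
  for (f in names(features)) {
    vf <- model$v_f[[f]] %||% 0
    denom <- model$prior_n[cand] + alpha * (vf + 1)
    for (val in features[[f]]) {
      pre <- paste0(f, "\r", val, "\r")
      cn <- vapply(cand, function(tg) {
        get0(paste0(pre, tg), envir = env, ifnotfound = 0)
      }, numeric(1), USE.NAMES = FALSE)
      scores <- scores + log((cn + alpha) / denom)
    }
  }
  scores
}

token_features <- function(iob) {
  low <- tolower(iob$surface)
  n <- length(low)
  # sentence-aware lag/lead without per-group dispatch
  new_sent <- c(TRUE, iob$sent_id[-1] != iob$sent_id[-n])
  prev <- c("<bos>", low[-n])
  prev[new_sent] <- "<bos>"
  nxt <- c(low[-1], "<eos>")
  nxt[c(new_sent[-1], TRUE)] <- "<eos>"
  iob$f_surface <- low
  iob$f_prev <- prev
  iob$f_next <- nxt
  iob$f_shape <- token_shape(iob$surface)
  iob
}

token_shape <- function(x) {
  s <- gsub("[[:upper:]]", "X", x)
  s <- gsub("[[:lower:]]", "x", s)
  s <- gsub("[0-9]", "d", s)
  s <- gsub("[^Xxd]", "p", s)
  gsub("(.)\\1+", "\\1", s)
}

#' Predict IOB tags with a reference tagger
#'
#' Tags are predicted token by token. For a surface seen in training, the
#' candidate set is the tags observed with that surface (scored with all
#' four features); for an unseen surface, all tags are scored from the
#' context and shape features alone, which under O-dominated training data
#' falls back to `O`. Ties break deterministically toward the
#' alphabetically first tag with `O` preferred.
#'
#' @param object A `ref_tagger`.
#' @param newdata Tibble with columns `sent_id` and `surface`.
#' @param ... Unused.
#' @return Character vector of predicted tags, one per row of `newdata`.
#' @export
predict.ref_tagger <- function(object, newdata, ...) {
  if (!nrow(newdata)) {
    return(character())
  }
  newdata$tag <- "O"  # placeholder so token_features() works
  feats <- token_features(newdata)
  tag_order <- c(intersect("O", object$tags),
                 sort(setdiff(object$tags, "O")))
  out <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    surf <- feats$f_surface[i]
    seen <- get0(paste0("f_surface\r", surf), envir = object$seen_env,
                 ifnotfound = NULL)
    if (!is.null(seen)) {
      cand <- intersect(tag_order, seen)
      fl <- list(f_surface = surf, f_prev = feats$f_prev[i],
                 f_next = feats$f_next[i], f_shape = feats$f_shape[i])
    } else {
      cand <- tag_order
      fl <- list(f_prev = feats$f_prev[i], f_next = feats$f_next[i],
                 f_shape = feats$f_shape[i])
    }
    sc <- nb_score(object, fl, cand)
    out[i] <- cand[which.max(sc)]
  }
  out
}

#' Predict entity spans for every sentence of a document
#'
#' Runs the tagger over the document's tokens and decodes the predicted IOB
#' tags back to offset-anchored entity spans (orphan `I-` tags repaired).
#'
#' @param tagger A fitted `ref_tagger`.
#' @param doc An `ie_document`, or a tibble of tokens with `sent_id`,
#'   `surface`, `start`, `end`.
#' @return A tibble of predicted entities: `sent_id`, `label`, `start`,
#'   `end`.
#' @export
predict_entities <- function(tagger, doc) {
  tokens <- if (inherits(doc, "ie_document")) doc$tokens else as_tibble(doc)
  if (!nrow(tokens)) {
    return(tibble(sent_id = character(), label = character(),
                  start = integer(), end = integer()))
  }
  tokens$tag <- predict(tagger, tokens)
  chunks <- split(tokens, factor(tokens$sent_id, levels = unique(tokens$sent_id)))
  out <- imap(chunks, function(ch, sid) {
    sp <- iob_to_spans(ch$tag, ch)
    if (!nrow(sp)) return(NULL)
    tibble::new_tibble(list(sent_id = rep(sid, nrow(sp)), label = sp$label,
                            start = sp$start, end = sp$end),
                       nrow = nrow(sp))
  })
  bind_rows(out)
}
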