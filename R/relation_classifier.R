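#' Reference relation classifier
#'
#' A deterministic naive-Bayes classifier over features of an entity pair:
#' the unordered pair of entity classes, a bucketed token distance, and the
#' bag of (lowercased) token surfaces lying strictly between the two spans.
#' All features are computed on the offset-ordered pair, so the classifier
#' is symmetric in argument order by construction — relation direction
#' carries no meaning. As with the reference tagger, it exists to exercise
#' the active-learning loop at desk scale behind the relation-classifier
#' contract; transformer relation models plug in behind the same contract.
#'
#' Warm starts pool feature counts from `init` with the new training counts.
#'
#' @param samples Relation samples (from [generate_relation_samples()] /
#'   [oversample_positives()]); the `label` column is the training target
#'   and must contain at least one value.
#' @param tokens Tibble of tokens covering the samples' sentences
#'   (`sent_id`, `surface`, `start`, `end`), used for the between-span bag.
#' @param seed Integer seed (contract only; the fit is closed-form).
#' @param init Optional previously fitted `ref_relation_classifier`.
#' @param alpha Additive smoothing.
#' @return An object of class `ref_relation_classifier`.
#' @export
fit_reference_relation_classifier <- function(samples, tokens, seed = 0L,
                                              init = NULL, alpha = 0.5) {
  if (!nrow(samples)) {
    abort("cannot fit a relation classifier on an empty training set",
          class = "alextract_param_error")
  }
  feats <- relation_features(samples, tokens)
  counts <- tibble(feature = feats$feature, value = feats$value,
                   tag = rep(samples$label, attr(feats, "n_feats"))) |>
    count(.data$feature, .data$value, .data$tag, name = "n")
  priors <- count(tibble(tag = samples$label), .data$tag, name = "n")
  if (!is.null(init)) {
    stopifnot(inherits(init, "ref_relation_classifier"))
    counts <- bind_rows(init$counts, counts) |>
      group_by(.data$feature, .data$value, .data$tag) |>
      summarise(n = sum(.data$n), .groups = "drop")
    priors <- bind_rows(init$priors, priors) |>
      group_by(.data$tag) |>
      summarise(n = sum(.data$n), .groups = "drop")
  }
  build_nb_model(counts, priors, alpha, class = "ref_relation_classifier")
}

# long (feature, value) record per sample, plus per-sample row counts; all
# features are computed on the offset-ordered pair (symmetry). Plain vectors:
# this sits in the innermost training/prediction loop.
relation_features <- function(samples, tokens) {
  n <- nrow(samples)
  tok_sent <- if (!is.null(tokens)) as.character(tokens$sent_id) else character()
  tok_start <- tokens$start
  tok_end <- tokens$end
  tok_low <- if (!is.null(tokens)) tolower(tokens$surface) else character()
  tok_idx <- split(seq_along(tok_sent), tok_sent)

  swap <- samples$e2_start < samples$e1_start |
    (samples$e2_start == samples$e1_start & samples$e2_end < samples$e1_end)
  first_end <- ifelse(swap, samples$e2_end, samples$e1_end)
  second_start <- ifelse(swap, samples$e1_start, samples$e2_start)
  pairlab <- paste(pmin(samples$e1_label, samples$e2_label),
                   pmax(samples$e1_label, samples$e2_label), sep = "|")

  feature <- vector("list", n)
  value <- vector("list", n)
  n_feats <- integer(n)
  for (i in seq_len(n)) {
    ti <- tok_idx[[samples$sent_id[i]]]
    between <- character()
    if (!is.null(ti)) {
      mid <- ti[tok_start[ti] >= first_end[i] & tok_end[ti] <= second_start[i]]
      between <- tok_low[mid]
    }
    nb <- length(between)
    dist <- if (nb <= 2) as.character(nb) else if (nb <= 4) "3-4" else
      if (nb <= 7) "5-7" else "8+"
    feature[[i]] <- c("pair", "dist", rep("between", nb))
    value[[i]] <- c(pairlab[i], dist, between)
    n_feats[i] <- 2L + nb
  }
  structure(
    list(feature = unlist(feature, use.names = FALSE),
         value = unlist(value, use.names = FALSE)),
    n_feats = n_feats
  )
}

#' Predict relation labels for candidate samples
#'
#' @param object A `ref_relation_classifier`.
#' @param newdata Relation samples tibble (same columns as the training
#'   samples, label not required).
#' @param tokens Tokens covering the samples' sentences, as in
#'   [fit_reference_relation_classifier()].
#' @param ... Unused.
#' @return Character vector of predicted labels (possibly `"no_relation"`),
#'   one per sample.
#' @export
predict.ref_relation_classifier <- function(object, newdata, tokens = NULL,
                                            ...) {
  if (!nrow(newdata)) {
    return(character())
  }
  feats <- relation_features(newdata, tokens)
  n_feats <- attr(feats, "n_feats")
  idx <- rep(seq_len(nrow(newdata)), n_feats)
  rows_of <- split(seq_along(idx), idx)
  tag_order <- c(intersect("no_relation", object$tags),
                 sort(setdiff(object$tags, "no_relation")))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    rows <- rows_of[[as.character(i)]]
    fl <- split(feats$value[rows], feats$feature[rows])
    sc <- nb_score(object, fl, tag_order)
    out[i] <- tag_order[which.max(sc)]
  }
  out
}
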