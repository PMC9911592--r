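#' Configuration for an active-learning run
#'
#' Collects the hyperparameters of the annotate-train-query cycle. The
#' defaults follow the reference workflow: an initial random seed set of
#' 268 sentences, 100 queried sentences per iteration, strategic sampling in
#' the (0.75, 0.90] percentile band, positives oversampled 4x inside each
#' retraining call (train split only), and a guard of 50 iterations for
#' non-converging configurations.
#'
#' @param n_init Size of the initial random seed set (default 268).
#' @param batch_size Sentences queried per iteration (default 100).
#' @param strategy Query strategy per iteration: a single string
#'   (`"random"` or `"strategic"`), a character vector indexed by iteration
#'   (last element recycled), or a function `iteration -> strategy`. See
#'   [strategy_schedule()] for the switch-at-iteration-k protocol.
#' @param band Percentile band for strategic sampling.
#' @param seed Integer master seed; all per-iteration draws derive from it.
#' @param n_iterations Maximum number of query iterations (in addition to
#'   any metric-based stopping).
#' @param stop_metric,stop_threshold Optional early stopping: a history
#'   column name (e.g. `"ner_macro_f1"`) and the held-out score at which
#'   annotation stops.
#' @param test_pool Optional held-out sentence pool evaluated after every
#'   retraining.
#' @param oversample_factor Positive-relation oversampling factor.
#' @param warm_start Refit backends warm-started from the previous
#'   iteration's counts instead of cold from the labeled set.
#' @param mlm Optional pre-fitted `masked_lm` used for acquisition scoring;
#'   by default a unigram model is fitted once on the full unlabeled pool
#'   and kept fixed across iterations.
#' @return An `al_config` list.
#' @export
al_config <- function(n_init = 268, batch_size = 100, strategy = "strategic",
                      band = c(0.75, 0.90), seed = 1L, n_iterations = 50,
                      stop_metric = NULL, stop_threshold = NULL,
                      test_pool = NULL, oversample_factor = 4,
                      warm_start = FALSE, mlm = NULL) {
  structure(
    list(n_init = n_init, batch_size = batch_size, strategy = strategy,
         band = band, seed = as.integer(seed), n_iterations = n_iterations,
         stop_metric = stop_metric, stop_threshold = stop_threshold,
         test_pool = test_pool, oversample_factor = oversample_factor,
         warm_start = warm_start, mlm = mlm),
    class = "al_config"
  )
}

#' A query schedule that switches strategy at a fixed iteration
#'
#' Returns a schedule function for [al_config()]'s `strategy` argument:
#' random sampling up to (excluding) `switch_at`, strategic sampling from
#' then on — the protocol of intervening with strategic sampling after a
#' random warm-up phase.
#'
#' @param switch_at First iteration that uses strategic sampling
#'   (default 8).
#' @return A function `iteration -> "random" | "strategic"`.
#' @export
strategy_schedule <- function(switch_at = 8) {
  force(switch_at)
  function(iteration) if (iteration < switch_at) "random" else "strategic"
}

strategy_for <- function(config, iteration) {
  s <- config$strategy
  out <- if (is.function(s)) {
    s(iteration)
  } else {
    s[[min(iteration, length(s))]]
  }
  if (!out %in% c("random", "strategic")) {
    abort(sprintf("unknown strategy '%s'", out),
          class = "alextract_param_error")
  }
  out
}

#' Initialize the active-learning state
#'
#' Draws the initial seed set uniformly from the pool, has the annotator
#' label it (no soft labels exist yet), fits the backends once on the seed
#' set, and fits (or accepts) the masked LM used for acquisition scoring on
#' the full pool — scoring is intrinsic and needs no labels.
#'
#' @param pool Sentence pool (tibble from [as_sentence_pool()], or a
#'   `synth_corpus`).
#' @param annotator An annotator (e.g. [oracle_annotator()]).
#' @param config An [al_config()].
#' @param schema Annotation schema.
#' @return An `al_state`: labeled/unlabeled id partition, iteration
#'   counter, per-iteration history, backend handles.
#' @export
initialize_state <- function(pool, annotator, config = al_config(),
                             schema = default_schema()) {
  if (inherits(pool, "synth_corpus")) {
    pool <- pool$pool
  }
  if (config$n_init < 1 || config$n_init > nrow(pool)) {
    abort(sprintf("n_init (%d) must lie in 1..pool size (%d)",
                  config$n_init, nrow(pool)),
          class = "alextract_param_error")
  }
  seed_ids <- random_sample(pool$sent_id, config$n_init, seed = config$seed)
  pool <- annotate_into_pool(pool, seed_ids, annotator, soft = NULL)
  mlm <- config$mlm %||% fit_unigram_mlm(pool)
  test_cache <- NULL
  if (!is.null(config$test_pool)) {
    tp <- config$test_pool
    if (inherits(tp, "synth_corpus")) tp <- tp$pool
    config$test_pool <- tp
    test_cache <- list(
      tokens = pool_tokens(tp),
      gold_ent = pool_entities(tp),
      gold_samples = pool_relation_samples(tp, schema = schema,
                                           split = "test")
    )
  }
  state <- structure(
    list(pool = pool, labeled_ids = seed_ids,
         unlabeled_ids = setdiff(pool$sent_id, seed_ids),
         iteration = 0L, history = NULL, proposed = NULL,
         tagger = NULL, relation_classifier = NULL, mlm = mlm,
         test_cache = test_cache, config = config, schema = schema),
    class = "al_state"
  )
  fit_backends(state)
}

# run the annotator over a set of ids, writing its (corrected) annotations
# back into the pool's gold columns
annotate_into_pool <- function(pool, ids, annotator, soft = NULL) {
  for (sid in ids) {
    i <- match(sid, pool$sent_id)
    srow <- if (!is.null(soft)) soft[soft$sent_id == sid, ] else NULL
    ann <- annotator$annotate(
      sid,
      soft_tags = if (!is.null(srow) && nrow(srow)) srow$soft_tags[[1]],
      soft_relations = if (!is.null(srow) && nrow(srow)) srow$soft_relations[[1]]
    )
    pool$entities[[i]] <- ann$entities
    pool$relations[[i]] <- ann$relations
  }
  pool
}

# (re)fit tagger and relation classifier on the current labeled set;
# retraining is always from the full labeled set, optionally warm-started
# from the previous counts
fit_backends <- function(state) {
  cfg <- state$config
  labeled <- state$pool[match(state$labeled_ids, state$pool$sent_id), ]
  iob <- pool_iob(labeled)
  tokens <- pool_tokens(labeled)
  samples <- pool_relation_samples(labeled, schema = state$schema)
  samples <- oversample_positives(samples, factor = cfg$oversample_factor,
                                  split = "train")
  init_tagger <- if (isTRUE(cfg$warm_start)) state$tagger
  init_rel <- if (isTRUE(cfg$warm_start)) state$relation_classifier
  state$tagger <- fit_reference_tagger(iob, seed = cfg$seed,
                                       init = init_tagger)
  state$relation_classifier <- fit_reference_relation_classifier(
    samples, tokens, seed = cfg$seed, init = init_rel)
  state
}

#' Propose the next annotation batch with soft labels
#'
#' Selects up to `batch_size` sentences from the unlabeled pool by the
#' given strategy, then pre-annotates each with the current tagger and
#' relation classifier. These predictions are the soft labels shown to the
#' annotator for correction — they are presentation-only and never enter
#' training uncorrected.
#'
#' @param state An `al_state`.
#' @param strategy `"random"` or `"strategic"` (default: the config's
#'   schedule at the next iteration).
#' @param seed Seed for the batch draw (default derived from the config
#'   seed and iteration).
#' @return A tibble with `sent_id` and list-columns `soft_tags`,
#'   `soft_entities`, `soft_relations`; zero rows when the pool is
#'   exhausted (completion, not an error). The strategy and fallback level
#'   are attached as attributes.
#' @export
propose_batch <- function(state, strategy = NULL, seed = NULL) {
  cfg <- state$config
  it <- state$iteration + 1L
  strategy <- strategy %||% strategy_for(cfg, it)
  seed <- seed %||% (cfg$seed + 1000L + it)
  unlabeled <- state$pool[match(state$unlabeled_ids, state$pool$sent_id), ]
  if (!nrow(unlabeled)) {
    out <- tibble(sent_id = character(), soft_tags = list(),
                  soft_entities = list(), soft_relations = list())
    attr(out, "strategy") <- strategy
    return(out)
  }
  k <- min(cfg$batch_size, nrow(unlabeled))
  fallback <- NA_character_
  ids <- if (strategy == "random") {
    random_sample(unlabeled$sent_id, k, seed = seed)
  } else {
    scores <- score_pool(state$mlm, unlabeled)
    sel <- strategic_sample(scores, band = cfg$band, batch_size = k,
                            seed = seed)
    fallback <- attr(sel, "fallback")
    as.character(sel)
  }
  batch <- unlabeled[match(ids, unlabeled$sent_id), ]
  tk_all <- pool_tokens(batch)
  tags_all <- predict(state$tagger, tk_all)
  tags_by_sent <- split(tags_all, factor(tk_all$sent_id,
                                         levels = batch$sent_id))
  ents_by_sent <- map(seq_len(nrow(batch)), function(i) {
    ents <- iob_to_spans(tags_by_sent[[i]], batch$tokens[[i]])
    ents$id <- if (nrow(ents)) paste0("P", seq_len(nrow(ents))) else character()
    ents
  })
  cand_all <- bind_rows(map(seq_len(nrow(batch)), function(i) {
    if (nrow(ents_by_sent[[i]]) < 2) return(NULL)
    generate_relation_samples(ents_by_sent[[i]], sent_id = batch$sent_id[i])
  }))
  if (nrow(cand_all)) {
    cand_all$label <- predict(state$relation_classifier, cand_all,
                              tokens = tk_all)
  } else {
    cand_all <- generate_relation_samples(empty_entities(), sent_id = "none")
  }
  rels_by_sent <- map(batch$sent_id, function(sid) {
    cand_all[cand_all$sent_id == sid, , drop = FALSE]
  })
  out <- tibble(
    sent_id = batch$sent_id,
    soft_tags = unname(tags_by_sent),
    soft_entities = ents_by_sent,
    soft_relations = rels_by_sent
  )
  attr(out, "strategy") <- strategy
  attr(out, "fallback") <- fallback
  out
}

#' Incorporate corrected annotations and retrain
#'
#' Moves the batch into the labeled set, writes the corrected annotations
#' into the pool, retrains both backends on the full labeled set, appends a
#' history row with the batch's diagnostics (size, average length and
#' pseudo-perplexity, entities per sentence, relation counts, the fraction
#' of soft tags the annotator accepted unchanged) and, when the config
#' holds a test pool, the held-out macro-F1 of both tasks.
#'
#' @param state An `al_state` whose last [propose_batch()] produced
#'   `proposed`.
#' @param proposed The batch returned by [propose_batch()].
#' @param corrected Tibble `(sent_id, entities, relations)` of
#'   annotator-corrected gold for exactly the proposed sentences; an
#'   annotation for an unproposed sentence is an error. Usually produced by
#'   [annotate_batch()].
#' @return The updated `al_state`.
#' @export
incorporate_annotations <- function(state, proposed, corrected) {
  extra <- setdiff(corrected$sent_id, proposed$sent_id)
  if (length(extra)) {
    abort(sprintf("corrected annotation for unproposed sentence(s): %s",
                  paste(head(extra, 3), collapse = ", ")),
          class = "alextract_param_error")
  }
  for (sid in corrected$sent_id) {
    i <- match(sid, state$pool$sent_id)
    j <- match(sid, corrected$sent_id)
    state$pool$entities[[i]] <- corrected$entities[[j]]
    state$pool$relations[[i]] <- corrected$relations[[j]]
  }
  state$labeled_ids <- c(state$labeled_ids, corrected$sent_id)
  state$unlabeled_ids <- setdiff(state$unlabeled_ids, corrected$sent_id)
  state$iteration <- state$iteration + 1L
  if (nrow(corrected)) {
    state <- fit_backends(state)
  }
  # soft-label utility: fraction of proposed tags accepted unchanged
  accept <- NA_real_
  if (nrow(proposed)) {
    batch_pool <- state$pool[match(proposed$sent_id, state$pool$sent_id), ]
    gold_tags <- unlist(map(seq_len(nrow(batch_pool)), function(i) {
      spans_to_iob(batch_pool$tokens[[i]], batch_pool$entities[[i]])$tag
    }))
    soft_tags <- unlist(proposed$soft_tags)
    accept <- mean(soft_tags == gold_tags)
  }
  row <- tibble(
    iteration = state$iteration,
    strategy = attr(proposed, "strategy") %||% NA_character_,
    fallback = attr(proposed, "fallback") %||% NA_character_,
    n_batch = nrow(corrected),
    n_labeled = length(state$labeled_ids),
    n_unlabeled = length(state$unlabeled_ids),
    soft_tag_accept = accept
  )
  if (nrow(corrected)) {
    batch_pool <- state$pool[match(corrected$sent_id, state$pool$sent_id), ]
    scores <- score_pool(state$mlm, batch_pool)
    row <- dplyr::bind_cols(row, select(batch_stats(batch_pool, scores),
                                        -"n_sentences"))
  }
  if (!is.null(state$config$test_pool)) {
    ev <- evaluate_cached(state$tagger, state$relation_classifier,
                          state$test_cache)
    row$ner_macro_f1 <- ev$ner$macro_f1
    row$re_macro_f1 <- ev$re$macro_f1
  }
  state$history <- bind_rows(state$history, row)
  state$proposed <- NULL
  state
}

#' Run an annotator over a proposed batch
#'
#' @param proposed Batch from [propose_batch()].
#' @param annotator An annotator object.
#' @return A `corrected` tibble for [incorporate_annotations()].
#' @export
annotate_batch <- function(proposed, annotator) {
  rows <- map(seq_len(nrow(proposed)), function(i) {
    ann <- annotator$annotate(proposed$sent_id[i],
                              soft_tags = proposed$soft_tags[[i]],
                              soft_relations = proposed$soft_relations[[i]])
    tibble(sent_id = proposed$sent_id[i],
           entities = list(ann$entities), relations = list(ann$relations))
  })
  if (!length(rows)) {
    return(tibble(sent_id = character(), entities = list(),
                  relations = list()))
  }
  bind_rows(rows)
}

#' Evaluate backends on a held-out pool
#'
#' NER is scored strict-span from raw tokens; RE is scored on the candidate
#' pairs generated from the gold entities (no oversampling — evaluation
#' reflects the actual label distribution), with `no_relation` excluded
#' from the macro mean.
#'
#' @param tagger A fitted tagger.
#' @param relation_classifier A fitted relation classifier.
#' @param test_pool Held-out sentence pool.
#' @param schema Annotation schema.
#' @return A list with `eval_report`s `ner` and `re`.
#' @export
evaluate_backends <- function(tagger, relation_classifier, test_pool,
                              schema = default_schema()) {
  if (inherits(test_pool, "synth_corpus")) {
    test_pool <- test_pool$pool
  }
  cache <- list(
    tokens = pool_tokens(test_pool),
    gold_ent = pool_entities(test_pool),
    gold_samples = pool_relation_samples(test_pool, schema = schema,
                                         split = "test")
  )
  evaluate_cached(tagger, relation_classifier, cache)
}

evaluate_cached <- function(tagger, relation_classifier, cache) {
  pred_ent <- predict_entities(tagger, cache$tokens)
  ner <- macro_f1_ner(
    cache$gold_ent[, c("sent_id", "label", "start", "end")],
    pred_ent[, c("sent_id", "label", "start", "end")]
  )
  pred_samples <- cache$gold_samples
  if (nrow(pred_samples)) {
    pred_samples$label <- predict(relation_classifier, pred_samples,
                                  tokens = cache$tokens)
  }
  re <- macro_f1_re(cache$gold_samples, pred_samples)
  list(ner = ner, re = re)
}

#' Stopping decision for the active-learning cycle
#'
#' Stops when the latest held-out metric reaches the threshold, when the
#' unlabeled pool is exhausted, or when the maximum number of iterations is
#' reached.
#'
#' @param state An `al_state`.
#' @param metric History column name (default from the config).
#' @param threshold Metric threshold (default from the config; `NULL`
#'   disables metric-based stopping).
#' @param max_iterations Iteration cap (default from the config).
#' @return `TRUE` or `FALSE`.
#' @export
should_stop <- function(state, metric = state$config$stop_metric,
                        threshold = state$config$stop_threshold,
                        max_iterations = state$config$n_iterations) {
  if (!length(state$unlabeled_ids)) {
    return(TRUE)
  }
  if (state$iteration >= max_iterations) {
    return(TRUE)
  }
  if (!is.null(metric) && !is.null(threshold) && !is.null(state$history) &&
      nrow(state$history)) {
    if (!metric %in% names(state$history)) {
      abort(sprintf("unknown stopping metric '%s'", metric),
            class = "alextract_param_error")
    }
    latest <- tail(state$history[[metric]], 1)
    if (!is.na(latest) && latest >= threshold) {
      return(TRUE)
    }
  }
  FALSE
}

#' Run the full active-learning cycle
#'
#' Initial seed annotation, then repeated query-annotate-retrain iterations
#' until [should_stop()] fires. The returned state carries the complete
#' per-iteration history (a machine-readable learning curve).
#'
#' @inheritParams initialize_state
#' @return The final `al_state`.
#' @examples
#' \donttest{
#' corpus <- generate_corpus(synth_config(n_sentences = 120), seed = 7)
#' oracle <- oracle_annotator(corpus)
#' cfg <- al_config(n_init = 20, batch_size = 10, n_iterations = 2,
#'                  strategy = "random", seed = 7)
#' st <- run_cycle(corpus, oracle, cfg)
#' st$history
#' }
#' @export
run_cycle <- function(pool, annotator, config = al_config(),
                      schema = default_schema()) {
  state <- initialize_state(pool, annotator, config, schema)
  while (!should_stop(state)) {
    proposed <- propose_batch(state)
    if (!nrow(proposed)) {
      break
    }
    corrected <- annotate_batch(proposed, annotator)
    state <- tryCatch(
      incorporate_annotations(state, proposed, corrected),
      error = function(e) {
        abort(sprintf("iteration %d failed: %s", state$iteration + 1L,
                      conditionMessage(e)),
              class = "alextract_al_error")
      }
    )
  }
  state
}

#' @export
print.al_state <- function(x, ...) {
  cat("<al_state>\n")
  cat("  iteration:", x$iteration, "\n")
  cat("  labeled:  ", length(x$labeled_ids), "\n")
  cat("  unlabeled:", length(x$unlabeled_ids), "\n")
  if (!is.null(x$history) && nrow(x$history)) {
    print(x$history, n = 5)
  }
  invisible(x)
}

#' Tidy an active-learning state into its iteration history
#'
#' @param x An `al_state`.
#' @param ... Unused.
#' @return The history tibble (one row per iteration).
#' @method tidy al_state
#' @export
tidy.al_state <- function(x, ...) {
  x$history %||% tibble(iteration = integer())
}

#' One-row summary of an active-learning state
#'
#' @param x An `al_state`.
#' @param ... Unused.
#' @return A one-row tibble: iterations run, labeled/unlabeled sizes, and
#'   the latest held-out scores if available.
#' @method glance al_state
#' @export
glance.al_state <- function(x, ...) {
  out <- tibble(
    iterations = x$iteration,
    n_labeled = length(x$labeled_ids),
    n_unlabeled = length(x$unlabeled_ids)
  )
  if (!is.null(x$history) && nrow(x$history)) {
    last <- tail(x$history, 1)
    for (col in intersect(c("ner_macro_f1", "re_macro_f1", "soft_tag_accept"),
                          names(last))) {
      out[[col]] <- last[[col]]
    }
  }
  out
}
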