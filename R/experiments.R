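#' Strategic-vs-random batch enrichment experiment
#'
#' For each seed: generate a corpus, fit the unigram masked LM on the full
#' pool, score it, then draw one strategic and one random batch of equal
#' size and compare their mean entities-per-sentence and the share of
#' entity mentions belonging to the corpus's rarest classes (the designated
#' minority classes). This is the batch-level diagnostic behind strategic
#' sampling: longer, higher-perplexity sentences carry more entities and a
#' fairer share of minority classes.
#'
#' @param config A [synth_config()].
#' @param seeds Integer vector of seeds (one corpus + draw per seed).
#' @param batch_size Batch size for both strategies.
#' @param band Percentile band for strategic sampling.
#' @return A tibble with one row per (seed, strategy):
#'   `avg_entities_per_sentence`, `rare_class_share`, `avg_length`,
#'   `avg_ppl`.
#' @export
enrichment_experiment <- function(config = synth_config(),
                                  seeds = 1:5, batch_size = 100,
                                  band = c(0.75, 0.90)) {
  rows <- map(seeds, function(sd) {
    corpus <- generate_corpus(config, seed = sd)
    mlm <- fit_unigram_mlm(corpus$pool)
    scores <- score_pool(mlm, corpus$pool)
    rare <- config$minority_classes
    batch_row <- function(ids, strategy) {
      sub <- corpus$pool[match(ids, corpus$pool$sent_id), ]
      st <- batch_stats(sub, scores)
      tibble(
        seed = sd, strategy = strategy,
        avg_entities_per_sentence = st$avg_entities_per_sentence,
        rare_class_share = rare_class_share(st$class_histogram[[1]], rare),
        avg_length = st$avg_sentence_length,
        avg_ppl = st$avg_ppl
      )
    }
    bind_rows(
      batch_row(strategic_sample(scores, band = band,
                                 batch_size = batch_size, seed = sd),
                "strategic"),
      batch_row(random_sample(corpus$pool$sent_id, batch_size, seed = sd),
                "random")
    )
  })
  bind_rows(rows)
}

#' Strategic-vs-random learning-curve experiment
#'
#' Runs the full simulated active-learning cycle twice per seed — once with
#' an all-random schedule, once with the strategic schedule — against a
#' held-out test pool from the same generative configuration, and reports
#' the final held-out macro-F1 of both tasks.
#'
#' @param config A [synth_config()] for the training pool.
#' @param seeds Integer seeds (one pair of runs per seed).
#' @param n_init Initial seed-set size.
#' @param batch_size Sentences per iteration.
#' @param n_iterations Query iterations after the seed set.
#' @param test_fraction Fraction of generated sentences held out for
#'   evaluation.
#' @param band Percentile band for strategic sampling.
#' @return A tibble with one row per (seed, strategy): final
#'   `ner_macro_f1`, `re_macro_f1`, `n_labeled`.
#' @export
strategy_comparison_experiment <- function(config = synth_config(n_sentences = 1200),
                                           seeds = 1:5, n_init = 100,
                                           batch_size = 50, n_iterations = 5,
                                           test_fraction = 0.25,
                                           band = c(0.75, 0.90)) {
  rows <- map(seeds, function(sd) {
    corpus <- generate_corpus(config, seed = sd)
    n_test <- round(test_fraction * nrow(corpus$pool))
    test_ids <- random_sample(corpus$pool$sent_id, n_test, seed = sd + 500L)
    test_pool <- corpus$pool[match(test_ids, corpus$pool$sent_id), ]
    train_pool <- corpus$pool[!corpus$pool$sent_id %in% test_ids, ]
    oracle <- oracle_annotator(corpus$pool)
    run_one <- function(strategy) {
      cfg <- al_config(n_init = n_init, batch_size = batch_size,
                       strategy = strategy, band = band, seed = sd,
                       n_iterations = n_iterations, test_pool = test_pool)
      st <- run_cycle(train_pool, oracle, cfg)
      last <- tail(st$history, 1)
      tibble(seed = sd, strategy = strategy,
             ner_macro_f1 = last$ner_macro_f1,
             re_macro_f1 = last$re_macro_f1,
             n_labeled = last$n_labeled)
    }
    bind_rows(run_one("random"), run_one("strategic"))
  })
  bind_rows(rows)
}

#' Warm-start domain-transfer experiment
#'
#' For each overlap level and seed: generate a domain pair, train source
#' backends on labeled domain-A sentences, then fine-tune on a small
#' labeled domain-B set either warm-started from the source counts or cold,
#' and evaluate both on held-out domain-B sentences. Reports the held-out
#' NER and RE macro-F1 of both starts and the warm-start gain.
#'
#' @param overlaps Numeric vector of vocabulary/template overlap levels.
#' @param seeds Integer seeds.
#' @param config Base [synth_config()] for both domains.
#' @param n_source Labeled domain-A sentences for source training.
#' @param n_target Labeled domain-B sentences for fine-tuning (kept small:
#'   the low-resource setting warm starts are for).
#' @param n_test Held-out domain-B sentences.
#' @return A tibble with one row per (overlap, seed, start) plus the
#'   per-(overlap, seed) `ner_gain` and `re_gain` on the warm rows.
#' @export
warm_start_experiment <- function(overlaps = c(0.8, 0.2), seeds = 1:5,
                                  config = synth_config(n_sentences = 700),
                                  n_source = 500, n_target = 200,
                                  n_test = 150) {
  rows <- map(overlaps, function(ov) {
    map(seeds, function(sd) {
      pair <- make_domain_pair(config, overlap = ov, seed = sd)
      src <- pair$A$pool
      src_ids <- random_sample(src$sent_id, min(n_source, nrow(src)),
                               seed = sd + 1L)
      src_pool <- src[match(src_ids, src$sent_id), ]
      tgt <- pair$B$pool
      tgt_ids <- random_sample(tgt$sent_id,
                               min(n_target + n_test, nrow(tgt)),
                               seed = sd + 2L)
      fit_ids <- tgt_ids[seq_len(min(n_target, length(tgt_ids) - 1))]
      test_ids <- setdiff(tgt_ids, fit_ids)
      fit_pool <- tgt[match(fit_ids, tgt$sent_id), ]
      test_pool <- tgt[match(test_ids, tgt$sent_id), ]

      fit_pair <- function(pool, init_tagger = NULL, init_rel = NULL) {
        iob <- pool_iob(pool)
        tokens <- pool_tokens(pool)
        samples <- oversample_positives(
          pool_relation_samples(pool), factor = 4, split = "train")
        list(
          tagger = fit_reference_tagger(iob, seed = sd, init = init_tagger),
          rel = fit_reference_relation_classifier(samples, tokens,
                                                  seed = sd, init = init_rel)
        )
      }
      source <- fit_pair(src_pool)
      warm <- fit_pair(fit_pool, source$tagger, source$rel)
      cold <- fit_pair(fit_pool)
      score <- function(models, start) {
        ev <- evaluate_backends(models$tagger, models$rel, test_pool)
        tibble(overlap = ov, seed = sd, start = start,
               ner_macro_f1 = ev$ner$macro_f1, re_macro_f1 = ev$re$macro_f1)
      }
      out <- bind_rows(score(warm, "warm"), score(cold, "cold"))
      out$ner_gain <- out$ner_macro_f1[1] - out$ner_macro_f1[2]
      out$re_gain <- out$re_macro_f1[1] - out$re_macro_f1[2]
      out
    }) |> bind_rows()
  })
  bind_rows(rows)
}
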