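make_small_setup <- function(n = 120, seed = 5) {
  corpus <- generate_corpus(synth_config(n_sentences = n), seed = seed)
  list(corpus = corpus, oracle = oracle_annotator(corpus))
}

test_that("initialization partitions the pool and fits backends on the seed set", {
  su <- make_small_setup()
  cfg <- al_config(n_init = 30, batch_size = 10, seed = 5)
  st <- initialize_state(su$corpus, su$oracle, cfg)
  expect_length(st$labeled_ids, 30)
  expect_length(st$unlabeled_ids, 90)
  expect_length(intersect(st$labeled_ids, st$unlabeled_ids), 0)
  expect_s3_class(st$tagger, "ref_tagger")
  expect_s3_class(st$relation_classifier, "ref_relation_classifier")
  expect_equal(st$iteration, 0L)
  # same seed, same seed set
  st2 <- initialize_state(su$corpus, oracle_annotator(su$corpus), cfg)
  expect_identical(sort(st$labeled_ids), sort(st2$labeled_ids))
  expect_error(
    initialize_state(su$corpus, su$oracle, al_config(n_init = 1000)),
    class = "alextract_param_error"
  )
})

test_that("proposed batches carry soft labels and respect the pool", {
  su <- make_small_setup()
  cfg <- al_config(n_init = 30, batch_size = 10, strategy = "strategic",
                   seed = 5)
  st <- initialize_state(su$corpus, su$oracle, cfg)
  batch <- propose_batch(st)
  expect_equal(nrow(batch), 10)
  expect_true(all(batch$sent_id %in% st$unlabeled_ids))
  expect_equal(attr(batch, "strategy"), "strategic")
  # soft tags align with the sentences' tokens
  i <- match(batch$sent_id[1], su$corpus$pool$sent_id)
  expect_length(batch$soft_tags[[1]],
                nrow(su$corpus$pool$tokens[[i]]))
  # a batch larger than the remaining pool returns the whole pool
  cfg_big <- al_config(n_init = 115, batch_size = 100, seed = 5)
  st_big <- initialize_state(su$corpus, su$oracle, cfg_big)
  expect_equal(nrow(propose_batch(st_big)), 5)
})

test_that("incorporating annotations moves ids, retrains, and logs history", {
  su <- make_small_setup()
  cfg <- al_config(n_init = 30, batch_size = 10, strategy = "random",
                   seed = 5)
  st <- initialize_state(su$corpus, su$oracle, cfg)
  batch <- propose_batch(st)
  corrected <- annotate_batch(batch, su$oracle)
  st2 <- incorporate_annotations(st, batch, corrected)
  expect_equal(length(st2$labeled_ids), 40)
  expect_equal(st2$iteration, 1L)
  expect_equal(nrow(st2$history), 1)
  expect_equal(st2$history$n_batch, 10)
  # history row is recomputable from the stored batch
  bpool <- st2$pool[match(batch$sent_id, st2$pool$sent_id), ]
  expect_equal(st2$history$avg_entities_per_sentence,
               mean(purrr::map_int(bpool$entities, nrow)))
  # pool conservation
  expect_equal(length(st2$labeled_ids) + length(st2$unlabeled_ids),
               nrow(su$corpus$pool))
  # annotating an unproposed sentence is an error
  rogue <- corrected
  rogue$sent_id[1] <- setdiff(st$unlabeled_ids, batch$sent_id)[1]
  expect_error(incorporate_annotations(st, batch, rogue),
               class = "alextract_param_error")
  # an empty corrected batch only advances the iteration counter
  empty <- corrected[0, ]
  st3 <- incorporate_annotations(st, batch[0, ], empty)
  expect_equal(st3$iteration, 1L)
  expect_equal(length(st3$labeled_ids), 30)
})

test_that("stopping honors threshold, exhaustion, and the iteration cap", {
  su <- make_small_setup()
  cfg <- al_config(n_init = 30, batch_size = 50, strategy = "random",
                   seed = 5, n_iterations = 2,
                   stop_metric = "ner_macro_f1", stop_threshold = 0.9,
                   test_pool = su$corpus$pool[1:20, ])
  st <- initialize_state(su$corpus, su$oracle, cfg)
  expect_false(should_stop(st))
  # threshold reached
  st$history <- tibble::tibble(iteration = 1L, ner_macro_f1 = 0.91)
  expect_true(should_stop(st))
  # unreachable threshold on a bounded metric does not stop
  st$history$ner_macro_f1 <- 0.5
  expect_false(should_stop(st, threshold = 1.1))
  # exhausted pool stops regardless of metric
  st$unlabeled_ids <- character()
  expect_true(should_stop(st, threshold = 1.1))
  # unknown metric errors
  st$unlabeled_ids <- "x"
  expect_error(should_stop(st, metric = "not_a_metric", threshold = 0.5),
               class = "alextract_param_error")
})

test_that("the full cycle runs to its budget with exact bookkeeping", {
  su <- make_small_setup(n = 80)
  cfg <- al_config(n_init = 20, batch_size = 10, strategy = "random",
                   seed = 9, n_iterations = 3,
                   test_pool = su$corpus$pool[1:20, ])
  st <- run_cycle(su$corpus, su$oracle, cfg)
  expect_equal(st$iteration, 3L)
  expect_equal(nrow(st$history), 3)
  expect_equal(length(st$labeled_ids), 20 + 30)
  # no sentence appears in two batches: labeled ids are unique
  expect_equal(anyDuplicated(st$labeled_ids), 0)
  expect_true(all(c("ner_macro_f1", "re_macro_f1", "soft_tag_accept")
                  %in% names(st$history)))
  expect_true(all(st$history$ner_macro_f1 >= 0 &
                    st$history$ner_macro_f1 <= 1))
  expect_s3_class(glance(st), "tbl_df")
  expect_equal(nrow(tidy(st)), 3)
})

test_that("a strategy schedule switches mid-run and is recorded", {
  su <- make_small_setup(n = 80)
  cfg <- al_config(n_init = 20, batch_size = 10,
                   strategy = strategy_schedule(switch_at = 2),
                   seed = 9, n_iterations = 2)
  st <- run_cycle(su$corpus, su$oracle, cfg)
  expect_equal(st$history$strategy, c("random", "strategic"))
  # vector schedules recycle their last entry
  cfg2 <- al_config(n_init = 20, batch_size = 10,
                    strategy = c("random", "strategic"),
                    seed = 9, n_iterations = 3)
  st2 <- run_cycle(su$corpus, su$oracle, cfg2)
  expect_equal(st2$history$strategy,
               c("random", "strategic", "strategic"))
})

test_that("a full run is bit-reproducible under fixed seeds", {
  su1 <- make_small_setup(n = 80, seed = 13)
  su2 <- make_small_setup(n = 80, seed = 13)
  cfg <- al_config(n_init = 20, batch_size = 10, strategy = "strategic",
                   seed = 21, n_iterations = 2,
                   test_pool = su1$corpus$pool[1:15, ])
  st1 <- run_cycle(su1$corpus, su1$oracle, cfg)
  cfg2 <- al_config(n_init = 20, batch_size = 10, strategy = "strategic",
                    seed = 21, n_iterations = 2,
                    test_pool = su2$corpus$pool[1:15, ])
  st2 <- run_cycle(su2$corpus, su2$oracle, cfg2)
  expect_identical(st1$history, st2$history)
  expect_identical(sort(st1$labeled_ids), sort(st2$labeled_ids))
})

test_that("soft-label acceptance is logged and grows as the tagger learns", {
  su <- make_small_setup(n = 100)
  cfg <- al_config(n_init = 40, batch_size = 15, strategy = "random",
                   seed = 3, n_iterations = 2)
  st <- run_cycle(su$corpus, su$oracle, cfg)
  expect_true(all(st$history$soft_tag_accept >= 0 &
                    st$history$soft_tag_accept <= 1))
  # the oracle logged per-sentence correction counts for every annotation
  lg <- su$oracle$log()
  expect_gte(nrow(lg), 40 + 30)
})

test_that("warm-started backends are accepted by the loop like cold ones", {
  su <- make_small_setup(n = 80)
  cfg <- al_config(n_init = 20, batch_size = 10, strategy = "random",
                   seed = 9, n_iterations = 2, warm_start = TRUE)
  st <- run_cycle(su$corpus, su$oracle, cfg)
  expect_equal(st$iteration, 2L)
  expect_s3_class(st$tagger, "ref_tagger")
})
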