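test_that("generated corpora are schema-valid and fully deterministic", {
  corpus <- generate_corpus(synth_config(n_sentences = 100), seed = 7)
  expect_equal(nrow(corpus$pool), 100)
  issues <- dplyr::bind_rows(lapply(corpus$documents, validate_annotations))
  expect_equal(nrow(issues), 0)
  # byte-identical regeneration under the same seed
  again <- generate_corpus(synth_config(n_sentences = 100), seed = 7)
  expect_identical(purrr::map_chr(corpus$documents, "text"),
                   purrr::map_chr(again$documents, "text"))
  expect_equal(corpus$pool$entities, again$pool$entities)
  # different seed, different corpus
  other <- generate_corpus(synth_config(n_sentences = 100), seed = 8)
  expect_false(identical(purrr::map_chr(corpus$documents, "text"),
                         purrr::map_chr(other$documents, "text")))
})

test_that("every entity class appears and minority classes skew to longer sentences", {
  corpus <- generate_corpus(synth_config(), seed = 3)
  d <- class_distribution(corpus$pool)
  expect_setequal(d$class[d$kind == "entity"],
                  default_schema()$entity_classes)
  mins <- synth_config()$minority_classes
  n_tokens <- purrr::map_int(corpus$pool$tokens, nrow)
  has_min <- purrr::map_lgl(corpus$pool$entities,
                            function(e) any(e$label %in% mins))
  expect_gt(mean(n_tokens[has_min]), mean(n_tokens[!has_min]))
  # minority share is a small fraction of all mentions
  share <- rare_class_share(d, mins)
  expect_gt(share, 0.03)
  expect_lt(share, 0.15)
})

test_that("sentences with rare terms carry higher pseudo-perplexity", {
  corpus <- generate_corpus(synth_config(n_sentences = 600), seed = 11)
  mlm <- fit_unigram_mlm(corpus$pool)
  tokens_by_sent <- purrr::map(corpus$pool$tokens, "surface")
  freq <- table(unlist(tokens_by_sent))
  qs <- stats::quantile(as.numeric(freq), c(0.1, 0.9))
  rare_terms <- names(freq)[as.numeric(freq) <= qs[1]]
  common_terms <- names(freq)[as.numeric(freq) >= qs[2]]
  scores <- score_pool(mlm, corpus$pool)
  has_rare <- purrr::map_lgl(tokens_by_sent,
                             function(t) any(t %in% rare_terms))
  all_common <- purrr::map_lgl(tokens_by_sent,
                               function(t) all(t %in% common_terms))
  expect_gt(mean(scores$ppl[has_rare]),
            mean(scores$ppl[all_common & !has_rare]))
})

test_that("generated relation samples obey the pair-count law by construction", {
  corpus <- small_corpus(50)
  s <- alextract:::pool_relation_samples(corpus$pool)
  k <- purrr::map_int(corpus$pool$entities, nrow)
  expect_equal(nrow(s), sum(choose(k, 2)))
  expect_true(all(s$label %in%
                    c(default_schema()$relation_classes, "no_relation")))
})

test_that("domain pairs share the configured fraction of vocabulary", {
  cfg <- synth_config(n_sentences = 60)
  full <- make_domain_pair(cfg, overlap = 1, seed = 2)
  expect_equal(full$shared_vocab_fraction, 1)
  none <- make_domain_pair(cfg, overlap = 0, seed = 2)
  expect_equal(none$shared_vocab_fraction, 0)
  va <- unlist(none$A$vocab$classes)
  vb <- unlist(none$B$vocab$classes)
  expect_length(intersect(va, vb), 0)
  mid <- make_domain_pair(cfg, overlap = 0.8, seed = 2)
  expect_gt(mid$shared_vocab_fraction, 0.7)
  expect_lt(mid$shared_vocab_fraction, 0.9)
  # both corpora remain schema-valid
  expect_equal(nrow(dplyr::bind_rows(
    lapply(mid$B$documents[1:3], validate_annotations))), 0)
})

test_that("the oracle annotator returns gold and counts corrections", {
  corpus <- small_corpus(20)
  oracle <- oracle_annotator(corpus)
  sid <- corpus$pool$sent_id[1]
  gold_iob <- spans_to_iob(corpus$pool$tokens[[1]],
                           corpus$pool$entities[[1]])
  # whatever the soft labels, gold comes back
  ann <- oracle$annotate(sid, soft_tags = rep("O", nrow(gold_iob)))
  expect_equal(ann$entities, corpus$pool$entities[[1]])
  expect_equal(ann$relations, corpus$pool$relations[[1]])
  # soft labels equal to gold: zero corrections
  oracle2 <- oracle_annotator(corpus)
  gold_samples <- generate_relation_samples(corpus$pool$entities[[1]],
                                            corpus$pool$relations[[1]],
                                            sent_id = sid)
  oracle2$annotate(sid, soft_tags = gold_iob$tag,
                   soft_relations = gold_samples)
  expect_equal(oracle2$log()$n_tag_corrections, 0)
  expect_equal(oracle2$log()$n_relation_corrections, 0)
  # corrupted soft labels: corrections equal the corruption count
  oracle3 <- oracle_annotator(corpus)
  corrupted <- gold_iob$tag
  flip <- seq_len(min(2, length(corrupted)))
  corrupted[flip] <- ifelse(corrupted[flip] == "O", "B-Dosing", "O")
  oracle3$annotate(sid, soft_tags = corrupted)
  expect_equal(oracle3$log()$n_tag_corrections, length(flip))
  # a sentence outside the pool is an error
  expect_error(oracle$annotate("nope"), class = "alextract_param_error")
})
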