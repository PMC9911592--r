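test_that("strict NER scoring counts exact span matches only", {
  gold <- tibble::tibble(
    sent_id = c("s1", "s1"), label = c("A", "B"),
    start = c(0L, 10L), end = c(5L, 15L)
  )
  # perfect prediction
  expect_equal(macro_f1_ner(gold, gold)$macro_f1, 1)
  # one class found, one missed: macro = (1 + 0) / 2
  pred <- gold[1, ]
  rep <- macro_f1_ner(gold, pred)
  expect_equal(rep$macro_f1, 0.5)
  expect_equal(dplyr::filter(tidy(rep), class == "A")$f1, 1)
  expect_equal(dplyr::filter(tidy(rep), class == "B")$f1, 0)
  # a shifted end offset is a miss under strict matching
  shifted <- dplyr::mutate(gold[1, ], end = end + 1L)
  rep2 <- macro_f1_ner(gold[1, ], shifted)
  expect_equal(rep2$macro_f1, 0)
})

test_that("token-level matching credits partial overlaps that strict matching rejects", {
  tokens <- dplyr::mutate(tokenize_text("ohne Hinweis auf Blutung"),
                          sent_id = "s1")
  gold <- tibble::tibble(sent_id = "s1", label = "Certainty_descriptor",
                         start = 0L, end = 12L)
  pred <- tibble::tibble(sent_id = "s1", label = "Certainty_descriptor",
                         start = 0L, end = 4L)  # first token only
  expect_equal(macro_f1_ner(gold, pred)$macro_f1, 0)
  tok_rep <- macro_f1_ner(gold, pred, matching = "token", tokens = tokens)
  expect_gt(tok_rep$macro_f1, 0)
  expect_lt(tok_rep$macro_f1, 1)
})

test_that("NER scorer agrees with an independent per-span counting oracle", {
  corpus <- small_corpus(40)
  pool <- corpus$pool
  gold <- alextract:::pool_entities(pool)[, c("sent_id", "label", "start",
                                              "end")]
  withr::with_seed(5, {
    for (rep in 1:20) {
      # corrupt a random subset: drop some spans, shift some starts
      pred <- gold[sample(nrow(gold), round(0.8 * nrow(gold))), ]
      shift <- sample(nrow(pred), round(0.2 * nrow(pred)))
      pred$start[shift] <- pred$start[shift] + 1L
      got <- macro_f1_ner(gold, pred)
      # oracle: brute-force per-class counting over string keys
      gkey <- paste(gold$sent_id, gold$start, gold$end, gold$label)
      pkey <- paste(pred$sent_id, pred$start, pred$end, pred$label)
      cls <- sort(union(gold$label, pred$label))
      f1s <- vapply(cls, function(cl) {
        g <- gkey[gold$label == cl]; p <- pkey[pred$label == cl]
        tp <- sum(p %in% g)
        prec <- if (length(p)) tp / length(p) else 0
        rec <- if (length(g)) tp / length(g) else 0
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      }, numeric(1))
      expect_equal(got$macro_f1, mean(f1s), tolerance = 1e-12)
    }
  })
})

test_that("macro-F1 is invariant under class relabeling", {
  gold <- tibble::tibble(sent_id = "s1", label = c("A", "B", "C"),
                         start = c(0L, 10L, 20L), end = c(5L, 15L, 25L))
  pred <- dplyr::mutate(gold, label = c("A", "C", "C"))
  perm <- c(A = "Z", B = "Y", C = "X")
  gold2 <- dplyr::mutate(gold, label = unname(perm[label]))
  pred2 <- dplyr::mutate(pred, label = unname(perm[label]))
  expect_equal(macro_f1_ner(gold, pred)$macro_f1,
               macro_f1_ner(gold2, pred2)$macro_f1)
})

test_that("eval reports carry their own recomputable counts", {
  gold <- tibble::tibble(sent_id = "s1", label = c("A", "A", "B"),
                         start = c(0L, 10L, 20L), end = c(5L, 15L, 25L))
  pred <- tibble::tibble(sent_id = "s1", label = c("A", "B", "B"),
                         start = c(0L, 10L, 20L), end = c(5L, 15L, 25L))
  rep <- macro_f1_ner(gold, pred)
  pc <- tidy(rep)
  prec <- ifelse(pc$tp + pc$fp > 0, pc$tp / (pc$tp + pc$fp), 0)
  recl <- ifelse(pc$tp + pc$fn > 0, pc$tp / (pc$tp + pc$fn), 0)
  f1 <- ifelse(prec + recl > 0, 2 * prec * recl / (prec + recl), 0)
  expect_equal(pc$precision, prec)
  expect_equal(pc$recall, recl)
  expect_equal(pc$f1, f1)
  expect_equal(rep$macro_f1, mean(f1))
  expect_equal(glance(rep)$macro_f1, rep$macro_f1)
})

test_that("RE scoring excludes no_relation by default and is order-symmetric", {
  ent <- fixture_entities(6)
  gold_rel <- tibble::tibble(
    label = c("Certainty", "Is_located", "Has_time_info", "Has_state"),
    arg1 = c("T5", "T4", "T6", "T1"), arg2 = c("T1", "T1", "T1", "T3")
  )
  gold <- generate_relation_samples(ent, gold_rel, sent_id = "s1")
  # perfect prediction on all 15 pairs
  expect_equal(macro_f1_re(gold, gold)$macro_f1, 1)
  # all positives predicted no_relation: per-positive-class F1 = 0
  none <- dplyr::mutate(gold, label = "no_relation")
  rep <- macro_f1_re(gold, none)
  expect_equal(rep$macro_f1, 0)
  expect_true(all(tidy(rep)$f1 == 0))
  # argument order does not matter
  sw <- gold
  sw$e1 <- gold$e2; sw$e2 <- gold$e1
  expect_equal(macro_f1_re(gold, sw)$macro_f1, 1)
  # with no_relation included the negative class joins the mean
  rep2 <- macro_f1_re(gold, gold, include_no_relation = TRUE)
  expect_equal(nrow(tidy(rep2)), nrow(tidy(macro_f1_re(gold, gold))) + 1)
  # a predicted pair outside the gold universe is an error
  alien <- dplyr::mutate(gold[1, ], e2 = "T99")
  expect_error(macro_f1_re(gold, alien), class = "alextract_param_error")
})

test_that("batch statistics summarize a sentence set and recompute from it", {
  corpus <- small_corpus(30)
  pool <- corpus$pool[1:10, ]
  mlm <- fit_unigram_mlm(corpus$pool)
  scores <- score_pool(mlm, pool)
  st <- batch_stats(pool, scores)
  expect_equal(st$n_sentences, 10)
  expect_equal(st$avg_entities_per_sentence,
               mean(purrr::map_int(pool$entities, nrow)))
  expect_equal(st$avg_sentence_length, mean(scores$length))
  expect_equal(st$avg_ppl, mean(scores$ppl))
  n_pos <- sum(purrr::map_int(pool$relations, nrow))
  expect_equal(st$n_rel_pos, n_pos)
  expect_equal(st$n_rel_neg,
               sum(choose(purrr::map_int(pool$entities, nrow), 2)) - n_pos)
  # a sentence without a score is an error
  expect_error(batch_stats(pool, scores[-1, ]),
               class = "alextract_param_error")
})

test_that("class distributions count every mention and normalize within kind", {
  corpus <- small_corpus(30)
  d <- class_distribution(corpus$pool)
  expect_equal(sum(d$n[d$kind == "entity"]),
               sum(purrr::map_int(corpus$pool$entities, nrow)))
  expect_equal(sum(d$n[d$kind == "relation"]),
               sum(purrr::map_int(corpus$pool$relations, nrow)))
  expect_equal(sum(d$share[d$kind == "entity"]), 1)
  # empty set: all-zero histogram
  empty <- class_distribution(corpus$pool[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(rare_class_share(empty, "Dosing"), 0)
})

test_that("Cohen's kappa matches hand-computed values", {
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "A", "B", "B")), 1)
  # p_o = 0.5, p_e = 0.5 -> kappa = 0
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  expect_equal(cohen_kappa(c("A", "A"), c("A", "A")), 1)
  # disjoint constant annotations: p_o = 0, p_e = 0 -> kappa = 0
  expect_equal(cohen_kappa(c("A", "A"), c("B", "B")), 0)
  expect_error(cohen_kappa(c("A", "B"), c("A", "B", "A")),
               class = "alextract_param_error")
})
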