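test_that("unigram masked LM matches the additive-smoothing formula", {
  m0 <- fit_unigram_mlm(c("a", "a", "b"), smoothing = 0)
  expect_equal(m0$conditional_prob("a"), 2 / 3)
  expect_equal(m0$conditional_prob("b"), 1 / 3)
  m1 <- fit_unigram_mlm(c("a", "a", "b"), smoothing = 1)
  expect_equal(m1$conditional_prob("a"), 3 / 5)  # (2+1)/(3+1*2)
  expect_equal(m1$conditional_prob("z"), 1 / 5)  # unseen: 1/(N+V)
  expect_error(fit_unigram_mlm(character(), smoothing = 0),
               class = "alextract_param_error")
})

test_that("unigram masked LM normalizes over vocabulary plus unseen mass", {
  m <- fit_unigram_mlm(c("a", "a", "b", "c"), smoothing = 1)
  vocab_mass <- m$conditional_prob("a") + m$conditional_prob("b") +
    m$conditional_prob("c")
  expect_equal(vocab_mass, (2 + 1 + 1 + 3) / (4 + 3), tolerance = 1e-12)
  # identical corpora give identical fingerprints; different ones differ
  expect_identical(m$fingerprint,
                   fit_unigram_mlm(c("a", "a", "b", "c"), 1)$fingerprint)
  expect_false(identical(m$fingerprint,
                         fit_unigram_mlm(c("a", "b"), 1)$fingerprint))
})

test_that("masking replaces ceiling(rate * n) positions and is seeded", {
  sents <- list(letters[1:20], "x")
  mk <- mask_tokens(sents, rate = 0.15, seed = 4)
  expect_length(mk$positions[[1]], 3)  # ceiling(0.15 * 20)
  expect_length(mk$positions[[2]], 1)  # ceiling on a 1-token sentence
  expect_equal(sum(mk$masked[[1]] == "[MASK]"), 3)
  expect_equal(mk$targets[[1]], letters[1:20][mk$positions[[1]]])
  mk2 <- mask_tokens(sents, rate = 0.15, seed = 4)
  expect_identical(mk$positions, mk2$positions)
  expect_error(mask_tokens(sents, rate = 1.5),
               class = "alextract_param_error")
})

test_that("the reference tagger memorizes a small fixture and falls back to O", {
  corpus <- small_corpus(25)
  pool <- corpus$pool[1:5, ]
  iob <- alextract:::pool_iob(pool)
  tagger <- fit_reference_tagger(iob, seed = 1)
  pred <- predict(tagger, iob[, c("sent_id", "surface")])
  expect_gte(mean(pred == iob$tag), 0.95)
  # unseen token under O-dominant training
  unseen <- tibble::tibble(sent_id = "sX", surface = "nieseltropf")
  expect_equal(predict(tagger, unseen), "O")
  expect_error(fit_reference_tagger(iob[0, ]),
               class = "alextract_param_error")
})

test_that("single-class training keeps predictions in that class's tag set plus O", {
  iob <- tibble::tibble(
    sent_id = rep("s1", 4),
    surface = c("Blutung", "ist", "akut", "hier"),
    tag = c("B-Medical_condition", "O", "O", "O")
  )
  tagger <- fit_reference_tagger(iob, seed = 1)
  pred <- predict(tagger, tibble::tibble(sent_id = "s2",
                                         surface = c("Blutung", "dort")))
  expect_true(all(pred %in% c("B-Medical_condition", "O")))
})

test_that("backends are deterministic and support warm starts", {
  corpus <- small_corpus(40)
  pool <- corpus$pool[1:20, ]
  iob <- alextract:::pool_iob(pool)
  t1 <- fit_reference_tagger(iob, seed = 1)
  t2 <- fit_reference_tagger(iob, seed = 1)
  probe <- alextract:::pool_tokens(corpus$pool[21:30, ])
  expect_identical(predict(t1, probe), predict(t2, probe))
  # warm start pools counts and is accepted wherever a cold fit is
  warm <- fit_reference_tagger(iob, seed = 1, init = t1)
  expect_s3_class(warm, "ref_tagger")
  expect_equal(sum(warm$priors$n), 2 * sum(t1$priors$n))
  expect_identical(predict(warm, probe), predict(t1, probe))
})

test_that("the relation classifier is symmetric in argument order", {
  corpus <- small_corpus(60)
  pool <- corpus$pool
  samples <- alextract:::pool_relation_samples(pool)
  tokens <- alextract:::pool_tokens(pool)
  clf <- fit_reference_relation_classifier(samples[1:200, ], tokens, seed = 1)
  probe <- samples[201:260, ]
  swapped <- probe
  swapped$e1 <- probe$e2; swapped$e2 <- probe$e1
  swapped$e1_label <- probe$e2_label; swapped$e2_label <- probe$e1_label
  swapped$e1_start <- probe$e2_start; swapped$e1_end <- probe$e2_end
  swapped$e2_start <- probe$e1_start; swapped$e2_end <- probe$e1_end
  expect_identical(predict(clf, probe, tokens),
                   predict(clf, swapped, tokens))
})

test_that("the relation classifier memorizes a small fixture and degenerates gracefully", {
  corpus <- small_corpus(60)
  samples <- alextract:::pool_relation_samples(corpus$pool)
  tokens <- alextract:::pool_tokens(corpus$pool)
  fix <- samples[1:20, ]
  clf <- fit_reference_relation_classifier(fix, tokens, seed = 1)
  expect_gte(mean(predict(clf, fix, tokens) == fix$label), 0.9)
  # training with only no_relation always predicts no_relation
  negs <- dplyr::filter(samples, label == "no_relation")[1:10, ]
  clf_neg <- fit_reference_relation_classifier(negs, tokens, seed = 1)
  expect_true(all(predict(clf_neg, samples[1:30, ], tokens) == "no_relation"))
  expect_error(fit_reference_relation_classifier(samples[0, ], tokens),
               class = "alextract_param_error")
})
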