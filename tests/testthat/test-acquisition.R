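test_that("pseudo-perplexity has its closed-form values", {
  # perfect prediction scores exactly 1
  expect_equal(pseudo_perplexity(constant_mlm(1), c("a", "b", "c")), 1)
  # unigram p(a)=0.8, p(b)=0.2: PPL = (0.8*0.2)^(-1/2) = 2.5
  m <- fit_unigram_mlm(c(rep("a", 8), rep("b", 2)), smoothing = 0)
  expect_equal(pseudo_perplexity(m, c("a", "b")), (0.8 * 0.2)^(-1 / 2))
  expect_equal(pseudo_perplexity(m, c("a", "b")), 2.5)
  # constant-probability model: PPL = 1/p independent of n
  for (n in c(1, 3, 10)) {
    expect_equal(pseudo_perplexity(constant_mlm(0.25), rep("x", n)), 4)
  }
})

test_that("pseudo-perplexity matches an independent mask-and-score oracle", {
  vocab <- letters[1:10]
  withr::with_seed(11, {
    corpus <- sample(vocab, 400, replace = TRUE,
                     prob = 1 / seq_len(10)^1.3)
    mlm <- fit_unigram_mlm(corpus, smoothing = 1)
    for (rep in 1:50) {
      toks <- sample(vocab, sample(1:12, 1), replace = TRUE)
      expect_equal(pseudo_perplexity(mlm, toks), ppl_oracle(mlm, toks),
                   tolerance = 1e-9)
    }
  })
})

test_that("pseudo-perplexity is order-invariant for a context-free model and errors on empty input", {
  m <- fit_unigram_mlm(c("a", "a", "b", "c"), smoothing = 1)
  toks <- c("a", "b", "c", "a")
  expect_equal(pseudo_perplexity(m, toks),
               pseudo_perplexity(m, rev(toks)))
  expect_error(pseudo_perplexity(m, character()),
               class = "alextract_param_error")
})

test_that("rare-term sentences score higher than common-term sentences", {
  # frequency contrast: a corpus where one condition term dominates
  corpus <- c(rep("Blutung", 50), rep("keine", 40), "Mikrophtalmie",
              rep("rezente", 20))
  mlm <- fit_unigram_mlm(corpus, smoothing = 1)
  common <- pseudo_perplexity(mlm, c("keine", "rezente", "Blutung"))
  rare <- pseudo_perplexity(mlm, c("Mikrophtalmie", "rezente", "Blutung"))
  expect_gt(rare, common)
})

test_that("score_pool preserves order, caches, and attaches sentence ids", {
  sents <- list(s1 = c("a", "b"), s2 = c("a"), s3 = c("b", "b", "b"))
  m <- fit_unigram_mlm(c("a", "a", "b"), smoothing = 1)
  sc <- score_pool(m, sents)
  expect_equal(sc$sent_id, c("s1", "s2", "s3"))
  expect_equal(sc$length, c(2L, 1L, 3L))
  sc2 <- score_pool(m, sents)  # cache hit
  expect_identical(sc, sc2)
})

test_that("percentile band selection follows the rank rule", {
  expect_equal(percentile_band(1:20, c(0.75, 0.90)), c(16L, 17L, 18L))
  expect_equal(percentile_band(1:7, c(0, 1)), 1:7)
  # N = 1: rank/N = 1 > 0.90, so the band is empty
  expect_length(percentile_band(5, c(0.75, 0.90)), 0)
  # ties keep stable input order
  expect_equal(percentile_band(c(1, 1, 1, 1), c(0.5, 1)), 3:4)
  expect_error(percentile_band(numeric(), c(0.75, 0.9)),
               class = "alextract_param_error")
  expect_error(percentile_band(1:5, c(0.9, 0.5)),
               class = "alextract_param_error")
})

test_that("percentile band is monotone in its bounds", {
  withr::with_seed(3, values <- stats::runif(200))
  base <- percentile_band(values, c(0.6, 0.8))
  expect_true(all(base %in% percentile_band(values, c(0.6, 0.9))))
  expect_true(all(percentile_band(values, c(0.7, 0.8)) %in% base))
})

test_that("strategic sampling draws from the band intersection with a fallback ladder", {
  scores <- tibble::tibble(
    sent_id = paste0("s", 1:10),
    ppl = c(1, 2, 9, 4, 8.5, 6, 8, 3, 5, 7),
    length = c(1, 2, 3, 4, 9, 6, 8, 5, 8.5, 7)
  )
  # ppl band (0.6, 0.9]: ranks 7..9 -> values 7, 8, 8.5 -> s10, s7, s5
  # length band: s10, s7, s9
  sel2 <- strategic_sample(scores, band = c(0.6, 0.9), batch_size = 2,
                           seed = 1)
  expect_setequal(sel2, c("s7", "s10"))
  expect_equal(attr(sel2, "fallback"), "intersection")
  sel3 <- strategic_sample(scores, band = c(0.6, 0.9), batch_size = 3,
                           seed = 1)
  expect_true(all(c("s7", "s10") %in% sel3))
  expect_true(setdiff(sel3, c("s7", "s10")) %in% c("s5", "s9"))
  expect_equal(attr(sel3, "fallback"), "union")
  # full-pool fallback and the trivial full-band draw
  sel_all <- strategic_sample(scores, band = c(0.001, 1), batch_size = 10,
                              seed = 1)
  expect_setequal(sel_all, scores$sent_id)
})

test_that("strategic sampling is deterministic, duplicate-free, within the pool", {
  corpus <- small_corpus(120)
  mlm <- fit_unigram_mlm(corpus$pool)
  scores <- score_pool(mlm, corpus$pool)
  a <- strategic_sample(scores, batch_size = 20, seed = 9)
  b <- strategic_sample(scores, batch_size = 20, seed = 9)
  expect_identical(as.character(a), as.character(b))
  expect_equal(anyDuplicated(a), 0)
  expect_true(all(a %in% scores$sent_id))
})

test_that("random sampling is uniform, seeded, and bounded by the pool", {
  pool <- paste0("s", 1:10)
  expect_setequal(random_sample(pool, 10, seed = 2), pool)
  expect_identical(random_sample(pool, 3, seed = 5),
                   random_sample(pool, 3, seed = 5))
  expect_error(random_sample(pool, 11, seed = 1),
               class = "alextract_param_error")
  # frequency check against the binomial: 10,000 seeded singleton draws
  small <- paste0("s", 1:4)
  draws <- vapply(1:10000, function(i) random_sample(small, 1, seed = i),
                  character(1))
  counts <- table(factor(draws, levels = small))
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
})
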