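# shared fixtures, all built in code

# the hand-annotated negation sentence used across parser tests
fixture_standoff <- function() {
  list(
    txt = "Keine rezente Blutung",
    ann = paste(
      "T1\tCertainty_descriptor 0 5\tKeine",
      "T2\tTime_information 6 13\trezente",
      "T3\tMedical_condition 14 21\tBlutung",
      sep = "\n"
    )
  )
}

# a sentence with k single-token entities at regular offsets
fixture_entities <- function(k, labels = NULL) {
  labels <- labels %||% rep(c("Medical_condition", "Anatomical_entity",
                              "Imaging_observation", "Location_descriptor",
                              "Certainty_descriptor", "Time_information"),
                            length.out = k)
  tibble::tibble(
    id = paste0("T", seq_len(k)),
    label = labels,
    start = as.integer((seq_len(k) - 1) * 10),
    end = as.integer((seq_len(k) - 1) * 10 + 5)
  )
}

# masked LM assigning a constant probability to every token
constant_mlm <- function(p) {
  masked_lm(function(token, left, right) p, fingerprint = paste0("const", p))
}

# independent brute-force pseudo-perplexity oracle: literal sum of logs,
# one explicit mask-and-score step per position
ppl_oracle <- function(mlm, tokens, eps = 1e-12) {
  n <- length(tokens)
  total <- 0
  for (i in seq_len(n)) {
    left <- if (i > 1) tokens[1:(i - 1)] else character()
    right <- if (i < n) tokens[(i + 1):n] else character()
    p <- mlm$conditional_prob(tokens[i], left, right)
    total <- total + log(max(p, eps))
  }
  exp(-total / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_corpus <- function(n = 150, seed = 42) {
  generate_corpus(synth_config(n_sentences = n), seed = seed)
}
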