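#' Configuration for the synthetic pseudo-clinical corpus generator
#'
#' The generator emulates the statistical structure an intrinsic
#' acquisition strategy exploits in real report corpora, without any real
#' clinical text: Zipf-distributed vocabulary per entity class (so rare
#' terms exist and surprise a language model), a template inventory whose
#' longer templates carry more entities, minority entity classes and the
#' rare dosing relation concentrated in those longer templates, and
#' schema-legal relations throughout. Texts are German-like filler and term
#' tokens assembled from syllables; no natural language is generated.
#'
#' @param n_sentences Number of sentences (default 2000).
#' @param sentences_per_doc Sentences per generated document (default 5).
#' @param zipf_exponent Zipf exponent for vocabulary draws (default 1.2).
#' @param filler_vocab_size Size of the non-entity filler vocabulary.
#' @param class_vocab_size Terms per majority entity class.
#' @param minority_vocab_size Terms per minority entity class.
#' @param minority_classes Entity classes designated minority; they appear
#'   only in the longer templates (explicit length affinity, so enrichment
#'   diagnostics have a controllable ground truth).
#' @param length_mix Named weights for the short/medium/long template
#'   groups; must sum to 1.
#' @param relation_density Probability that a template's relation is
#'   annotated in an instantiated sentence.
#' @param two_token_share Fraction of entity terms built from two words.
#' @param seed Default seed used by [generate_corpus()] when none is given.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 2000,
                         sentences_per_doc = 5,
                         zipf_exponent = 1.2,
                         filler_vocab_size = 350,
                         class_vocab_size = 40,
                         minority_vocab_size = 25,
                         minority_classes = c("Procedure", "Medical_device",
                                              "Non_anatomical_substance",
                                              "Dosing", "Score_Grade_Type"),
                         length_mix = c(short = 0.55, medium = 0.30,
                                        long = 0.15),
                         relation_density = 0.9,
                         two_token_share = 0.3,
                         seed = 1L) {
  stopifnot(n_sentences >= 1, zipf_exponent > 0,
            abs(sum(length_mix) - 1) < 1e-8,
            relation_density >= 0, relation_density <= 1)
  structure(
    list(n_sentences = as.integer(n_sentences),
         sentences_per_doc = as.integer(sentences_per_doc),
         zipf_exponent = zipf_exponent,
         filler_vocab_size = as.integer(filler_vocab_size),
         class_vocab_size = as.integer(class_vocab_size),
         minority_vocab_size = as.integer(minority_vocab_size),
         minority_classes = minority_classes,
         length_mix = length_mix,
         relation_density = relation_density,
         two_token_share = two_token_share,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# --- template inventory -----------------------------------------------------
# Slots: "F" = filler token, otherwise an entity-class slot. Relations
# reference slot indices and use only schema-legal class pairs. Six relation
# classes are active; Has_dosing appears only in a long template, making it
# a rare relation concentrated in long sentences.
synth_templates <- function() {
  tpl <- function(name, group, slots, rel = NULL) {
    list(name = name, group = group, slots = slots,
         relations = rel %||% tibble(label = character(), i = integer(),
                                     j = integer()))
  }
  rels <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(label = m[, 1], i = as.integer(m[, 2]), j = as.integer(m[, 3]))
  }
  list(
    tpl("s1", "short", c("Certainty_descriptor", "Time_information",
                         "Medical_condition"),
        rels("Certainty", 1, 3, "Has_time_info", 2, 3)),
    tpl("s2", "short", c("F", "Anatomical_entity", "F", "State_of_health")),
    tpl("s3", "short", c("Certainty_descriptor", "Imaging_observation", "F",
                         "F", "Anatomical_entity"),
        rels("Certainty", 1, 2, "Is_located", 5, 2)),
    tpl("s4", "short", c("Radlex_descriptor", "Medical_condition",
                         "Location_descriptor"),
        rels("Is_located", 3, 2)),
    tpl("s5", "short", c("F", "F", "Medical_condition", "F",
                         "Anatomical_entity", "F"),
        rels("Is_located", 5, 3)),
    tpl("s6", "short", c("State_of_health", "F", "Property", "F",
                         "Anatomical_entity")),
    tpl("s7", "short", c("Certainty_descriptor", "Medical_condition"),
        rels("Certainty", 1, 2)),
    tpl("s8", "short", c("Imaging_observation", "F", "Location_descriptor",
                         "F"),
        rels("Is_located", 3, 1)),
    tpl("s9", "short", c("F", "Time_information", "F", "Medical_condition",
                         "F"),
        rels("Has_time_info", 2, 4)),
    tpl("s10", "short", c("Anatomical_entity", "F", "State_of_health")),
    tpl("m1", "medium", c("Diaglab_procedure", "F", "Anatomical_entity", "F",
                          "F", "Imaging_observation", "F",
                          "Location_descriptor", "F", "F"),
        rels("Is_located", 8, 6, "Has_state", 3, 6)),
    tpl("m2", "medium", c("Certainty_descriptor", "Imaging_observation", "F",
                          "Anatomical_entity", "F", "F", "Time_information",
                          "F", "Medical_condition", "F", "F"),
        rels("Certainty", 1, 2, "Has_time_info", 7, 9, "Is_located", 4, 2)),
    tpl("m3", "medium", c("Quality_descriptor", "F", "F",
                          "Diaglab_procedure", "F", "Anatomical_entity", "F",
                          "F", "Radlex_descriptor", "Imaging_observation",
                          "F"),
        rels("Has_state", 6, 10)),
    tpl("m4", "medium", c("Prior_investigation", "F", "F",
                          "Imaging_observation", "F", "F", "Dynamism", "F",
                          "Medical_condition", "F", "F", "Measurement"),
        rels("Has_measure", 12, 9)),
    tpl("m5", "medium", c("Follow_Up", "F", "F", "Medical_condition", "F",
                          "Location_descriptor", "F", "F",
                          "Time_information", "F"),
        rels("Is_located", 6, 4, "Has_time_info", 9, 4)),
    tpl("m6", "medium", c("F", "Medical_condition", "F",
                          "Non_anatomical_substance", "F", "Dosing", "F",
                          "Imaging_observation", "F", "Certainty_descriptor",
                          "F", "F", "F"),
        rels("Has_dosing", 6, 4, "Certainty", 10, 8)),
    tpl("m7", "medium", c("Score_Grade_Type", "F", "F", "Medical_condition",
                          "F", "F", "Anatomical_entity", "F",
                          "Radlex_descriptor", "F", "Imaging_observation",
                          "F", "F"),
        rels("Is_located", 7, 11)),
    tpl("l1", "long", c("Certainty_descriptor", "F", "Imaging_observation",
                        "F", "Location_descriptor", "F", "Anatomical_entity",
                        "F", "F", "Medical_condition", "F", "F",
                        "Time_information", "F", "F", "Dynamism", "F",
                        "Measurement", "F"),
        rels("Certainty", 1, 3, "Is_located", 5, 10, "Has_time_info", 13, 10,
             "Has_measure", 18, 10)),
    tpl("l2", "long", c("Procedure", "F", "F", "Medical_condition", "F", "F",
                        "Anatomical_entity", "F", "Medical_device", "F",
                        "Location_descriptor", "F", "Imaging_observation",
                        "F", "State_of_health"),
        rels("Is_located", 11, 13, "Has_state", 7, 13)),
    tpl("l3", "long", c("Non_anatomical_substance", "F", "Dosing", "F", "F",
                        "Diaglab_procedure", "F", "Anatomical_entity", "F",
                        "Imaging_observation", "F", "Certainty_descriptor",
                        "F", "F", "Medical_condition", "F",
                        "Time_information"),
        rels("Has_dosing", 3, 1, "Certainty", 12, 15,
             "Has_time_info", 17, 15)),
    tpl("l4", "long", c("State_of_health", "F", "Measurement", "F", "F",
                        "Medical_condition", "F", "F", "Location_descriptor",
                        "F", "Anatomical_entity", "F", "F",
                        "Imaging_observation", "F", "Dynamism", "F",
                        "Radlex_descriptor"),
        rels("Has_measure", 3, 6, "Is_located", 9, 6, "Has_state", 11, 14)),
    tpl("l5", "long", c("F", "Certainty_descriptor", "F",
                        "Imaging_observation", "F", "F", "Anatomical_entity",
                        "F", "F", "Medical_condition", "F", "F",
                        "Location_descriptor", "F", "F", "Time_information",
                        "F", "F", "Measurement", "F", "F", "Dynamism", "F",
                        "Radlex_descriptor"),
        rels("Certainty", 2, 4, "Is_located", 13, 10, "Has_time_info", 16, 10,
             "Has_measure", 19, 10))
  )
}

# pseudo-German word factory: syllable assembly, deterministic under the
# ambient RNG state, globally unique within one call
make_words <- function(n, capitalize = FALSE) {
  onset <- c("b", "bl", "br", "d", "dr", "f", "fl", "fr", "g", "gl", "gr",
             "h", "k", "kl", "kr", "l", "m", "n", "p", "pf", "pl", "r",
             "s", "sch", "schl", "schr", "sp", "st", "str", "t", "tr",
             "v", "w", "z", "zw")
  nucleus <- c("a", "e", "i", "o", "u", "au", "ei", "eu", "ie", "oe", "ue", "ae")
  coda <- c("", "b", "ch", "ck", "d", "f", "g", "hl", "hr", "l", "ld", "lk",
            "ln", "lt", "m", "n", "nd", "ng", "nk", "nt", "r", "rd", "rm",
            "rn", "rt", "s", "st", "t", "tz", "x")
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    nsyl <- sample(2:3, k, replace = TRUE)
    words <- vapply(nsyl, function(s) {
      paste0(vapply(seq_len(s), function(i) {
        paste0(sample(onset, 1), sample(nucleus, 1), sample(coda, 1))
      }, character(1)), collapse = "")
    }, character(1))
    out <- unique(c(out, words))
  }
  out <- out[seq_len(n)]
  if (capitalize) {
    out <- paste0(toupper(substr(out, 1, 1)), substring(out, 2))
  }
  out
}

# build per-class term vocabularies and the filler vocabulary
build_vocab <- function(config, schema) {
  cls <- schema$entity_classes
  sizes <- ifelse(cls %in% config$minority_classes,
                  config$minority_vocab_size, config$class_vocab_size)
  words <- make_words(sum(sizes), capitalize = TRUE)
  fillers <- make_words(config$filler_vocab_size, capitalize = FALSE)
  splits <- split(words, rep(seq_along(cls), sizes))
  class_terms <- map(splits, function(w) {
    two <- stats::runif(length(w)) < config$two_token_share
    ifelse(two, paste(w, sample(w, length(w), replace = TRUE)), w)
  })
  list(classes = setNames(class_terms, cls), fillers = fillers)
}

zipf_draw <- function(n, v, exponent) {
  p <- 1 / seq_len(v)^exponent
  sample.int(v, n, replace = TRUE, prob = p)
}

# instantiate one template: tokens plus entity/relation annotations in
# token coordinates
instantiate_template <- function(tpl, vocab, config) {
  slots <- tpl$slots
  tokens <- vector("list", length(slots) + 1L)
  ent_label <- character(); ent_from <- integer(); ent_to <- integer()
  slot_entity <- integer(length(slots))  # slot index -> entity number
  pos <- 0L
  for (si in seq_along(slots)) {
    s <- slots[si]
    if (s == "F") {
      idx <- zipf_draw(1, length(vocab$fillers), config$zipf_exponent)
      tokens[[si]] <- vocab$fillers[idx]
      pos <- pos + 1L
    } else {
      terms <- vocab$classes[[s]]
      idx <- zipf_draw(1, length(terms), config$zipf_exponent)
      term_tokens <- strsplit(terms[idx], " ", fixed = TRUE)[[1]]
      ent_label[length(ent_label) + 1] <- s
      ent_from[length(ent_from) + 1] <- pos + 1L
      ent_to[length(ent_to) + 1] <- pos + length(term_tokens)
      slot_entity[si] <- length(ent_label)
      tokens[[si]] <- term_tokens
      pos <- pos + length(term_tokens)
    }
  }
  tokens[[length(slots) + 1L]] <- "."
  rel <- tpl$relations
  if (nrow(rel)) {
    keep <- stats::runif(nrow(rel)) < config$relation_density
    rel <- rel[keep, ]
  }
  list(
    tokens = unlist(tokens, use.names = FALSE),
    entities = tibble::new_tibble(
      list(label = ent_label, tok_from = ent_from, tok_to = ent_to),
      nrow = length(ent_label)),
    relations = tibble::new_tibble(
      list(label = rel$label, e_i = slot_entity[rel$i],
           e_j = slot_entity[rel$j]),
      nrow = nrow(rel))
  )
}

#' Generate a synthetic annotated corpus
#'
#' Fully deterministic under the seed. Every generated document passes
#' [validate_annotations()] with zero issues and round-trips through brat
#' standoff write/read.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to the config's seed.
#' @param templates Template inventory (advanced use; defaults to the
#'   built-in inventory).
#' @param vocab Pre-built vocabulary (advanced use, e.g. domain pairs).
#' @param doc_prefix Prefix for document ids.
#' @return A `synth_corpus`: list with `documents` (list of
#'   `ie_document`), `pool` (sentence-pool tibble, see
#'   [as_sentence_pool()]), `schema`, `config`, `vocab` and `templates`.
#' @export
generate_corpus <- function(config = synth_config(), seed = config$seed,
                            templates = synth_templates(), vocab = NULL,
                            doc_prefix = "synth") {
  schema <- default_schema()
  bad <- setdiff(unlist(map(templates, function(t) setdiff(t$slots, "F"))),
                 schema$entity_classes)
  if (length(bad)) {
    abort(sprintf("template references unknown entity class: %s",
                  paste(bad, collapse = ", ")),
          class = "alextract_config_error")
  }
  groups <- map_chr(templates, "group")
  w <- unname(config$length_mix[groups] / table(groups)[groups])

  withr::with_seed(seed, {
    if (is.null(vocab)) {
      vocab <- build_vocab(config, schema)
    }
    tpl_idx <- sample.int(length(templates), config$n_sentences,
                          replace = TRUE, prob = w)
    sents <- map(tpl_idx, function(i) {
      instantiate_template(templates[[i]], vocab, config)
    })
  })

  n_docs <- ceiling(config$n_sentences / config$sentences_per_doc)
  doc_of <- rep(seq_len(n_docs), each = config$sentences_per_doc,
                length.out = config$n_sentences)
  docs <- map(seq_len(n_docs), function(d) {
    ss <- sents[doc_of == d]
    offset <- 0L
    ent_all <- list(); rel_all <- list(); texts <- character(0)
    ent_counter <- 0L
    for (s in ss) {
      tok <- s$tokens
      starts <- offset + c(0L, cumsum(nchar(tok) + 1L))[seq_along(tok)]
      ends <- starts + nchar(tok)
      text <- paste(tok, collapse = " ")
      ids <- paste0("T", ent_counter + seq_len(nrow(s$entities)))
      if (nrow(s$entities)) {
        ent_all[[length(ent_all) + 1]] <- tibble::new_tibble(list(
          id = ids,
          label = s$entities$label,
          start = starts[s$entities$tok_from],
          end = ends[s$entities$tok_to]
        ), nrow = length(ids))
      }
      if (nrow(s$relations)) {
        rel_all[[length(rel_all) + 1]] <- tibble::new_tibble(list(
          label = s$relations$label,
          arg1 = ids[s$relations$e_i],
          arg2 = ids[s$relations$e_j]
        ), nrow = nrow(s$relations))
      }
      ent_counter <- ent_counter + nrow(s$entities)
      texts <- c(texts, text)
      offset <- offset + nchar(text) + 1L  # newline joint
    }
    ie_document(
      doc_id = sprintf("%s_%04d", doc_prefix, d),
      text = paste(texts, collapse = "\n"),
      entities = if (length(ent_all)) bind_rows(ent_all) else empty_entities(),
      relations = if (length(rel_all)) bind_rows(rel_all) else
        empty_relations(),
      schema = schema
    )
  })
  structure(
    list(documents = docs, pool = as_sentence_pool(docs), schema = schema,
         config = config, vocab = vocab, templates = templates),
    class = "synth_corpus"
  )
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus>\n")
  cat("  documents:", length(x$documents), "\n")
  cat("  sentences:", nrow(x$pool), "\n")
  cat("  entities: ", sum(map_int(x$pool$entities, nrow)), "\n")
  cat("  relations:", sum(map_int(x$pool$relations, nrow)), "\n")
  invisible(x)
}

#' Generate a pair of synthetic corpora with controlled overlap
#'
#' Emulates two clinical reporting domains whose content overlaps to a
#' configurable degree: `overlap` is the fraction of vocabulary (term and
#' filler entries, matched by frequency rank so the shared part carries the
#' same Zipf mass in both domains) and of templates shared between domain A
#' and domain B. Non-shared templates are restyled for B by shuffling their
#' filler slots. High overlap mimics two modalities read by the same
#' department; low overlap mimics a change of modality and anatomy.
#'
#' @param base A [synth_config()] used for both domains.
#' @param overlap Shared fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return A list with corpora `A` and `B` and the realized
#'   `shared_vocab_fraction`.
#' @export
make_domain_pair <- function(base = synth_config(), overlap = 0.8,
                             seed = base$seed) {
  stopifnot(overlap >= 0, overlap <= 1)
  schema <- default_schema()
  seed_a <- seed
  seed_b <- seed + 10000L
  vocab_a <- withr::with_seed(seed_a, build_vocab(base, schema))
  vocab_b <- withr::with_seed(seed_b, {
    fresh <- build_vocab(base, schema)
    share_ranks <- function(a, b) {
      v <- length(a)
      k <- round(overlap * v)
      shared <- if (k > 0) sort(sample.int(v, k)) else integer()
      b[shared] <- a[shared]
      b
    }
    list(
      classes = setNames(map2(vocab_a$classes, fresh$classes, share_ranks),
                         names(vocab_a$classes)),
      fillers = share_ranks(vocab_a$fillers, fresh$fillers)
    )
  })
  templates_a <- synth_templates()
  templates_b <- withr::with_seed(seed_b + 1L, {
    map(templates_a, function(tpl) {
      if (stats::runif(1) < overlap) {
        return(tpl)
      }
      fill <- which(tpl$slots == "F")
      if (length(fill) > 1) {
        # restyle: move one filler elsewhere in the slot order
        from <- sample(fill, 1)
        slots <- append(tpl$slots[-from], "F",
                        after = sample(length(tpl$slots) - 1L, 1))
        # recompute relation slot indices against the new layout
        ent_pos_old <- which(tpl$slots != "F")
        ent_pos_new <- which(slots != "F")
        remap <- setNames(ent_pos_new, ent_pos_old)
        tpl$relations$i <- unname(remap[as.character(tpl$relations$i)])
        tpl$relations$j <- unname(remap[as.character(tpl$relations$j)])
        tpl$slots <- slots
      }
      tpl
    })
  })
  shared_frac <- mean(unlist(map2(c(vocab_a$classes, list(vocab_a$fillers)),
                                  c(vocab_b$classes, list(vocab_b$fillers)),
                                  function(a, b) mean(a == b))))
  list(
    A = generate_corpus(base, seed = seed_a, templates = templates_a,
                        vocab = vocab_a, doc_prefix = "domA"),
    B = generate_corpus(base, seed = seed_b + 2L, templates = templates_b,
                        vocab = vocab_b, doc_prefix = "domB"),
    shared_vocab_fraction = shared_frac
  )
}

#' An oracle annotator over a gold-annotated pool
#'
#' Simulates the human annotation/review phase: whatever soft labels are
#' proposed, the oracle returns the gold annotations for the sentence, and
#' records how many proposed tags and relation labels it had to correct —
#' the observable measure of how much pre-annotation saves.
#'
#' @param pool A gold sentence pool (tibble from [as_sentence_pool()]) or a
#'   `synth_corpus`.
#' @return An object of class `oracle_annotator`: list with `annotate(
#'   sent_id, soft_tags, soft_relations)` returning
#'   `list(entities, relations)` and `log()` returning the correction
#'   record.
#' @export
oracle_annotator <- function(pool) {
  if (inherits(pool, "synth_corpus")) {
    pool <- pool$pool
  }
  gold <- pool
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  annotate <- function(sent_id, soft_tags = NULL, soft_relations = NULL) {
    i <- match(sent_id, gold$sent_id)
    if (is.na(i)) {
      abort(sprintf("sentence '%s' is outside the gold pool", sent_id),
            class = "alextract_param_error")
    }
    gold_iob <- spans_to_iob(gold$tokens[[i]], gold$entities[[i]])
    n_tag_corr <- if (is.null(soft_tags)) length(gold_iob$tag) else
      sum(soft_tags != gold_iob$tag)
    gold_samples <- generate_relation_samples(
      gold$entities[[i]], gold$relations[[i]], sent_id = sent_id)
    # soft relations are matched to gold pairs by span offsets (model
    # pre-annotations carry no gold entity ids); an unproposed gold pair
    # counts as a correction when its gold label is a real relation
    n_rel_corr <- if (is.null(soft_relations) || !nrow(gold_samples)) {
      nrow(filter(gold_samples, .data$label != "no_relation"))
    } else {
      key <- function(d) paste(d$e1_start, d$e1_end, d$e2_start, d$e2_end)
      m <- match(key(gold_samples), key(soft_relations))
      sum(gold_samples$label !=
            ifelse(is.na(m), "no_relation", soft_relations$label[m]))
    }
    log_env$rows[[length(log_env$rows) + 1]] <- tibble(
      sent_id = sent_id,
      n_tags = length(gold_iob$tag),
      n_tag_corrections = n_tag_corr,
      n_pairs = nrow(gold_samples),
      n_relation_corrections = n_rel_corr
    )
    list(entities = gold$entities[[i]], relations = gold$relations[[i]])
  }
  structure(
    list(
      annotate = annotate,
      log = function() bind_rows(log_env$rows)
    ),
    class = "oracle_annotator"
  )
}
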