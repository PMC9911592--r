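empty_relation_samples <- tibble::new_tibble(list(
  sent_id = character(), e1 = character(), e2 = character(),
  e1_label = character(), e2_label = character(),
  e1_start = integer(), e1_end = integer(),
  e2_start = integer(), e2_end = integer(),
  label = character(), split = character(), copy = integer()
), nrow = 0L)

#' Generate within-sentence relation samples for one sentence
#'
#' Every unordered pair of distinct entities in a sentence with `k` entities
#' yields exactly one candidate sample, `choose(k, 2)` in total. Pairs
#' carrying an annotated relation keep its label; all remaining pairs are
#' automatically labeled `no_relation`. Pairs are canonical: `e1` precedes
#' `e2` in (start, end) offset order, and relation direction is never
#' meaningful.
#'
#' Rule handling (`enforce_rules`): under `"relabel"` (default), candidate
#' pairs that no schema rule allows are retained and labeled `no_relation`
#' unless annotated — the pair count stays exactly `choose(k, 2)`. Under
#' `"strict"`, unannotated pairs allowed by no rule are dropped from the
#' candidate set (annotated pairs are always kept so that gold is never
#' silently discarded).
#'
#' @param entities Tibble of the sentence's entities (`id`, `label`, `start`,
#'   `end`).
#' @param gold_relations Tibble of annotated relations (`label`, `arg1`,
#'   `arg2`) among those entities. A relation whose argument is not among
#'   `entities` is an error.
#' @param schema An `ie_schema`; used only when `enforce_rules = "strict"`.
#' @param enforce_rules `"relabel"` or `"strict"`.
#' @param sent_id Sentence id attached to the samples.
#' @param split `"train"` or `"test"` marker.
#' @return A tibble with columns `sent_id`, `e1`, `e2`, `e1_label`,
#'   `e2_label`, `e1_start`, `e1_end`, `e2_start`, `e2_end`, `label`,
#'   `split`, `copy` (copy index, 0 before oversampling).
#' @examples
#' ent <- tibble::tibble(
#'   id = paste0("T", 1:4),
#'   label = c("Certainty_descriptor", "Imaging_observation",
#'             "Anatomical_entity", "Medical_condition"),
#'   start = c(0L, 10L, 20L, 30L), end = c(5L, 15L, 25L, 35L)
#' )
#' nrow(generate_relation_samples(ent, sent_id = "s1"))  # choose(4, 2) = 6
#' @export
generate_relation_samples <- function(entities,
                                      gold_relations = empty_relations(),
                                      schema = default_schema(),
                                      enforce_rules = c("relabel", "strict"),
                                      sent_id = "s1",
                                      split = "train") {
  enforce_rules <- match.arg(enforce_rules)
  entities <- as_tibble(entities)
  gold_relations <- as_tibble(gold_relations)
  k <- nrow(entities)
  empty <- empty_relation_samples
  if (nrow(gold_relations)) {
    missing <- setdiff(c(gold_relations$arg1, gold_relations$arg2),
                       entities$id)
    if (length(missing)) {
      abort(sprintf("gold relation argument not among sentence entities: %s",
                    paste(missing, collapse = ", ")),
            class = "alextract_sample_error")
    }
  }
  if (k < 2) {
    return(empty)
  }
  ord <- order(entities$start, entities$end)
  entities <- entities[ord, ]
  pairs <- t(combn(k, 2))
  n <- nrow(pairs)
  samples <- tibble::new_tibble(list(
    sent_id = rep(sent_id, n),
    e1 = entities$id[pairs[, 1]],
    e2 = entities$id[pairs[, 2]],
    e1_label = entities$label[pairs[, 1]],
    e2_label = entities$label[pairs[, 2]],
    e1_start = entities$start[pairs[, 1]],
    e1_end = entities$end[pairs[, 1]],
    e2_start = entities$start[pairs[, 2]],
    e2_end = entities$end[pairs[, 2]],
    label = rep("no_relation", n),
    split = rep(split, n),
    copy = rep(0L, n)
  ), nrow = n)
  if (nrow(gold_relations)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(samples$e1, samples$e2),
               key(gold_relations$arg1, gold_relations$arg2))
    hit <- !is.na(m)
    samples$label[hit] <- gold_relations$label[m[hit]]
  }
  if (enforce_rules == "strict") {
    allowed <- map_lgl(seq_len(nrow(samples)), function(i) {
      samples$label[i] != "no_relation" ||
        any(map_lgl(schema$relation_classes, function(rc) {
          rule_allows(schema, rc, samples$e1_label[i], samples$e2_label[i])
        }))
    })
    samples <- samples[allowed, ]
  }
  samples
}

#' Generate relation samples for every sentence of a document
#'
#' Entities without a sentence assignment and relations crossing sentence
#' boundaries are excluded (they are validation issues, not samples).
#'
#' @param doc An `ie_document`.
#' @inheritParams generate_relation_samples
#' @return A tibble of samples, see [generate_relation_samples()].
#' @export
relation_samples <- function(doc, schema = doc$schema,
                             enforce_rules = c("relabel", "strict"),
                             split = "train") {
  enforce_rules <- match.arg(enforce_rules)
  ent <- filter(doc$entities, !is.na(.data$sent_id))
  rel <- doc$relations
  if (nrow(rel)) {
    s1 <- ent$sent_id[match(rel$arg1, ent$id)]
    s2 <- ent$sent_id[match(rel$arg2, ent$id)]
    rel <- rel[!is.na(s1) & !is.na(s2) & s1 == s2, ]
  }
  out <- map(doc$sentences$sent_id, function(sid) {
    e <- filter(ent, .data$sent_id == sid)
    r <- rel[rel$arg1 %in% e$id & rel$arg2 %in% e$id, ]
    generate_relation_samples(e, r, schema = schema,
                              enforce_rules = enforce_rules,
                              sent_id = sid, split = split)
  })
  bind_rows(out)
}

#' Oversample positive relation samples in the training split
#'
#' Positive samples (label other than `no_relation`) are duplicated to
#' `factor` copies each to counter the dominance of auto-generated negatives
#' during training; negatives are never touched. Test-split samples are
#' returned unchanged so evaluation reflects the actual label distribution.
#' Copies carry a `copy` index (0 = original) so downstream code can
#' deduplicate.
#'
#' @param samples Tibble of relation samples.
#' @param factor Integer >= 1; number of copies per positive (default 4).
#' @param split Which split these samples belong to; `"test"` disables
#'   oversampling.
#' @return A tibble of samples.
#' @export
oversample_positives <- function(samples, factor = 4L, split = "train") {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != as.integer(factor)) {
    abort("oversampling factor must be an integer >= 1",
          class = "alextract_param_error")
  }
  factor <- as.integer(factor)
  if (identical(split, "test") || factor == 1L || !nrow(samples)) {
    return(samples)
  }
  pos <- filter(samples, .data$label != "no_relation")
  copies <- map(seq_len(factor - 1L), function(i) mutate(pos, copy = i))
  bind_rows(samples, copies) |>
    arrange(.data$sent_id, .data$e1, .data$e2, .data$copy)
}
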