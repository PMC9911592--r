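#' Flatten documents into a sentence pool
#'
#' Builds the tabular pool the active-learning loop operates on: one row per
#' sentence with nested tokens, gold entity spans and gold within-sentence
#' relations. Entities straddling sentence boundaries and cross-sentence
#' relations are excluded (they are validation issues, not samples).
#'
#' @param docs A list of `ie_document` objects (or a single document).
#' @return A tibble with columns `sent_id`, `doc_id`, `text`, and
#'   list-columns `tokens` (tibbles with `surface`, `start`, `end`),
#'   `entities` (tibbles with `id`, `label`, `start`, `end`, `surface`) and
#'   `relations` (tibbles with `label`, `arg1`, `arg2`).
#' @export
as_sentence_pool <- function(docs) {
  if (inherits(docs, "ie_document")) {
    docs <- list(docs)
  }
  rows <- map(docs, function(doc) {
    ent <- filter(doc$entities, !is.na(.data$sent_id))
    rel <- doc$relations
    if (nrow(rel)) {
      s1 <- ent$sent_id[match(rel$arg1, ent$id)]
      s2 <- ent$sent_id[match(rel$arg2, ent$id)]
      rel$sent_id <- ifelse(!is.na(s1) & !is.na(s2) & s1 == s2, s1,
                            NA_character_)
      rel <- filter(rel, !is.na(.data$sent_id))
    } else {
      rel$sent_id <- character()
    }
    sids <- doc$sentences$sent_id
    by_sent <- function(d) {
      chunks <- split(select(d, -"sent_id"),
                      factor(d$sent_id, levels = sids))
      unname(chunks)
    }
    tibble(
      sent_id = sids,
      doc_id = doc$doc_id,
      text = substring(doc$text, doc$sentences$start + 1, doc$sentences$end),
      tokens = by_sent(doc$tokens),
      entities = by_sent(ent),
      relations = by_sent(rel)
    )
  })
  bind_rows(rows)
}

# long token table (sent_id, surface, start, end) for a pool subset
pool_tokens <- function(pool) {
  bind_rows(map2(pool$sent_id, pool$tokens, function(sid, tk) {
    tibble::new_tibble(c(as.list(tk), list(sent_id = rep(sid, nrow(tk)))),
                       nrow = nrow(tk))
  }))
}

# long entity table for a pool subset
pool_entities <- function(pool) {
  bind_rows(map2(pool$sent_id, pool$entities, function(sid, e) {
    if (nrow(e)) mutate(e, sent_id = sid) else NULL
  }))
}

# gold IOB table for a pool subset
pool_iob <- function(pool) {
  bind_rows(map2(pool$sent_id, seq_len(nrow(pool)), function(sid, i) {
    iob <- spans_to_iob(pool$tokens[[i]], pool$entities[[i]])
    n <- nrow(iob)
    tibble::new_tibble(list(
      sent_id = rep(sid, n), surface = iob$surface, tag = iob$tag,
      start = pool$tokens[[i]]$start, end = pool$tokens[[i]]$end
    ), nrow = n)
  }))
}

# gold relation samples (all candidate pairs, labeled) for a pool subset
pool_relation_samples <- function(pool, schema = default_schema(),
                                  split = "train") {
  bind_rows(map(seq_len(nrow(pool)), function(i) {
    generate_relation_samples(pool$entities[[i]], pool$relations[[i]],
                              schema = schema, sent_id = pool$sent_id[i],
                              split = split)
  }))
}

#' Summary statistics of an annotation batch
#'
#' The per-iteration training-set diagnostics of the active-learning loop:
#' batch size, average sentence length (in tokens), average
#' pseudo-perplexity, average number of entities per sentence, and the
#' counts of positive relations and auto-labeled `no_relation` pairs.
#' Statistics are computed on the batch as annotated, before any
#' oversampling.
#'
#' @param pool Sentence-pool tibble rows making up the batch.
#' @param scores Acquisition scores covering the batch (`sent_id`,
#'   `length`, `ppl`), as from [score_pool()]. A sentence without a score is
#'   an error.
#' @return A one-row tibble: `n_sentences`, `avg_sentence_length`,
#'   `avg_ppl`, `avg_entities_per_sentence`, `n_rel_pos`, `n_rel_neg`, plus
#'   a `class_histogram` list-column.
#' @export
batch_stats <- function(pool, scores) {
  m <- match(pool$sent_id, scores$sent_id)
  if (anyNA(m)) {
    abort(sprintf("no acquisition score for sentence(s): %s",
                  paste(head(pool$sent_id[is.na(m)], 3), collapse = ", ")),
          class = "alextract_param_error")
  }
  n_ent <- map_int(pool$entities, nrow)
  n_pos <- map_int(pool$relations, nrow)
  n_pairs <- choose(n_ent, 2)
  tibble(
    n_sentences = nrow(pool),
    avg_sentence_length = mean(scores$length[m]),
    avg_ppl = mean(scores$ppl[m]),
    avg_entities_per_sentence = mean(n_ent),
    n_rel_pos = sum(n_pos),
    n_rel_neg = sum(n_pairs - n_pos),
    class_histogram = list(class_distribution(pool))
  )
}

#' Entity- and relation-class distribution of a sentence set
#'
#' Counts and normalized shares per class, the raw material for class-skew
#' diagnostics (e.g. how strongly a batch is enriched in minority classes).
#'
#' @param pool Sentence-pool tibble rows.
#' @return A tibble with columns `kind` (`"entity"` / `"relation"`),
#'   `class`, `n`, `share` (within kind).
#' @export
class_distribution <- function(pool) {
  ents <- unlist(map(pool$entities, function(e) e$label))
  rels <- unlist(map(pool$relations, function(r) r$label))
  out <- bind_rows(
    if (length(ents)) count(tibble(kind = "entity", class = ents),
                            .data$kind, .data$class, name = "n") else NULL,
    if (length(rels)) count(tibble(kind = "relation", class = rels),
                            .data$kind, .data$class, name = "n") else NULL
  )
  if (!nrow(out)) {
    return(tibble(kind = character(), class = character(), n = integer(),
                  share = numeric()))
  }
  out |>
    group_by(.data$kind) |>
    mutate(share = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$kind, dplyr::desc(.data$n))
}

#' Share of a reference set of rare classes within a batch
#'
#' Given a class distribution of a batch and the set of classes designated
#' rare (e.g. the k rarest classes of the full corpus), returns the fraction
#' of the batch's entity (or relation) mentions belonging to those classes.
#'
#' @param dist A distribution from [class_distribution()].
#' @param rare_classes Character vector of class names.
#' @param kind `"entity"` or `"relation"`.
#' @return A single number in \[0, 1\] (0 for an empty batch).
#' @export
rare_class_share <- function(dist, rare_classes, kind = "entity") {
  d <- filter(dist, .data$kind == !!kind)
  if (!nrow(d)) {
    return(0)
  }
  sum(d$n[d$class %in% rare_classes]) / sum(d$n)
}
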