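#' Construct an annotated document
#'
#' The central corpus container: raw text, sentence and token segmentation
#' with document-absolute 0-based half-open character offsets, entity spans
#' and canonicalized undirected relations. Entities are assigned to the
#' sentence that wholly contains them; an entity straddling a sentence
#' boundary gets `sent_id = NA` and is excluded from sentence-level samples
#' (recorded as a segmentation issue).
#'
#' @param doc_id Document identifier.
#' @param text Document text.
#' @param entities Tibble with columns `id`, `label`, `start`, `end`
#'   (`surface` is recomputed from `text`). May be empty.
#' @param relations Tibble with columns `label`, `arg1`, `arg2` (entity ids).
#'   Stored canonically with `arg1` preceding `arg2` in (start, end) order;
#'   direction carries no meaning. May be empty.
#' @param schema An `ie_schema`; entity and relation labels are checked
#'   against it.
#' @param splitter Sentence splitter: a function `text -> tibble(start, end)`
#'   with 0-based half-open ranges. Defaults to [split_sentence_ranges()].
#' @param sections Optional precomputed tibble of sections (`section`,
#'   `text`); if `NULL`, sections are extracted with default headers.
#' @return An object of class `ie_document`.
#' @export
ie_document <- function(doc_id, text,
                        entities = empty_entities(),
                        relations = empty_relations(),
                        schema = default_schema(),
                        splitter = split_sentence_ranges,
                        sections = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1)
  stopifnot(is.character(text), length(text) == 1)
  entities <- as_tibble(entities)
  relations <- as_tibble(relations)
  n <- nchar(text)

  if (nrow(entities)) {
    bad <- entities$start < 0 | entities$end > n | entities$start >= entities$end
    if (any(bad)) {
      abort(sprintf("entity offsets out of range or empty for: %s",
                    paste(entities$id[bad], collapse = ", ")),
            class = "alextract_offset_error")
    }
    if (anyDuplicated(entities$id)) {
      abort("duplicate entity ids", class = "alextract_offset_error")
    }
    entities$surface <- substring(text, entities$start + 1, entities$end)
  } else {
    entities <- empty_entities()
  }

  if (nrow(relations)) {
    missing <- setdiff(c(relations$arg1, relations$arg2), entities$id)
    if (length(missing)) {
      abort(sprintf("relation argument refers to unknown entity: %s",
                    paste(missing, collapse = ", ")),
            class = "alextract_offset_error")
    }
    relations <- canonicalize_relations(relations, entities)
  } else {
    relations <- empty_relations()
  }

  sent_ranges <- splitter(text)
  sentences <- tibble(
    sent_id = paste0(doc_id, ":s", seq_len(nrow(sent_ranges))),
    start = sent_ranges$start,
    end = sent_ranges$end
  )
  tokens <- pmap(sentences, function(sent_id, start, end) {
    tk <- tokenize_text(substr(text, start + 1, end))
    tk$start <- tk$start + start
    tk$end <- tk$end + start
    tk$sent_id <- sent_id
    tk
  }) |> bind_rows()
  if (!nrow(tokens)) {
    tokens <- tibble(surface = character(), start = integer(),
                     end = integer(), sent_id = character())
  }

  # sentence assignment: wholly-contained, else NA
  entities$sent_id <- rep(NA_character_, nrow(entities))
  if (nrow(entities) && nrow(sentences)) {
    for (i in seq_len(nrow(entities))) {
      hit <- which(sentences$start <= entities$start[i] &
                     entities$end[i] <= sentences$end)
      if (length(hit) == 1) entities$sent_id[i] <- sentences$sent_id[hit]
    }
  }

  structure(
    list(
      doc_id = doc_id,
      text = text,
      sections = sections %||% extract_sections(text),
      sentences = sentences,
      tokens = tokens,
      entities = entities,
      relations = relations,
      schema = schema
    ),
    class = "ie_document"
  )
}

empty_entities <- function() {
  tibble(id = character(), label = character(), start = integer(),
         end = integer(), surface = character())
}

empty_relations <- function() {
  tibble(label = character(), arg1 = character(), arg2 = character())
}

# order args by (start, end) of the referenced spans; idempotent
canonicalize_relations <- function(relations, entities) {
  key <- function(ids) {
    i <- match(ids, entities$id)
    list(start = entities$start[i], end = entities$end[i])
  }
  k1 <- key(relations$arg1)
  k2 <- key(relations$arg2)
  if (any(relations$arg1 == relations$arg2)) {
    abort("relation with identical arguments", class = "alextract_offset_error")
  }
  swap <- k2$start < k1$start | (k2$start == k1$start & k2$end < k1$end)
  a1 <- ifelse(swap, relations$arg2, relations$arg1)
  a2 <- ifelse(swap, relations$arg1, relations$arg2)
  tibble(label = relations$label, arg1 = a1, arg2 = a2) |> distinct()
}

#' @export
print.ie_document <- function(x, ...) {
  cat("<ie_document> ", x$doc_id, "\n", sep = "")
  cat("  text:      ", nchar(x$text), " chars\n", sep = "")
  cat("  sentences: ", nrow(x$sentences), "\n", sep = "")
  cat("  entities:  ", nrow(x$entities), "\n", sep = "")
  cat("  relations: ", nrow(x$relations), "\n", sep = "")
  invisible(x)
}

#' Validate a document's annotations against a schema
#'
#' Reports (never raises) the following issue types: entity or relation
#' labels unknown to the schema, overlapping entity spans, relations whose
#' argument classes violate the schema's relation rules, relations crossing a
#' sentence boundary, and entities straddling sentence boundaries.
#'
#' @param doc An `ie_document`.
#' @param schema An `ie_schema` (defaults to the document's own).
#' @return A tibble with columns `type`, `ref`, `message`; zero rows for a
#'   clean document.
#' @export
validate_annotations <- function(doc, schema = doc$schema) {
  issues <- list()
  add <- function(type, ref, message) {
    issues[[length(issues) + 1]] <<- tibble(type = type, ref = ref,
                                            message = message)
  }
  ent <- doc$entities
  for (i in seq_len(nrow(ent))) {
    if (!ent$label[i] %in% schema$entity_classes) {
      add("unknown_entity_class", ent$id[i],
          sprintf("entity class '%s' not in schema", ent$label[i]))
    }
    if (is.na(ent$sent_id[i])) {
      add("sentence_straddle", ent$id[i],
          "entity is not wholly contained in a single sentence")
    }
  }
  if (nrow(ent) > 1) {
    for (i in seq_len(nrow(ent) - 1)) {
      for (j in seq(i + 1, nrow(ent))) {
        if (ent$start[i] < ent$end[j] && ent$start[j] < ent$end[i]) {
          add("overlap", paste(ent$id[i], ent$id[j], sep = "+"),
              sprintf("entity spans %s and %s overlap", ent$id[i], ent$id[j]))
        }
      }
    }
  }
  rel <- doc$relations
  for (i in seq_len(nrow(rel))) {
    if (!rel$label[i] %in% schema$relation_classes) {
      add("unknown_relation_class", rel$label[i],
          sprintf("relation class '%s' not in schema", rel$label[i]))
      next
    }
    i1 <- match(rel$arg1[i], ent$id)
    i2 <- match(rel$arg2[i], ent$id)
    c1 <- ent$label[i1]; c2 <- ent$label[i2]
    if (c1 %in% schema$entity_classes && c2 %in% schema$entity_classes &&
        !rule_allows(schema, rel$label[i], c1, c2)) {
      add("rule_violation", paste(rel$arg1[i], rel$arg2[i], sep = "+"),
          sprintf("relation '%s' does not allow pair (%s, %s)",
                  rel$label[i], c1, c2))
    }
    s1 <- ent$sent_id[i1]; s2 <- ent$sent_id[i2]
    if (!is.na(s1) && !is.na(s2) && s1 != s2) {
      add("cross_sentence", paste(rel$arg1[i], rel$arg2[i], sep = "+"),
          sprintf("relation '%s' crosses a sentence boundary", rel$label[i]))
    }
  }
  if (!length(issues)) {
    return(tibble(type = character(), ref = character(), message = character()))
  }
  bind_rows(issues)
}
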