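#' Encode entity spans of one sentence as IOB tags
#'
#' The first token of an entity gets `B-<class>`, subsequent tokens
#' `I-<class>`, all remaining tokens `O`. Entity spans must align exactly
#' with token boundaries: a span starting or ending inside a token is a hard
#' error naming the span — silent clipping would corrupt the round trip.
#' Overlapping entities are likewise rejected.
#'
#' @param tokens Tibble of one sentence's tokens (`surface`, `start`, `end`;
#'   offsets in the same coordinate system as `entities`).
#' @param entities Tibble of entity spans (`id`, `label`, `start`, `end`)
#'   lying within the sentence.
#' @return A tibble with columns `surface` and `tag`, one row per token.
#' @examples
#' tk <- tokenize_text("ohne Hinweis auf")
#' ent <- tibble::tibble(id = "T1", label = "Certainty_descriptor",
#'                       start = 0L, end = 12L)
#' spans_to_iob(tk, ent)$tag
#' @export
spans_to_iob <- function(tokens, entities) {
  tokens <- as_tibble(tokens)
  entities <- as_tibble(entities)
  tags <- rep("O", nrow(tokens))
  if (nrow(entities) > 1) {
    ord <- order(entities$start, entities$end)
    entities <- entities[ord, ]
    if (any(entities$start[-1] < entities$end[-nrow(entities)])) {
      abort("overlapping entity spans cannot be IOB-encoded",
            class = "alextract_iob_error")
    }
  }
  for (i in seq_len(nrow(entities))) {
    idx <- which(tokens$start >= entities$start[i] &
                   tokens$end <= entities$end[i])
    aligned <- length(idx) > 0 &&
      tokens$start[idx[1]] == entities$start[i] &&
      tokens$end[idx[length(idx)]] == entities$end[i]
    if (!aligned) {
      abort(sprintf(
        "entity %s [%d,%d) does not align with token boundaries",
        if ("id" %in% names(entities)) entities$id[i] else i,
        entities$start[i], entities$end[i]), class = "alextract_iob_error")
    }
    if (any(tags[idx] != "O")) {
      abort("overlapping entity spans cannot be IOB-encoded",
            class = "alextract_iob_error")
    }
    tags[idx] <- c(paste0("B-", entities$label[i]),
                   rep(paste0("I-", entities$label[i]),
                       length(idx) - 1))
  }
  tibble::new_tibble(list(surface = tokens$surface, tag = tags),
                     nrow = nrow(tokens))
}

#' Decode IOB tags back to entity spans
#'
#' Inverse of [spans_to_iob()]. An orphan `I-c` tag (no preceding `B-c` or
#' `I-c` of the same class) is repaired to `B-c`; repairs are recorded in the
#' `"repairs"` attribute of the result rather than raised, so that model
#' predictions can always be decoded.
#'
#' @param tags Character vector of IOB tags.
#' @param tokens Tibble of the sentence tokens (`surface`, `start`, `end`),
#'   same length as `tags`.
#' @return A tibble of spans (`label`, `start`, `end`, `surface`) with an
#'   integer attribute `repairs` counting orphan-I repairs.
#' @export
iob_to_spans <- function(tags, tokens) {
  tokens <- as_tibble(tokens)
  stopifnot(length(tags) == nrow(tokens))
  repairs <- 0L
  lab <- character(); from <- integer(); to <- integer()
  cur_lab <- NA_character_; cur_from <- 0L; cur_to <- 0L
  flush <- function() {
    if (!is.na(cur_lab)) {
      lab[length(lab) + 1] <<- cur_lab
      from[length(from) + 1] <<- cur_from
      to[length(to) + 1] <<- cur_to
    }
    cur_lab <<- NA_character_
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (is.na(tag) || tag == "O") {
      flush()
      next
    }
    kind <- substr(tag, 1, 1)
    cls <- substring(tag, 3)
    if (kind == "B") {
      flush()
      cur_lab <- cls; cur_from <- i; cur_to <- i
    } else if (kind == "I") {
      if (!is.na(cur_lab) && cur_lab == cls) {
        cur_to <- i
      } else {
        # orphan I-c: repaired to B-c
        repairs <- repairs + 1L
        flush()
        cur_lab <- cls; cur_from <- i; cur_to <- i
      }
    } else {
      abort(sprintf("malformed IOB tag '%s'", tag),
            class = "alextract_iob_error")
    }
  }
  flush()
  out <- tibble::new_tibble(list(
    label = lab,
    start = tokens$start[from],
    end = tokens$end[to],
    surface = rep(NA_character_, length(lab))
  ), nrow = length(lab))
  attr(out, "repairs") <- repairs
  out
}

#' Encode all sentences of a document as IOB sequences
#'
#' Entities without a sentence assignment (boundary straddlers) are skipped;
#' they are already surfaced by [validate_annotations()].
#'
#' @param doc An `ie_document`.
#' @return A tibble with columns `sent_id`, `surface`, `tag`, `start`, `end`.
#' @export
encode_iob <- function(doc) {
  stopifnot(inherits(doc, "ie_document"))
  out <- map(doc$sentences$sent_id, function(sid) {
    tk <- filter(doc$tokens, .data$sent_id == sid)
    ent <- filter(doc$entities, !is.na(.data$sent_id), .data$sent_id == sid)
    iob <- spans_to_iob(tk, ent)
    tibble(sent_id = sid, surface = iob$surface, tag = iob$tag,
           start = tk$start, end = tk$end)
  })
  bind_rows(out)
}

#' Write IOB sequences as CoNLL-style TSV
#'
#' One `token<TAB>tag` line per token, a blank line between sentences.
#'
#' @param iob Tibble as returned by [encode_iob()] (needs `sent_id`,
#'   `surface`, `tag`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(iob, path) {
  chunks <- split(iob, factor(iob$sent_id, levels = unique(iob$sent_id)))
  lines <- unlist(map(chunks, function(ch) {
    c(paste(ch$surface, ch$tag, sep = "\t"), "")
  }), use.names = FALSE)
  writeLines(head(lines, -1), path, useBytes = TRUE)
  invisible(path)
}

#' Read CoNLL-style TSV into IOB sequences
#'
#' @param path File written by [write_conll()].
#' @return A tibble with columns `sent_id` (`s1`, `s2`, ...), `surface`,
#'   `tag`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sid <- cumsum(c(TRUE, !nzchar(head(lines, -1))))
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  tibble(
    sent_id = paste0("s", sid[keep]),
    surface = map_chr(parts, 1),
    tag = map_chr(parts, 2)
  )
}
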