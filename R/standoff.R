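#' Read a brat standoff document
#'
#' Parses brat `T` (entity span) and `R` (binary relation) records. Offsets
#' are 0-based half-open character positions into the text; the surface field
#' of every `T` line is cross-checked against the corresponding text slice
#' and any mismatch is a parse error naming the offending line. Relations are
#' stored canonically with the earlier span (by start, then end offset)
#' first; direction is never meaningful. Attribute (`A`) and note (`#`) lines
#' are not supported and raise an error.
#'
#' @param txt_content Document text (single string).
#' @param ann_content Annotation content (single string, possibly empty);
#'   lines as in a brat `.ann` file.
#' @param schema An `ie_schema` used to check entity and relation classes.
#' @param doc_id Document identifier.
#' @param splitter Sentence splitter, see [ie_document()].
#' @return An `ie_document`.
#' @examples
#' txt <- "Keine rezente Blutung"
#' ann <- paste(
#'   "T1\tCertainty_descriptor 0 5\tKeine",
#'   "T2\tTime_information 6 13\trezente",
#'   "T3\tMedical_condition 14 21\tBlutung",
#'   sep = "\n"
#' )
#' doc <- read_standoff(txt, ann)
#' nrow(doc$entities)
#' @export
read_standoff <- function(txt_content, ann_content, schema = default_schema(),
                          doc_id = "doc1", splitter = split_sentence_ranges) {
  stopifnot(is.character(txt_content), length(txt_content) == 1)
  stopifnot(is.character(ann_content), length(ann_content) == 1)
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]

  ents <- list()
  rels <- list()
  for (line in lines) {
    if (grepl("^T", line)) {
      m <- regmatches(line,
                      regexec("^(T\\d+)\t(\\S+) (\\d+) (\\d+)\t(.*)$", line))[[1]]
      if (!length(m)) {
        abort(sprintf("malformed T line: %s", line),
              class = "alextract_parse_error")
      }
      id <- m[2]; label <- m[3]
      start <- as.integer(m[4]); end <- as.integer(m[5]); surface <- m[6]
      if (start < 0 || end > nchar(txt_content) || start >= end) {
        abort(sprintf("offsets out of range in line %s (%d..%d, text has %d chars)",
                      id, start, end, nchar(txt_content)),
              class = "alextract_parse_error")
      }
      slice <- substr(txt_content, start + 1, end)
      if (!identical(slice, surface)) {
        abort(sprintf(
          "surface mismatch in line %s: annotation says '%s' but text slice is '%s'",
          id, surface, slice), class = "alextract_parse_error")
      }
      if (!label %in% schema$entity_classes) {
        abort(sprintf("unknown entity class '%s' in line %s", label, id),
              class = "alextract_schema_violation")
      }
      ents[[length(ents) + 1]] <-
        tibble(id = id, label = label, start = start, end = end,
               surface = surface)
    } else if (grepl("^R", line)) {
      m <- regmatches(line,
                      regexec("^(R\\d+)\t(\\S+) Arg1:(T\\d+) Arg2:(T\\d+)\\s*$",
                              line))[[1]]
      if (!length(m)) {
        abort(sprintf("malformed R line: %s", line),
              class = "alextract_parse_error")
      }
      if (!m[3] %in% schema$relation_classes) {
        abort(sprintf("unknown relation class '%s' in line %s", m[3], m[2]),
              class = "alextract_schema_violation")
      }
      rels[[length(rels) + 1]] <- tibble(label = m[3], arg1 = m[4], arg2 = m[5])
    } else {
      abort(sprintf("unsupported annotation line (only T and R records): %s",
                    line), class = "alextract_parse_error")
    }
  }
  ie_document(
    doc_id = doc_id, text = txt_content,
    entities = if (length(ents)) bind_rows(ents) else empty_entities(),
    relations = if (length(rels)) bind_rows(rels) else empty_relations(),
    schema = schema, splitter = splitter
  )
}

#' Write a document to brat standoff content
#'
#' Inverse of [read_standoff()]: `read_standoff(write_standoff(doc))`
#' reproduces the document's entities and relations exactly.
#'
#' @param doc An `ie_document`.
#' @return A list with elements `txt` and `ann` (single strings; `ann` is
#'   `""` for an unannotated document).
#' @export
write_standoff <- function(doc) {
  stopifnot(inherits(doc, "ie_document"))
  ent <- doc$entities
  t_lines <- character()
  if (nrow(ent)) {
    ord <- order(suppressWarnings(as.integer(sub("^T", "", ent$id))),
                 ent$id, na.last = TRUE)
    ent <- ent[ord, ]
    t_lines <- sprintf("%s\t%s %d %d\t%s", ent$id, ent$label, ent$start,
                       ent$end, ent$surface)
  }
  rel <- doc$relations
  r_lines <- character()
  if (nrow(rel)) {
    r_lines <- sprintf("R%d\t%s Arg1:%s Arg2:%s", seq_len(nrow(rel)),
                       rel$label, rel$arg1, rel$arg2)
  }
  list(txt = doc$text, ann = paste(c(t_lines, r_lines), collapse = "\n"))
}

#' Read a brat standoff corpus directory
#'
#' Reads every `.txt` file that has a sibling `.ann` file (a missing `.ann`
#' is treated as unannotated).
#'
#' @param dir Directory of `.txt`/`.ann` pairs.
#' @inheritParams read_standoff
#' @return A list of `ie_document` objects, named by document id (the file
#'   stem).
#' @export
read_standoff_dir <- function(dir, schema = default_schema(),
                              splitter = split_sentence_ranges) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- map(txts, function(f) {
    stem <- sub("\\.txt$", "", basename(f))
    annf <- file.path(dir, paste0(stem, ".ann"))
    ann <- if (file.exists(annf)) {
      paste(readLines(annf, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    } else ""
    read_standoff(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"),
                  ann, schema = schema, doc_id = stem, splitter = splitter)
  })
  setNames(docs, map_chr(docs, "doc_id"))
}

#' Write documents to a brat standoff directory
#'
#' @param docs A list of `ie_document` objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_standoff_dir <- function(docs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (doc in docs) {
    so <- write_standoff(doc)
    writeLines(so$txt, file.path(dir, paste0(doc$doc_id, ".txt")), useBytes = TRUE)
    writeLines(so$ann, file.path(dir, paste0(doc$doc_id, ".ann")), useBytes = TRUE)
  }
  invisible(dir)
}
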