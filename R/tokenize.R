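#' Tokenize text into word and punctuation tokens with character offsets
#'
#' Tokens are maximal runs of Unicode letters, digits and underscores, plus
#' standalone punctuation characters. Offsets are 0-based half-open character
#' positions into `text`, so `substr(text, start + 1, end)` recovers the
#' surface. Subword tokenization belongs to model backends, not to the corpus
#' layer: corpus offsets stay model-independent.
#'
#' @param text A single string.
#' @return A tibble with columns `surface`, `start`, `end`.
#' @examples
#' tokenize_text("Keine rezente Blutung.")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) {
    return(tibble(surface = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(surface = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::new_tibble(list(
    surface = substring(text, m, m + len - 1),
    start = as.integer(m - 1L),
    end = as.integer(m - 1L + len)
  ), nrow = length(m))
}

default_abbreviations <- function() {
  c("z.B.", "ca.", "bzw.", "u.a.", "V.a.", "Z.n.", "St.p.", "inkl.",
    "bds.", "re.", "li.", "Dr.", "Prof.", "vgl.", "evtl.", "ggf.")
}

#' Split text into sentence ranges
#'
#' Rule-based splitter: sentence boundaries fall after `.`, `!` or `?`
#' followed by whitespace, and at line breaks. A configurable abbreviation
#' list protects common German clinical abbreviations from splitting.
#' The splitter is pluggable everywhere it is used: any function mapping a
#' string to a tibble of 0-based half-open `start`/`end` ranges can replace
#' it.
#'
#' @param text A single string.
#' @param abbreviations Character vector of abbreviations that must not end a
#'   sentence.
#' @return A tibble with columns `start`, `end` (0-based, half-open), one row
#'   per sentence, whitespace-trimmed, ordered, non-overlapping.
#' @export
split_sentence_ranges <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar(text)
  if (n == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  chars <- strsplit(text, "")[[1]]
  # candidate boundary after position i (1-based char index)
  boundary <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") {
      boundary[i] <- TRUE
    } else if (ch %in% c(".", "!", "?")) {
      nxt <- if (i < n) chars[i + 1] else " "
      if (grepl("\\s", nxt)) {
        # protect abbreviations: the token ending at i
        pre <- sub(".*\\s", "", substr(text, max(1, i - 12), i))
        if (!(pre %in% abbreviations)) boundary[i] <- TRUE
      }
    }
  }
  cuts <- which(boundary)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  # trim whitespace off each slice
  out <- map2(starts, ends, function(s, e) {
    slice <- substr(text, s, e)
    lead <- nchar(sub("^(\\s*).*$", "\\1", slice))
    trail <- nchar(sub("^.*?(\\s*)$", "\\1", slice))
    s2 <- s + lead
    e2 <- e - trail
    if (s2 > e2) NULL else c(s2 - 1L, e2)  # to 0-based half-open
  })
  out <- out[!map_lgl(out, is.null)]
  if (!length(out)) {
    return(tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Default section-header synonyms for radiology reports
#'
#' Maps header strings as they appear in reports (German and English) to the
#' four canonical sections of a radiology report.
#'
#' @return A named character vector: names are header strings, values are
#'   canonical section names (`findings`, `impression`, `history`,
#'   `comparison`).
#' @export
default_section_headers <- function() {
  c(
    Befund = "findings", Findings = "findings",
    Beurteilung = "impression", Impression = "impression",
    Anamnese = "history", Klinik = "history", History = "history",
    Vergleich = "comparison", Comparison = "comparison"
  )
}

#' Extract named report sections from free text
#'
#' Headers are matched case-insensitively as `Header:`; each detected header
#' owns the text up to the next header. Text before the first header is
#' returned as section `"preamble"`. A header occurring twice contributes a
#' second segment appended (newline-joined) to the same section. Sections
#' absent from the text are absent from the result.
#'
#' @param text Report text, a single string.
#' @param headers Named character vector mapping header strings to canonical
#'   section names; see [default_section_headers()].
#' @return A tibble with columns `section` and `text`.
#' @examples
#' extract_sections("Befund: A. Beurteilung: B.")
#' @export
extract_sections <- function(text, headers = default_section_headers()) {
  stopifnot(is.character(text), length(text) == 1)
  if (!length(headers)) {
    return(tibble(section = "preamble", text = text))
  }
  pat <- sprintf("(?i)(?:^|(?<=[\\s\\n]))(%s)\\s*:",
                 paste(map_chr(names(headers),
                               function(h) gsub("([.|()\\^{}+$*?\\[\\]\\\\])",
                                                "\\\\\\1", h)),
                       collapse = "|"))
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(section = "preamble", text = text))
  }
  len <- attr(m, "match.length")
  hdr_txt <- substring(text, m, m + len - 1)
  hdr_name <- sub("\\s*:$", "", hdr_txt)
  canon <- unname(headers[match(tolower(hdr_name), tolower(names(headers)))])
  seg_start <- m + len
  seg_end <- c(m[-1] - 1L, nchar(text))
  segs <- tibble(
    section = canon,
    text = trimws(substring(text, seg_start, seg_end))
  )
  pre <- trimws(substr(text, 1, m[1] - 1))
  if (nzchar(pre)) {
    segs <- bind_rows(tibble(section = "preamble", text = pre), segs)
  }
  segs |>
    group_by(.data$section) |>
    summarise(text = paste(.data$text, collapse = "\n"), .groups = "drop") |>
    arrange(match(.data$section,
                  c("preamble", "findings", "impression", "history", "comparison")))
}
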