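#' Entity-level macro-F1 for named entity recognition
#'
#' Under strict matching (default), a predicted span counts as a true
#' positive only on an exact (sentence, start, end, class) match with a gold
#' span. Under token-level matching, spans are expanded to per-token class
#' labels over the supplied tokens and counted per token. Per-class
#' precision, recall and F1 use the 0-convention (F1 = 0 when P + R = 0);
#' the macro-F1 is the unweighted mean of per-class F1 over all classes with
#' gold or predicted support — every class counts equally, regardless of
#' frequency. `O` (non-entity) is never a class.
#'
#' @param gold Gold entities: tibble with `sent_id`, `label`, `start`,
#'   `end`; or an `ie_document` (its entities are used).
#' @param pred Predicted entities, same shape.
#' @param matching `"strict"` (exact span) or `"token"`.
#' @param tokens Tokens tibble (`sent_id`, `start`, `end`), required for
#'   token-level matching.
#' @return An `eval_report`: per-class counts and scores plus the macro-F1.
#' @export
macro_f1_ner <- function(gold, pred, matching = c("strict", "token"),
                         tokens = NULL) {
  matching <- match.arg(matching)
  gold <- entity_table(gold)
  pred <- entity_table(pred)
  if (matching == "token") {
    if (is.null(tokens)) {
      abort("token-level matching needs a tokens tibble",
            class = "alextract_param_error")
    }
    gold <- spans_to_token_units(gold, tokens)
    pred <- spans_to_token_units(pred, tokens)
  }
  classes <- sort(union(gold$label, pred$label))
  per_class <- map(classes, function(cl) {
    g <- filter(gold, .data$label == cl)
    p <- filter(pred, .data$label == cl)
    key <- function(d) paste(d$sent_id, d$start, d$end)
    tp <- sum(key(p) %in% key(g))
    tibble(class = cl, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp,
           support = nrow(g))
  }) |> bind_rows()
  new_eval_report(per_class, task = "ner", matching = matching)
}

entity_table <- function(x) {
  if (inherits(x, "ie_document")) {
    x <- filter(x$entities, !is.na(.data$sent_id))
  }
  as_tibble(x)[, c("sent_id", "label", "start", "end")]
}

# expand spans to one row per covered token (token-level matching)
spans_to_token_units <- function(spans, tokens) {
  tokens <- as_tibble(tokens)
  out <- map(seq_len(nrow(spans)), function(i) {
    tk <- filter(tokens, .data$sent_id == spans$sent_id[i],
                 .data$start >= spans$start[i], .data$end <= spans$end[i])
    if (!nrow(tk)) return(NULL)
    tibble(sent_id = tk$sent_id, label = spans$label[i],
           start = tk$start, end = tk$end)
  })
  bind_rows(out)
}

#' Macro-F1 for relation extraction
#'
#' Gold and predicted samples are aligned on the canonical pair key
#' `(sent_id, e1, e2)`; a predicted pair outside the gold candidate universe
#' is an error (candidate pairs are generated from the same entity sets for
#' both sides). By default `no_relation` is excluded from the macro mean:
#' the overwhelming negative class would otherwise mask performance on the
#' relation classes that are meant to count equally. Set
#' `include_no_relation = TRUE` to bracket that choice. Scoring is symmetric
#' in argument order because the pair key is canonical.
#'
#' @param gold_samples Tibble of gold relation samples (`sent_id`, `e1`,
#'   `e2`, `label`), e.g. from [relation_samples()].
#' @param pred_samples Tibble of the same pairs with predicted `label`.
#' @param include_no_relation Count `no_relation` as a class (default
#'   `FALSE`).
#' @return An `eval_report`.
#' @export
macro_f1_re <- function(gold_samples, pred_samples,
                        include_no_relation = FALSE) {
  key <- function(d) paste(d$sent_id, pmin(d$e1, d$e2), pmax(d$e1, d$e2))
  gk <- key(gold_samples)
  pk <- key(pred_samples)
  outside <- setdiff(pk, gk)
  if (length(outside)) {
    abort(sprintf("predicted pair not in the gold universe: %s",
                  paste(head(outside, 3), collapse = "; ")),
          class = "alextract_param_error")
  }
  m <- match(gk, pk)
  conf <- tibble(
    gold = gold_samples$label,
    pred = ifelse(is.na(m), "no_relation", pred_samples$label[m])
  )
  classes <- sort(union(conf$gold, conf$pred))
  if (!include_no_relation) {
    classes <- setdiff(classes, "no_relation")
  }
  per_class <- map(classes, function(cl) {
    tp <- sum(conf$gold == cl & conf$pred == cl)
    fp <- sum(conf$gold != cl & conf$pred == cl)
    fn <- sum(conf$gold == cl & conf$pred != cl)
    tibble(class = cl, tp = tp, fp = fp, fn = fn,
           support = sum(conf$gold == cl))
  }) |> bind_rows()
  new_eval_report(per_class, task = "re",
                  matching = if (include_no_relation) "with_no_relation"
                  else "positives_only")
}

new_eval_report <- function(per_class, task, matching) {
  per_class <- per_class |>
    mutate(
      precision = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), 0),
      recall = ifelse(.data$tp + .data$fn > 0,
                      .data$tp / (.data$tp + .data$fn), 0),
      f1 = ifelse(.data$precision + .data$recall > 0,
                  2 * .data$precision * .data$recall /
                    (.data$precision + .data$recall), 0)
    ) |>
    filter(.data$support > 0 | .data$tp + .data$fp > 0)
  macro <- if (nrow(per_class)) mean(per_class$f1) else NA_real_
  structure(
    list(task = task, matching = matching, per_class = per_class,
         macro_f1 = macro),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task=%s matching=%s\n", x$task, x$matching))
  cat(sprintf("  macro-F1: %.4f over %d classes\n", x$macro_f1,
              nrow(x$per_class)))
  print(x$per_class, n = 8)
  invisible(x)
}

#' Tidy an evaluation report into per-class rows
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per class: counts, precision, recall, F1.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  mutate(x$per_class, task = x$task)
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble: task, matching mode, macro-F1, number of
#'   classes, total gold support.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(task = x$task, matching = x$matching, macro_f1 = x$macro_f1,
         n_classes = nrow(x$per_class), support = sum(x$per_class$support))
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of the two annotators' marginal
#' label distributions. With degenerate marginals (`p_e = 1`), kappa is 1
#' when observed agreement is also perfect and undefined (error) otherwise.
#'
#' @param ann1,ann2 Equal-length label vectors.
#' @return A single number in \[-1, 1\].
#' @examples
#' cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))  # 0
#' @export
cohen_kappa <- function(ann1, ann2) {
  if (length(ann1) != length(ann2)) {
    abort("annotator label sequences must have equal length",
          class = "alextract_param_error")
  }
  if (!length(ann1)) {
    abort("cannot compute agreement on empty sequences",
          class = "alextract_param_error")
  }
  levels <- sort(union(ann1, ann2))
  a <- factor(ann1, levels = levels)
  b <- factor(ann2, levels = levels)
  p_o <- mean(a == b)
  p_e <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (isTRUE(all.equal(p_e, 1))) {
    if (isTRUE(all.equal(p_o, 1))) {
      return(1)
    }
    abort("expected agreement is 1 with imperfect observed agreement; kappa undefined",
          class = "alextract_param_error")
  }
  (p_o - p_e) / (1 - p_e)
}
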