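#' Plot the learning curve of an active-learning run
#'
#' Held-out macro-F1 (NER and RE) against iteration, with vertical marks
#' where the query strategy changes.
#'
#' @param object An `al_state` with a history containing held-out scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot al_state
#' @export
autoplot.al_state <- function(object, ...) {
  h <- tidy(object)
  if (!nrow(h) || !"ner_macro_f1" %in% names(h)) {
    abort("history carries no held-out scores; run with a test_pool",
          class = "alextract_param_error")
  }
  long <- tidyr::pivot_longer(
    h[, c("iteration", "ner_macro_f1", "re_macro_f1")],
    c("ner_macro_f1", "re_macro_f1"),
    names_to = "task", values_to = "macro_f1"
  )
  long$task <- ifelse(long$task == "ner_macro_f1", "NER", "RE")
  switches <- h$iteration[which(h$strategy != dplyr::lag(h$strategy,
                                                         default = h$strategy[1]))]
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$iteration, y = .data$macro_f1,
                                    colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "active-learning iteration", y = "held-out macro-F1",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (length(switches)) {
    p <- p + ggplot2::geom_vline(xintercept = switches, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot entity- or relation-class distributions
#'
#' Side-by-side class histograms, e.g. of a strategic versus a random
#' batch, to visualize minority-class enrichment.
#'
#' @param dists Named list of distributions from [class_distribution()]
#'   (names become facet labels).
#' @param kind `"entity"` or `"relation"`.
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(dists, kind = "entity") {
  long <- bind_rows(imap(dists, function(d, nm) {
    mutate(filter(d, .data$kind == !!kind), set = nm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                                     y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = NULL, y = "share of mentions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
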