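#' The default clinical annotation schema
#'
#' A general annotation schema for radiology reports covering 20 entity
#' classes (pathological findings, anatomy, imaging observations, descriptors,
#' specifications such as dosing, measurements and temporal information) and
#' 15 undirected relation classes. Relation rules restrict, for a subset of
#' relations, which unordered pairs of entity classes may serve as arguments;
#' relations without a rule are unrestricted. The reserved label
#' `"no_relation"` marks entity pairs without an annotated relation and is
#' never itself a relation class.
#'
#' @return An object of class `ie_schema`: a list with character vectors
#'   `entity_classes` and `relation_classes`, and `relation_rules`, a named
#'   list mapping a relation class to a two-column tibble of allowed unordered
#'   entity-class pairs (a zero-row tibble means unrestricted).
#' @examples
#' sc <- default_schema()
#' length(sc$entity_classes)   # 20
#' length(sc$relation_classes) # 15
#' @export
default_schema <- function() {
  entity_classes <- c(
    "Medical_condition", "Anatomical_entity", "Imaging_observation",
    "Diaglab_procedure", "Non_anatomical_substance", "Procedure",
    "Medical_device", "Follow_Up", "Prior_investigation",
    "Location_descriptor", "Certainty_descriptor", "Quality_descriptor",
    "Radlex_descriptor", "Dosing", "State_of_health", "Measurement",
    "Time_information", "Dynamism", "Property", "Score_Grade_Type"
  )
  relation_classes <- c(
    "Shows", "Examines", "Compares", "DDx", "Recommendation",
    "Has_state", "Has_property", "Has_dosing", "Has_time_info",
    "Has_measure", "Has_dynamic", "Has_score", "Has_treated",
    "Is_located", "Certainty"
  )
  pair_tbl <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble(class1 = pmin(m[, 1], m[, 2]), class2 = pmax(m[, 1], m[, 2]))
  }
  rules <- list(
    Shows = pair_tbl(
      "Diaglab_procedure", "Medical_condition",
      "Diaglab_procedure", "Imaging_observation"
    ),
    Examines = pair_tbl("Diaglab_procedure", "Anatomical_entity"),
    Recommendation = pair_tbl(
      "Follow_Up", "Medical_condition",
      "Follow_Up", "Imaging_observation"
    ),
    Has_state = pair_tbl(
      "Medical_condition", "Imaging_observation",
      "Anatomical_entity", "Imaging_observation"
    ),
    Has_dosing = pair_tbl("Dosing", "Non_anatomical_substance"),
    Has_treated = pair_tbl("Procedure", "Medical_condition"),
    Is_located = pair_tbl(
      "Location_descriptor", "Medical_condition",
      "Location_descriptor", "Imaging_observation",
      "Anatomical_entity", "Medical_condition",
      "Anatomical_entity", "Imaging_observation"
    )
  )
  new_schema(entity_classes, relation_classes, rules)
}

new_schema <- function(entity_classes, relation_classes, relation_rules = list()) {
  check_class_names <- function(x, what) {
    if (anyDuplicated(x)) {
      abort(sprintf("duplicate %s class name: %s", what,
                    paste(unique(x[duplicated(x)]), collapse = ", ")),
            class = "alextract_schema_error")
    }
    bad <- x[!nzchar(x) | grepl("\\s", x)]
    if (length(bad)) {
      abort(sprintf("invalid %s class name (empty or contains whitespace): %s",
                    what, paste(shQuote(bad), collapse = ", ")),
            class = "alextract_schema_error")
    }
  }
  check_class_names(entity_classes, "entity")
  check_class_names(relation_classes, "relation")
  if ("no_relation" %in% relation_classes) {
    abort("'no_relation' is reserved and cannot be a relation class",
          class = "alextract_schema_error")
  }
  unknown_rel <- setdiff(names(relation_rules), relation_classes)
  if (length(unknown_rel)) {
    abort(sprintf("relation rule refers to unknown relation class: %s",
                  paste(unknown_rel, collapse = ", ")),
          class = "alextract_schema_error")
  }
  relation_rules <- map(relation_rules, function(tb) {
    tb <- as_tibble(tb)
    bad <- setdiff(unique(c(tb$class1, tb$class2)), entity_classes)
    if (length(bad)) {
      abort(sprintf("relation rule refers to unknown entity class: %s",
                    paste(bad, collapse = ", ")),
            class = "alextract_schema_error")
    }
    tibble(class1 = pmin(tb$class1, tb$class2),
           class2 = pmax(tb$class1, tb$class2))
  })
  structure(
    list(entity_classes = entity_classes,
         relation_classes = relation_classes,
         relation_rules = relation_rules),
    class = "ie_schema"
  )
}

#' Load an annotation schema from a YAML config or use the default
#'
#' The config file is a YAML map with keys `entity_classes` (list of names),
#' `relation_classes` (list of names) and optionally `relation_rules`, a map
#' from relation class to a list of two-element entity-class pairs. With no
#' path, the built-in default radiology schema is returned.
#'
#' @param path Path to a YAML schema config, or `NULL` for the default.
#' @return An `ie_schema` object.
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) {
    return(default_schema())
  }
  rlang::check_installed("yaml")
  cfg <- yaml::read_yaml(path)
  rules <- map(cfg$relation_rules %||% list(), function(pairs) {
    m <- do.call(rbind, map(pairs, function(p) {
      if (length(p) != 2) {
        abort("each relation rule entry must be a pair of entity classes",
              class = "alextract_schema_error")
      }
      as.character(p)
    }))
    tibble(class1 = m[, 1], class2 = m[, 2])
  })
  new_schema(
    entity_classes = as.character(unlist(cfg$entity_classes %||% character())),
    relation_classes = as.character(unlist(cfg$relation_classes %||% character())),
    relation_rules = rules
  )
}

#' @export
print.ie_schema <- function(x, ...) {
  cat("<ie_schema>\n")
  cat("  entity classes:   ", length(x$entity_classes), "\n")
  cat("  relation classes: ", length(x$relation_classes), "\n")
  cat("  restricted rules: ", length(x$relation_rules), "\n")
  invisible(x)
}

# TRUE iff the unordered pair (c1, c2) is allowed as arguments of `label`
rule_allows <- function(schema, label, c1, c2) {
  rule <- schema$relation_rules[[label]]
  if (is.null(rule) || nrow(rule) == 0) {
    return(TRUE)
  }
  lo <- pmin(c1, c2)
  hi <- pmax(c1, c2)
  any(rule$class1 == lo & rule$class2 == hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
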