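#' Emotion category hierarchy
#'
#' The default hierarchy used throughout the package: total affect at the
#' root, positive and negative emotion beneath it, and the anxiety, anger
#' and sadness subcategories beneath negative emotion. This mirrors the
#' arrangement used by LIWC-family dictionaries, where a hit on a
#' subcategory (e.g. "cried" in sadness) also counts toward negative
#' emotion and total affect.
#'
#' @return A tibble with columns `id`, `name`, `parent` (`NA` for the root).
#' @export
#' @examples
#' emotion_hierarchy()
emotion_hierarchy <- function() {
  tibble::tibble(
    id     = c("affect", "posemo", "negemo", "anx", "anger", "sad"),
    name   = c("Total affect", "Positive emotion", "Negative emotion",
               "Anxiety", "Anger", "Sadness"),
    parent = c(NA, "affect", "affect", "negemo", "negemo", "negemo")
  )
}

tdx_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "textdx_error")))
}

#' Validate a category table
#'
#' Checks that the hierarchy is acyclic, that every non-root category has
#' exactly one parent that resolves in the table, and that ids are unique.
#'
#' @param categories Tibble with columns `id`, `name`, `parent`.
#' @return The table, invisibly, if valid; otherwise an error of class
#'   `textdx_lexicon_error`.
#' @export
validate_hierarchy <- function(categories) {
  if (anyDuplicated(categories$id)) {
    tdx_error("duplicate category ids in hierarchy", "textdx_lexicon_error")
  }
  known <- categories$id
  bad <- !is.na(categories$parent) & !(categories$parent %in% known)
  if (any(bad)) {
    tdx_error(
      paste0("unknown parent category: ",
             paste(categories$parent[bad], collapse = ", ")),
      "textdx_lexicon_error"
    )
  }
  # cycle check: walking up from any node must terminate within |V| steps
  parent_of <- stats::setNames(categories$parent, categories$id)
  for (id in known) {
    cur <- id
    for (step in seq_len(nrow(categories) + 1L)) {
      cur <- parent_of[[cur]]
      if (is.na(cur)) break
      if (cur == id || step > nrow(categories)) {
        tdx_error(paste0("category hierarchy contains a cycle at '", id, "'"),
                  "textdx_lexicon_error")
      }
    }
  }
  invisible(categories)
}

#' Ancestors of a category
#'
#' @param id Category id.
#' @param categories Category table (default [emotion_hierarchy()]).
#' @return Character vector of ancestor ids, nearest first (may be empty).
#' @export
category_ancestors <- function(id, categories = emotion_hierarchy()) {
  parent_of <- stats::setNames(categories$parent, categories$id)
  if (!id %in% categories$id) {
    tdx_error(paste0("unknown category '", id, "'"), "textdx_lexicon_error")
  }
  out <- character()
  cur <- parent_of[[id]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

#' Expand category ids upward through the hierarchy
#'
#' A hit on a subcategory propagates to every ancestor, so the returned set
#' is closed under parent expansion (a sadness hit yields sadness, negative
#' emotion and total affect).
#'
#' @param ids Character vector of category ids (may be empty).
#' @param categories Category table.
#' @return Sorted character vector, closed under parent expansion.
#' @export
expand_categories <- function(ids, categories = emotion_hierarchy()) {
  if (length(ids) == 0L) return(character())
  unknown <- setdiff(ids, categories$id)
  if (length(unknown) > 0L) {
    tdx_error(paste0("entry references unknown category: ",
                     paste(unknown, collapse = ", ")),
              "textdx_lexicon_error")
  }
  anc <- unlist(lapply(ids, category_ancestors, categories = categories))
  sort(unique(c(ids, anc)))
}
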