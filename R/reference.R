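#' Human coding subcategories
#'
#' The closed 8-value scheme used for token-level human emotion coding:
#' three positive subcategories, three specific negative subcategories, a
#' residual negative class, and not-emotion.
#'
#' @return Character vector of the eight subcategory names.
#' @export
reference_subcategories <- function() {
  c("positive-feelings", "optimism", "anxiety", "anger", "sadness",
    "other-positive", "other-negative", "not-emotion")
}

#' Roll a human subcategory up to machine category ids
#'
#' Human subcategories map onto the machine hierarchy at the finest level
#' that exists there: anxiety/anger/sadness keep their own machine
#' subcategory and gain negative emotion and total affect; the positive
#' subcategories (including optimism and positive feelings, which newer
#' dictionary versions dropped for poor base rates) map to positive emotion
#' and total affect; other-negative maps to negative emotion and total
#' affect; not-emotion maps to the empty set.
#'
#' @param subcategory Character vector of subcategory names.
#' @param categories Category table.
#' @return A list of character vectors (one per input element), each closed
#'   under parent expansion.
#' @export
#' @examples
#' rollup("anxiety")
#' rollup("not-emotion")
rollup <- function(subcategory, categories = emotion_hierarchy()) {
  map <- list(
    "positive-feelings" = "posemo",
    "optimism"          = "posemo",
    "other-positive"    = "posemo",
    "anxiety"           = "anx",
    "anger"             = "anger",
    "sadness"           = "sad",
    "other-negative"    = "negemo",
    "not-emotion"       = character()
  )
  unknown <- setdiff(subcategory, names(map))
  if (length(unknown) > 0L) {
    tdx_error(paste0("unknown subcategory: ", paste(unknown, collapse = ", ")),
              "textdx_data_error")
  }
  uniq <- unique(subcategory)
  sets <- lapply(uniq, function(s) expand_categories(map[[s]], categories))
  sets[match(subcategory, uniq)]
}

#' Read / write token-level reference annotations
#'
#' TSV with a required header row and columns `participant_id`, `position`,
#' `surface`, `subcategory` (UTF-8). At most one label per (participant,
#' position); subcategories must come from [reference_subcategories()].
#'
#' @param path File path.
#' @return A tibble of reference labels.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    tdx_error(paste0("reference file not found: ", path),
              "textdx_config_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("participant_id", "position", "surface", "subcategory")
  if (!all(need %in% names(df))) {
    tdx_error(paste0(path, ": reference TSV must have columns ",
                     paste(need, collapse = ", ")), "textdx_parse_error")
  }
  df$position <- as.integer(df$position)
  validate_reference(tibble::as_tibble(df[need]))
}

#' @rdname read_reference
#' @param labels A reference-label tibble.
#' @export
write_reference <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_reference <- function(labels) {
  unknown <- setdiff(unique(labels$subcategory), reference_subcategories())
  if (length(unknown) > 0L) {
    tdx_error(paste0("unknown subcategory: ", paste(unknown, collapse = ", ")),
              "textdx_data_error")
  }
  if (anyDuplicated(labels[, c("participant_id", "position")])) {
    tdx_error("more than one reference label at a (participant, position)",
              "textdx_data_error")
  }
  labels
}

#' Align reference labels with a tagged corpus
#'
#' Pairs every countable token with its human reference label (rolled up
#' through the hierarchy; unlabeled tokens and not-emotion labels give the
#' empty set) and the machine-predicted category set.
#'
#' @param reference Reference-label tibble (see [read_reference()]); rows
#'   with subcategory "not-emotion" are allowed and equivalent to absent.
#' @param tagged Output of [tag_corpus()].
#' @param categories Category table.
#' @return An object of class `textdx_aligned` with elements `tokens`
#'   (tibble: participant_id, position, surface, norm), `ref` and `pred`
#'   (logical token x category matrices, both closed under parent
#'   expansion), `categories`, `participants`, `total_tokens`.
#' @export
align <- function(reference, tagged, categories = emotion_hierarchy()) {
  validate_reference(reference)
  tg <- tagged[tagged$countable, ]
  tg <- dplyr::arrange(tg, .data$participant_id, .data$position)
  key_tok <- paste(tg$participant_id, tg$position)
  key_ref <- paste(reference$participant_id, reference$position)
  miss <- !(key_ref %in% key_tok)
  if (any(miss)) {
    # distinguish "past end of document" from "on a non-countable token"
    maxpos <- tapply(tagged$position, tagged$participant_id, max)
    beyond <- is.na(maxpos[reference$participant_id[miss]]) |
      reference$position[miss] > maxpos[reference$participant_id[miss]]
    if (any(beyond)) {
      tdx_error(
        paste0("reference label position exceeds document length for ",
               paste(unique(reference$participant_id[miss][beyond]),
                     collapse = ", ")),
        "textdx_data_error"
      )
    }
    warning("dropping ", sum(miss),
            " reference label(s) on non-countable tokens")
    reference <- reference[!miss, ]
    key_ref <- key_ref[!miss]
  }
  ref_sets <- rep(list(character()), nrow(tg))
  if (nrow(reference) > 0L) {
    ref_sets[match(key_ref, key_tok)] <-
      rollup(reference$subcategory, categories)
  }
  structure(
    list(
      tokens = tg[, c("participant_id", "position", "surface", "norm")],
      ref = category_matrix(ref_sets, categories$id),
      pred = category_matrix(tg$categories, categories$id),
      categories = categories,
      participants = unique(tg$participant_id),
      total_tokens = nrow(tg)
    ),
    class = "textdx_aligned"
  )
}

#' @export
print.textdx_aligned <- function(x, ...) {
  cat("<textdx_aligned>", x$total_tokens, "tokens,",
      length(x$participants), "participants,",
      sum(rowSums(x$ref) > 0), "reference-emotion tokens\n")
  invisible(x)
}

#' Per-participant percentages of the reference coding
#'
#' The human-coder analogue of [category_percentages()]: rolls the
#' reference labels up the hierarchy and reports per-participant
#' percentages of countable tokens.
#'
#' @param aligned A [align()] result.
#' @return Long tibble like [category_percentages()].
#' @export
reference_percentages <- function(aligned) {
  ids <- aligned$categories$id
  pid <- aligned$tokens$participant_id
  n_by <- table(pid)
  out <- lapply(ids, function(cid) {
    h <- tapply(aligned$ref[, cid], pid, sum)
    nn <- as.integer(n_by[names(h)])
    tibble::tibble(
      participant_id = names(h), category = cid,
      hits = as.integer(h), n_tokens = nn,
      percentage = 100 * as.numeric(h) / as.numeric(nn)
    )
  })
  dplyr::bind_rows(out)
}

#' Cohen's kappa for two raters over the same items
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with
#' observed agreement p_o and chance agreement p_e from the marginals of
#' the joint label contingency table.
#'
#' @param a,b Label vectors of equal length (any atomic type or factor).
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(c("x", "y", "x"), c("x", "y", "x"))  # 1
cohen_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L) {
    tdx_error("raters must label the same nonempty token set",
              "textdx_data_error")
  }
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1 - .Machine$double.eps^0.5) {
    tdx_error("kappa undefined: chance agreement is 1 (single category)",
              "textdx_data_error")
  }
  (po - pe) / (1 - pe)
}
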