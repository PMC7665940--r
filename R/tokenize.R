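#' Tokenize raw text word-by-word
#'
#' Splits text into word tokens (maximal runs of letters and internal
#' apostrophes after Unicode case folding; hyphenated forms split at the
#' hyphen) and, optionally, emoticon tokens. A whitespace-delimited chunk
#' that exactly matches a string in `emoticons` becomes a single emoticon
#' token; everything else contributes its alphabetic runs as word tokens.
#' Pure punctuation and whitespace produce no tokens.
#'
#' @param text A character scalar (any Unicode string; `NA` treated as "").
#' @param emoticons Character vector of emoticon strings to recognize.
#' @return A tibble with columns `position` (0-based token index), `surface`,
#'   `norm` (lowercased form; equal to `surface` for emoticons), `is_word`,
#'   `is_emoticon`.
#' @export
#' @examples
#' tokenize("I like you :)", emoticons = ":)")
tokenize <- function(text, emoticons = character()) {
  empty <- tibble::tibble(
    position = integer(), surface = character(), norm = character(),
    is_word = logical(), is_emoticon = logical()
  )
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(empty)
  chunks <- strsplit(text, "\\s+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) return(empty)

  is_emo <- chunks %in% emoticons
  surfaces <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    if (is_emo[i]) {
      surfaces[[i]] <- chunks[i]
    } else {
      m <- gregexpr("\\p{L}[\\p{L}']*", chunks[i], perl = TRUE)[[1]]
      surfaces[[i]] <- if (m[1] == -1L) character() else
        regmatches(chunks[i], list(m))[[1]]
    }
  }
  n_per <- lengths(surfaces)
  if (sum(n_per) == 0L) return(empty)
  surface <- unlist(surfaces, use.names = FALSE)
  emo_flag <- rep(is_emo, n_per)
  norm <- ifelse(emo_flag, surface, sub("'+$", "", tolower(surface)))
  keep <- emo_flag | nzchar(norm)
  surface <- surface[keep]; norm <- norm[keep]; emo_flag <- emo_flag[keep]
  tibble::tibble(
    position = seq_along(surface) - 1L,
    surface = surface,
    norm = norm,
    is_word = !emo_flag,
    is_emoticon = emo_flag
  )
}

#' Tokenize a corpus of participant texts
#'
#' @param texts A tibble with columns `participant_id`, `text` (one row per
#'   participant; multiple rows per participant are concatenated in order
#'   with a space).
#' @param emoticons Character vector of emoticon strings to recognize. When
#'   several lexicons with different emoticon inventories will be compared,
#'   pass the union so token positions are comparable across versions.
#' @return A token tibble with `participant_id` plus the [tokenize()]
#'   columns; positions are 0-based within each participant.
#' @export
tokenize_corpus <- function(texts, emoticons = character()) {
  stopifnot(all(c("participant_id", "text") %in% names(texts)))
  texts <- dplyr::summarise(
    dplyr::group_by(texts, .data$participant_id),
    text = paste(.data$text, collapse = " "), .groups = "drop"
  )
  out <- lapply(seq_len(nrow(texts)), function(i) {
    tk <- tokenize(texts$text[i], emoticons = emoticons)
    if (nrow(tk) == 0L) return(NULL)
    tibble::tibble(participant_id = texts$participant_id[i], tk)
  })
  dplyr::bind_rows(out)
}
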