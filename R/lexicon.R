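#' Construct a lexicon
#'
#' A lexicon maps word, stem, and emoticon entries to one or more emotion
#' categories arranged in a hierarchy, optionally with context rules that
#' make a word's category assignment depend on its neighbors (the classic
#' example is "like", which counts as positive emotion only when attributed
#' to a person or action: "I like", "they like", "will like").
#'
#' @param entries A data frame with columns `pattern` (lowercase string;
#'   emoticon patterns may contain punctuation), `is_stem` (logical; a stem
#'   matches any token having the pattern as a prefix), `categories` (a
#'   list-column of character vectors of category ids, or a single
#'   comma-separated string per row). `is_emoticon` is derived: any pattern
#'   containing characters other than letters and apostrophes.
#' @param categories Category table, see [emotion_hierarchy()].
#' @param context_rules A list of rules from [context_rule()].
#' @param version_tag Free-form label for the dictionary version.
#' @param count_emoticons_as_words Should emoticon tokens count toward the
#'   word-token denominator (and be taggable)? Emulates newer dictionary
#'   versions that include netspeak.
#' @return An object of class `textdx_lexicon`.
#' @export
#' @examples
#' lx <- lexicon(
#'   data.frame(pattern = c("cried", "happ*"), is_stem = c(FALSE, TRUE),
#'              categories = c("sad", "posemo")),
#'   version_tag = "mini"
#' )
#' match_token(lx, tokenize("she cried"), 1)
lexicon <- function(entries, categories = emotion_hierarchy(),
                    context_rules = list(), version_tag = "custom",
                    count_emoticons_as_words = FALSE) {
  validate_hierarchy(categories)
  entries <- tibble::as_tibble(entries)
  if (!"is_stem" %in% names(entries)) entries$is_stem <- FALSE
  star <- endsWith(entries$pattern, "*")   # "happ*" shorthand for a stem
  entries$pattern[star] <- sub("\\*$", "", entries$pattern[star])
  entries$is_stem <- entries$is_stem | star
  if (!is.list(entries$categories)) {
    entries$categories <- strsplit(as.character(entries$categories), ",\\s*")
  }
  if (nrow(entries) > 0L) {
    if (any(!nzchar(entries$pattern))) {
      tdx_error("empty entry pattern", "textdx_lexicon_error")
    }
    if (any(lengths(entries$categories) == 0L)) {
      tdx_error("entry with empty category set", "textdx_lexicon_error")
    }
    unknown <- setdiff(unique(unlist(entries$categories)), categories$id)
    if (length(unknown) > 0L) {
      tdx_error(paste0("entry references unknown category: ",
                       paste(unknown, collapse = ", ")),
                "textdx_lexicon_error")
    }
    if (anyDuplicated(entries[, c("pattern", "is_stem")])) {
      tdx_error("duplicate (pattern, is_stem) entry", "textdx_lexicon_error")
    }
  }
  entries$is_emoticon <- !grepl("^\\p{L}[\\p{L}']*$", entries$pattern,
                                perl = TRUE)
  entries <- entries[, c("pattern", "is_stem", "categories", "is_emoticon")]
  if (any(entries$is_emoticon & entries$is_stem)) {
    tdx_error("emoticon entries cannot be stems", "textdx_lexicon_error")
  }
  for (r in context_rules) {
    unknown <- setdiff(r$grant, categories$id)
    if (length(unknown) > 0L) {
      tdx_error(paste0("context rule references unknown category: ",
                       paste(unknown, collapse = ", ")),
                "textdx_lexicon_error")
    }
  }
  structure(
    list(version_tag = version_tag, categories = categories,
         entries = entries, context_rules = context_rules,
         count_emoticons_as_words = count_emoticons_as_words),
    class = "textdx_lexicon"
  )
}

#' @export
print.textdx_lexicon <- function(x, ...) {
  cat("<textdx_lexicon> version:", x$version_tag, "\n",
      nrow(x$entries), "entries (",
      sum(x$entries$is_stem), "stems,",
      sum(x$entries$is_emoticon), "emoticons ),",
      length(x$context_rules), "context rules\n")
  invisible(x)
}

#' Context rule for a target word
#'
#' The rule grants categories to `target` when one of `words` appears among
#' the `window` normalized tokens immediately preceding it. Missing
#' neighbors at a document boundary never satisfy the condition. When
#' `suppress_default` is `TRUE`, the target receives no categories from
#' ordinary entry lookup: it is tagged only when a rule fires.
#'
#' @param target Lowercase token the rule applies to.
#' @param words Character vector of normalized tokens that trigger the rule.
#' @param grant Category ids granted when the rule fires.
#' @param window How many preceding tokens to inspect (1 or 2).
#' @param suppress_default Disable ordinary entry lookup for `target`.
#' @return A list of class `textdx_context_rule`.
#' @export
context_rule <- function(target, words, grant, window = 1L,
                         suppress_default = TRUE) {
  stopifnot(window >= 1L, window <= 2L, nzchar(target), length(grant) > 0L)
  structure(
    list(target = target, words = words, grant = grant,
         window = as.integer(window), suppress_default = suppress_default),
    class = "textdx_context_rule"
  )
}

# Resolve the default (context-free) category set for one normalized token.
# Precedence: an exact entry beats all stems; among stems the longest
# pattern wins and contributes its full category set.
match_norm_default <- function(lexicon, norm, emoticon = FALSE) {
  e <- lexicon$entries
  if (nrow(e) == 0L) return(character())
  if (emoticon) {
    hit <- e$is_emoticon & e$pattern == norm
    if (!any(hit)) return(character())
    return(expand_categories(unique(unlist(e$categories[hit])),
                             lexicon$categories))
  }
  exact <- !e$is_stem & !e$is_emoticon & e$pattern == norm
  if (any(exact)) {
    return(expand_categories(unique(unlist(e$categories[exact])),
                             lexicon$categories))
  }
  stems <- which(e$is_stem & startsWith(norm, e$pattern))
  if (length(stems) == 0L) return(character())
  best <- stems[which.max(nchar(e$pattern[stems]))]
  expand_categories(e$categories[[best]], lexicon$categories)
}

# Category set for one norm given its (possibly missing) preceding norms.
match_norm <- function(lexicon, norm, prev = character(), emoticon = FALSE) {
  rules <- Filter(function(r) r$target == norm, lexicon$context_rules)
  granted <- character()
  suppress <- FALSE
  for (r in rules) {
    if (r$suppress_default) suppress <- TRUE
    ctx <- utils::head(prev, r$window)
    if (length(ctx) > 0L && any(ctx %in% r$words)) {
      granted <- c(granted, r$grant)
    }
  }
  if (!suppress) {
    granted <- c(granted, match_norm_default(lexicon, norm, emoticon))
  }
  expand_categories(unique(granted), lexicon$categories)
}

#' Match one token of a document against a lexicon
#'
#' Returns the union of matched entry categories expanded upward through
#' the hierarchy; context rules for the token's normalized form are
#' evaluated first and, when `suppress_default` is set, replace ordinary
#' entry lookup.
#'
#' @param lexicon A [lexicon()].
#' @param doc A token tibble for a single document (from [tokenize()]).
#' @param position 0-based token position.
#' @return Character vector of category ids, closed under parent expansion.
#' @export
match_token <- function(lexicon, doc, position) {
  i <- match(position, doc$position)
  if (is.na(i)) {
    tdx_error(paste0("no token at position ", position), "textdx_data_error")
  }
  prev <- doc$norm[doc$position %in% c(position - 1L, position - 2L)]
  prev <- rev(prev)  # nearest first
  match_norm(lexicon, doc$norm[i], prev, emoticon = doc$is_emoticon[i])
}

#' Tag every countable token of a corpus
#'
#' Applies [match_token()] semantics across all documents. Word tokens are
#' always countable; emoticon tokens are countable only when the lexicon
#' sets `count_emoticons_as_words`. Non-countable tokens receive an empty
#' category set and `countable = FALSE`.
#'
#' @param lexicon A [lexicon()].
#' @param docs Token tibble with `participant_id` (from [tokenize_corpus()]).
#' @return The token tibble with added columns `countable` (logical) and
#'   `categories` (list-column of category-id character vectors).
#' @export
tag_corpus <- function(lexicon, docs) {
  if (nrow(docs) == 0L) {
    tdx_error("empty document collection", "textdx_data_error")
  }
  docs <- dplyr::arrange(docs, .data$participant_id, .data$position)
  countable <- docs$is_word |
    (docs$is_emoticon & lexicon$count_emoticons_as_words)

  cats <- rep(list(character()), nrow(docs))
  rule_targets <- vapply(lexicon$context_rules, `[[`, "", "target")

  # context-free tokens: resolve once per unique (norm, emoticon) pair
  free <- countable & !(docs$norm %in% rule_targets)
  key <- paste0(ifelse(docs$is_emoticon, "e:", "w:"), docs$norm)
  uk <- unique(key[free])
  if (length(uk) > 0L) {
    lut <- lapply(uk, function(k) {
      match_norm_default(lexicon, substring(k, 3L),
                         emoticon = startsWith(k, "e:"))
    })
    names(lut) <- uk
    cats[free] <- lut[key[free]]
  }

  # context-sensitive tokens need their neighbors
  dep <- which(countable & (docs$norm %in% rule_targets))
  if (length(dep) > 0L) {
    grp <- docs$participant_id
    prev1 <- ifelse(seq_len(nrow(docs)) > 1L &
                      grp == dplyr::lag(grp, default = grp[1]),
                    dplyr::lag(docs$norm), NA_character_)
    prev2 <- ifelse(seq_len(nrow(docs)) > 2L &
                      grp == dplyr::lag(grp, 2L, default = grp[1]),
                    dplyr::lag(docs$norm, 2L), NA_character_)
    for (i in dep) {
      prev <- c(prev1[i], prev2[i])
      prev <- prev[!is.na(prev)]
      cats[[i]] <- match_norm(lexicon, docs$norm[i], prev,
                              emoticon = docs$is_emoticon[i])
    }
  }
  docs$countable <- countable
  docs$categories <- cats
  docs
}

#' Per-participant category percentages
#'
#' The dictionary report format: for each participant and category,
#' 100 x (countable tokens carrying the category) / (countable tokens).
#'
#' @param tagged Output of [tag_corpus()].
#' @param categories Category table.
#' @return Long tibble: `participant_id`, `category`, `hits`, `n_tokens`,
#'   `percentage`.
#' @export
category_percentages <- function(tagged, categories = emotion_hierarchy()) {
  tg <- tagged[tagged$countable, ]
  n_by <- table(tg$participant_id)
  all_p <- unique(tagged$participant_id)
  empty <- setdiff(all_p, names(n_by))
  if (length(empty) > 0L) {
    tdx_error(paste0("participant with no countable tokens: ",
                     paste(empty, collapse = ", ")),
              "textdx_data_error", participants = empty)
  }
  hit_mat <- category_matrix(tg$categories, categories$id)
  out <- lapply(categories$id, function(cid) {
    h <- tapply(hit_mat[, cid], tg$participant_id, sum)
    nn <- as.integer(n_by[names(h)])
    tibble::tibble(
      participant_id = names(h),
      category = cid,
      hits = as.integer(h),
      n_tokens = nn,
      percentage = 100 * as.numeric(h) / as.numeric(nn)
    )
  })
  dplyr::bind_rows(out)
}

# list-of-charvec -> logical token x category matrix
category_matrix <- function(cat_list, ids) {
  m <- matrix(FALSE, nrow = length(cat_list), ncol = length(ids),
              dimnames = list(NULL, ids))
  lens <- lengths(cat_list)
  nz <- which(lens > 0L)
  if (length(nz) > 0L) {
    rows <- rep.int(nz, lens[nz])
    cols <- match(unlist(cat_list[nz], use.names = FALSE), ids)
    ok <- !is.na(cols)
    m[cbind(rows[ok], cols[ok])] <- TRUE
  }
  m
}

#' Summarize percentages across participants
#'
#' Unweighted mean and SD of per-participant percentages per category (the
#' usual dictionary-report summary row).
#'
#' @param pct Output of [category_percentages()].
#' @return Tibble: `category`, `mean_pct`, `sd_pct`, `n_participants`.
#' @export
summarize_percentages <- function(pct) {
  dplyr::summarise(
    dplyr::group_by(pct, .data$category),
    mean_pct = mean(.data$percentage),
    sd_pct = stats::sd(.data$percentage),
    n_participants = dplyr::n(),
    .groups = "drop"
  )
}
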