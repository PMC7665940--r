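# Shared fixtures and independent oracles, built in code at test time.

mini_lexicon <- function(count_emoticons_as_words = TRUE) {
  lexicon(
    data.frame(
      pattern = c("cried", "happy", "stammer*", "worr*", "furious", ":)"),
      categories = c("sad", "posemo", "negemo", "anx", "anger", "posemo")
    ),
    context_rules = list(
      context_rule("like", words = c("i", "they", "will"),
                   grant = "posemo", window = 1L, suppress_default = TRUE)
    ),
    version_tag = "mini-2015",
    count_emoticons_as_words = count_emoticons_as_words
  )
}

# Brute-force scanner: tests every entry against a token by direct
# equality / prefix comparison, then applies the documented precedence
# (exact beats stems; longest stem wins) and expands ancestors. Written
# independently of the engine's lookup-table path.
brute_force_match <- function(lx, norm, is_emoticon = FALSE) {
  hits_exact <- character()
  stem_hits <- list()
  for (i in seq_len(nrow(lx$entries))) {
    e_pat <- lx$entries$pattern[i]
    e_stem <- lx$entries$is_stem[i]
    e_emo <- lx$entries$is_emoticon[i]
    if (is_emoticon) {
      if (e_emo && e_pat == norm) {
        hits_exact <- c(hits_exact, lx$entries$categories[[i]])
      }
    } else if (!e_emo) {
      if (!e_stem && e_pat == norm) {
        hits_exact <- c(hits_exact, lx$entries$categories[[i]])
      } else if (e_stem && substr(norm, 1, nchar(e_pat)) == e_pat) {
        stem_hits[[length(stem_hits) + 1L]] <-
          list(pat = e_pat, cats = lx$entries$categories[[i]])
      }
    }
  }
  cats <- if (length(hits_exact) > 0L) {
    hits_exact
  } else if (length(stem_hits) > 0L) {
    lens <- vapply(stem_hits, function(h) nchar(h$pat), 0L)
    stem_hits[[which.max(lens)]]$cats
  } else character()
  expand_categories(unique(cats), lx$categories)
}

# Random entry-only mini-lexicon over a pseudo-word alphabet.
random_lexicon <- function(n_entries = 20L) {
  syll <- c("ba", "be", "bo", "da", "de", "do", "ka", "ke", "ko",
            "la", "le", "lo", "ma", "me", "mo", "na", "ne", "no")
  word <- function() paste(sample(syll, sample(2:4, 1), replace = TRUE),
                           collapse = "")
  pats <- unique(replicate(n_entries, word()))
  is_stem <- stats::runif(length(pats)) < 0.4
  cats <- lapply(seq_along(pats), function(i) {
    sample(emotion_hierarchy()$id, sample(1:2, 1))
  })
  # drop duplicate (pattern, is_stem) combos after stem truncation
  pats[is_stem] <- substr(pats[is_stem], 1, pmax(2, nchar(pats[is_stem]) - 2))
  keep <- !duplicated(paste(pats, is_stem))
  lexicon(tibble::tibble(pattern = pats[keep], is_stem = is_stem[keep],
                         categories = cats[keep]),
          version_tag = "random")
}

random_document <- function(n_tokens = 200L) {
  syll <- c("ba", "be", "bo", "da", "de", "do", "ka", "ke", "ko",
            "la", "le", "lo", "ma", "me", "mo", "na", "ne", "no", "zu")
  norms <- replicate(n_tokens, paste(
    sample(syll, sample(2:5, 1), replace = TRUE), collapse = ""))
  tibble::tibble(position = seq_len(n_tokens) - 1L, surface = norms,
                 norm = norms, is_word = TRUE, is_emoticon = FALSE)
}

# small deterministic aligned fixture from explicit sets
aligned_from_sets <- function(ref_sets, pred_sets) {
  n <- length(ref_sets)
  h <- emotion_hierarchy()
  tagged <- tibble::tibble(
    participant_id = "p1", position = seq_len(n) - 1L,
    surface = paste0("w", seq_len(n)), norm = paste0("w", seq_len(n)),
    is_word = TRUE, is_emoticon = FALSE, countable = TRUE,
    categories = lapply(pred_sets, expand_categories)
  )
  sub_for <- c(posemo = "positive-feelings", anx = "anxiety",
               anger = "anger", sad = "sadness", negemo = "other-negative")
  ref_rows <- which(lengths(ref_sets) > 0)
  reference <- tibble::tibble(
    participant_id = "p1",
    position = as.integer(ref_rows - 1L),
    surface = paste0("w", ref_rows),
    subcategory = vapply(ref_sets[ref_rows], function(s) {
      leaf <- setdiff(s, c("affect"))
      leaf <- if (length(leaf) == 0) "posemo" else leaf[length(leaf)]
      sub_for[[leaf]]
    }, "")
  )
  align(reference, tagged, h)
}
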