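test_that("tokenizer splits words, emoticons and hyphenated forms", {
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("  ,. !! ")), 0L)

  tk <- tokenize("I like you :)", emoticons = ":)")
  expect_equal(tk$norm, c("i", "like", "you", ":)"))
  expect_equal(tk$is_emoticon, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tk$position, 0:3)

  tk <- tokenize("stammered, stammering.")
  expect_equal(tk$norm, c("stammered", "stammering"))

  # hyphenated forms split; apostrophes internal to words survive
  tk <- tokenize("self-doubt isn't easy")
  expect_equal(tk$norm, c("self", "doubt", "isn't", "easy"))

  # without the emoticon inventory, ":)" yields no token
  expect_equal(nrow(tokenize(":)")), 0L)
})

test_that("matching expands hits upward through the hierarchy", {
  lx <- mini_lexicon()
  doc <- tokenize("she cried loudly")
  expect_equal(match_token(lx, doc, 1), c("affect", "negemo", "sad"))
  expect_equal(match_token(lx, doc, 0), character())

  # stems match extended forms and expand from their own level
  doc2 <- tokenize("he stammered and stammers")
  expect_equal(match_token(lx, doc2, 1), c("affect", "negemo"))
  expect_equal(match_token(lx, doc2, 3), c("affect", "negemo"))
})

test_that("context rule tags 'like' only when attributed to person/action", {
  lx <- mini_lexicon()
  doc <- tokenize("I like it")
  expect_equal(match_token(lx, doc, 1), c("affect", "posemo"))
  doc2 <- tokenize("it looks like rain")
  expect_equal(match_token(lx, doc2, 2), character())
  doc3 <- tokenize("they will like it")
  expect_equal(match_token(lx, doc3, 2), c("affect", "posemo"))
  # document-initial target: missing neighbors never satisfy the rule
  doc4 <- tokenize("like it")
  expect_equal(match_token(lx, doc4, 0), character())
})

test_that("exact entries override stems; longest stem wins", {
  lx <- lexicon(tibble::tibble(
    pattern = c("worried", "worr", "worrie"),
    is_stem = c(FALSE, TRUE, TRUE),
    categories = list("posemo", "anx", "sad")
  ))
  doc <- tokenize("worried worrying worrier")
  # exact beats both stems
  expect_equal(match_token(lx, doc, 0), c("affect", "posemo"))
  # longest applicable stem wins: "worrie" over "worr"
  expect_equal(match_token(lx, doc, 2), c("affect", "negemo", "sad"))
  # only the shorter stem applies
  expect_equal(match_token(lx, doc, 1), c("affect", "anx", "negemo"))
})

test_that("tagging is deterministic and counts countable tokens", {
  lx <- mini_lexicon()
  docs <- tokenize_corpus(
    tibble::tibble(participant_id = c("a", "b"),
                   text = c("I like it :) but she cried",
                            "nothing emotional here at all")),
    emoticons = ":)")
  t1 <- tag_corpus(lx, docs)
  t2 <- tag_corpus(lx, docs)
  expect_identical(t1, t2)
  expect_true(all(lengths(t2$categories[t2$participant_id == "b"]) == 0))
  # emoticon countable because the lexicon counts emoticons as words
  expect_true(all(t1$countable))

  lx_no <- mini_lexicon(count_emoticons_as_words = FALSE)
  t3 <- tag_corpus(lx_no, docs)
  expect_false(t3$countable[t3$is_emoticon][1])
  expect_length(t3$categories[t3$is_emoticon][[1]], 0)
})

test_that("per-participant percentages have the dictionary-report semantics", {
  h <- emotion_hierarchy()
  lx <- mini_lexicon()
  text <- paste(c("cried", rep("neutral", 99)), collapse = " ")
  docs <- tokenize_corpus(tibble::tibble(participant_id = "p", text = text))
  pct <- category_percentages(tag_corpus(lx, docs), h)
  expect_equal(pct$percentage[pct$category == "sad"], 1.0)
  expect_equal(pct$percentage[pct$category == "affect"], 1.0)
  expect_equal(pct$percentage[pct$category == "posemo"], 0.0)
  expect_equal(unique(pct$n_tokens), 100L)

  # all-hit corpus saturates at 100
  docs2 <- tokenize_corpus(tibble::tibble(participant_id = "p",
                                          text = "cried cried cried"))
  pct2 <- category_percentages(tag_corpus(lx, docs2), h)
  expect_equal(pct2$percentage[pct2$category == "sad"], 100)

  # child never exceeds parent, all within [0, 100]
  wide <- tidyr::pivot_wider(pct[, c("participant_id", "category", "percentage")],
                             names_from = "category",
                             values_from = "percentage")
  expect_true(all(wide$sad <= wide$negemo & wide$negemo <= wide$affect))
  expect_true(all(pct$percentage >= 0 & pct$percentage <= 100))
})

test_that("malformed lexicons are rejected", {
  expect_error(lexicon(tibble::tibble(pattern = "x", categories = list("nope"))),
               class = "textdx_lexicon_error")
  expect_error(lexicon(tibble::tibble(pattern = "", categories = list("sad"))),
               class = "textdx_lexicon_error")
  expect_error(
    lexicon(tibble::tibble(pattern = c("a", "a"), is_stem = FALSE,
                           categories = list("sad", "anx"))),
    class = "textdx_lexicon_error")
  bad_h <- tibble::tibble(id = c("a", "b"), name = c("a", "b"),
                          parent = c("b", "a"))
  expect_error(validate_hierarchy(bad_h), class = "textdx_lexicon_error")
})

test_that("engine agrees with a brute-force entry scanner on random inputs", {
  withr::local_seed(421)
  for (rep in 1:30) {
    lx <- random_lexicon(sample(5:50, 1))
    doc <- random_document(sample(50:200, 1))
    tagged <- tag_corpus(lx, doc |>
                           dplyr::mutate(participant_id = "p", .before = 1))
    expected <- lapply(doc$norm, function(nm) brute_force_match(lx, nm))
    expect_identical(tagged$categories, expected)
  }
})

test_that("counts respect hierarchy conservation and entry monotonicity", {
  withr::local_seed(99)
  h <- emotion_hierarchy()
  for (rep in 1:10) {
    lx <- random_lexicon(25)
    doc <- dplyr::mutate(random_document(150), participant_id = "p",
                         .before = 1)
    pct <- category_percentages(tag_corpus(lx, doc), h)
    counts <- stats::setNames(pct$hits, pct$category)
    for (i in which(!is.na(h$parent))) {
      expect_lte(counts[[h$id[i]]], counts[[h$parent[i]]])
    }
    # adding an entry never decreases any count
    extra <- tibble::tibble(pattern = substr(doc$norm[1], 1, 2),
                            is_stem = TRUE, categories = list("anger"))
    if (!any(lx$entries$pattern == extra$pattern & lx$entries$is_stem)) {
      lx2 <- lexicon(rbind(lx$entries[, c("pattern", "is_stem", "categories")],
                           extra), version_tag = "random+1")
      pct2 <- category_percentages(tag_corpus(lx2, doc), h)
      counts2 <- stats::setNames(pct2$hits, pct2$category)
      expect_true(all(counts2[names(counts)] >= counts))
    }
  }
})

test_that("percentages signal a participant with no countable tokens", {
  lx <- mini_lexicon(count_emoticons_as_words = FALSE)
  docs <- tibble::tibble(participant_id = "p", position = 0L,
                         surface = ":)", norm = ":)",
                         is_word = FALSE, is_emoticon = TRUE)
  expect_error(category_percentages(tag_corpus(lx, docs)),
               class = "textdx_data_error")
})

test_that("dictionary files round-trip exactly and fail with line numbers", {
  lx <- mini_lexicon()
  path <- withr::local_tempfile(fileext = ".dic")
  write_lexicon(lx, path)
  lx2 <- read_lexicon(path)
  expect_identical(lx$entries, lx2$entries)
  expect_identical(lx$categories, lx2$categories)
  expect_identical(lx$context_rules, lx2$context_rules)
  expect_identical(lx$version_tag, lx2$version_tag)
  expect_identical(lx$count_emoticons_as_words, lx2$count_emoticons_as_words)

  # stem entry grammar
  txt <- c("version: t", "%", "negemo\tNegative emotion\t-", "%",
           "stammer* negemo")
  path2 <- withr::local_tempfile(lines = txt)
  lx3 <- read_lexicon(path2)
  expect_true(lx3$entries$is_stem[1])
  expect_equal(lx3$entries$pattern[1], "stammer")
  expect_equal(lx3$entries$categories[[1]], "negemo")

  # unknown category must name the offending line
  bad <- c("version: t", "%", "negemo\tNegative emotion\t-", "%",
           "oops nosuchcat")
  path3 <- withr::local_tempfile(lines = bad)
  err <- expect_error(read_lexicon(path3), class = "textdx_parse_error")
  expect_match(conditionMessage(err), ":5:")

  # duplicate entries rejected
  dup <- c("version: t", "%", "negemo\tNegative emotion\t-", "%",
           "sad negemo", "sad negemo")
  path4 <- withr::local_tempfile(lines = dup)
  expect_error(read_lexicon(path4), class = "textdx_parse_error")
})
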