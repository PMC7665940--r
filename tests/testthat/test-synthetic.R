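test_that("generator config validates prevalence structure", {
  expect_s3_class(generator_config(), "textdx_genconfig")
  expect_error(
    generator_config(prevalence = c(affect = 0.018, posemo = 0.009,
                                    negemo = 0.009, anx = 0.02,
                                    anger = 0.001, sad = 0.002)),
    class = "textdx_config_error")
  expect_error(
    generator_config(prevalence = c(affect = 0.5, posemo = 0.009,
                                    negemo = 0.009, anx = 0.003,
                                    anger = 0.001, sad = 0.002)),
    class = "textdx_config_error")
})

test_that("same seed gives identical corpora; prevalence edges behave", {
  cfg <- generator_config(seed = 42, n_participants = 4,
                          tokens_per_participant = 300)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$docs, s2$docs)
  expect_identical(s1$reference, s2$reference)

  zero <- generator_config(seed = 1, n_participants = 2,
                           tokens_per_participant = 50,
                           prevalence = c(affect = 0, posemo = 0, negemo = 0,
                                          anx = 0, anger = 0, sad = 0))
  expect_equal(nrow(generate_corpus(zero)$reference), 0L)

  all_emo <- generator_config(seed = 1, n_participants = 2,
                              tokens_per_participant = 50,
                              prevalence = c(affect = 1, posemo = 0.5,
                                             negemo = 0.5, anx = 0.2,
                                             anger = 0.1, sad = 0.1))
  expect_equal(nrow(generate_corpus(all_emo)$reference), 100L)
})

test_that("realized prevalence sits within binomial bounds of the dial", {
  cfg <- generator_config(seed = 9)
  syn <- generate_corpus(cfg)
  n <- nrow(syn$docs)
  expect_equal(n, 63L * 2631L)
  p <- cfg$prevalence[["affect"]]
  realized <- nrow(syn$reference) / n
  expect_lt(abs(realized - p), 3 * sqrt(p * (1 - p) / n))
  # structural invariants hold by construction
  expect_true(all(syn$docs$is_word))
  expect_false(anyDuplicated(
    syn$reference[, c("participant_id", "position")]) > 0)
})

test_that("predictions hit the dialed operating points and stay closed", {
  cfg <- generator_config(seed = 5, n_participants = 20,
                          tokens_per_participant = 2000)
  syn <- generate_corpus(cfg)
  ops <- operating_points_published("2001")

  pr <- generate_predictions(syn, ops, seed = 77, build_tagged = FALSE)
  h <- emotion_hierarchy()
  for (i in which(!is.na(h$parent))) {
    expect_true(all(!pr$pred[, h$id[i]] | pr$pred[, h$parent[i]]))
  }
  # realized counts match the assignment log by definition of the log,
  # and sens/spec land near the dial
  al <- as_aligned(pr)
  for (cid in c("affect", "negemo")) {
    cc <- confusion(al, cid)
    expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                     unclass(pr$truth[[cid]])[c("tp", "fp", "fn", "tn")])
    o <- ops[ops$category == cid, ]
    expect_lt(abs(sensitivity(cc)$value - o$sens), 0.06)
    expect_lt(abs(specificity(cc)$value - o$spec), 0.01)
  }

  # degenerate operating points
  perfect <- tibble::tibble(category = h$id, sens = 1, spec = 1)
  pp <- generate_predictions(syn, perfect, seed = 1, build_tagged = FALSE)
  expect_identical(pp$pred, pp$ref)
  blind <- tibble::tibble(category = h$id, sens = 0, spec = 1)
  pb <- generate_predictions(syn, blind, seed = 1, build_tagged = FALSE)
  expect_equal(sum(pb$pred), 0L)
})

test_that("unrealizable operating points are rejected", {
  cfg <- generator_config(seed = 2, n_participants = 5,
                          tokens_per_participant = 500)
  syn <- generate_corpus(cfg)
  h <- emotion_hierarchy()
  # children detect nearly everything but the parent is dialed very low:
  # closure cannot average down to it
  ops <- tibble::tibble(category = h$id,
                        sens = c(0.05, 0.99, 0.99, 0.9, 0.9, 0.9),
                        spec = c(0.99, 0.97, 0.97, 0.99, 0.99, 0.99))
  expect_error(generate_predictions(syn, ops, seed = 1),
               class = "textdx_config_error")
})

test_that("operating points converge at large n (law of large numbers)", {
  cfg <- generator_config(seed = 31, n_participants = 10,
                          tokens_per_participant = 100000L,
                          prevalence = c(affect = 0.1, posemo = 0.05,
                                         negemo = 0.05, anx = 0.02,
                                         anger = 0.01, sad = 0.01))
  syn <- generate_corpus(cfg)
  ops <- operating_points_published("2015")
  pr <- generate_predictions(syn, ops, seed = 8, build_tagged = FALSE)
  al <- as_aligned(pr)
  cc <- confusion(al, "affect")
  o <- ops[ops$category == "affect", ]
  expect_lt(abs(sensitivity(cc)$value - o$sens), 0.002)
  expect_lt(abs(specificity(cc)$value - o$spec), 0.002)
})

test_that("lexicon fixtures reproduce their planted confusion log", {
  h <- emotion_hierarchy()
  for (seed in 1:20) {
    fx <- generate_lexicon(seed)
    tagged <- tag_corpus(fx$lexicon, fx$docs)
    al <- align(fx$reference, tagged, h)
    for (cid in h$id) {
      cc <- confusion(al, cid)
      expect_identical(unclass(cc)[c("tp", "fp", "fn", "tn")],
                       unclass(fx$truth[[cid]])[c("tp", "fp", "fn", "tn")],
                       label = paste("seed", seed, cid))
    }
  }
  # the stem trap plants a false positive for sadness
  fx <- generate_lexicon(4)
  expect_gte(fx$truth[["sad"]]$fp, 1L)
})

test_that("synthetic TSVs re-enter the pipeline unchanged", {
  cfg <- generator_config(seed = 12, n_participants = 3,
                          tokens_per_participant = 400)
  syn <- generate_corpus(cfg)
  dir <- withr::local_tempdir()
  write_synthetic(syn, dir)
  ref <- read_reference(file.path(dir, "reference.tsv"))
  expect_equal(as.data.frame(ref), as.data.frame(syn$reference))
  corpus <- read_corpus(file.path(dir, "corpus.tsv"))
  expect_equal(nrow(corpus), 3L)
  # re-tokenizing reproduces the generator's token stream
  docs2 <- tokenize_corpus(corpus)
  expect_equal(docs2$norm, syn$docs$norm)
  expect_equal(docs2$position, syn$docs$position)
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 12L)
})
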