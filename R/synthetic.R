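#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the scale and emotion prevalence of a token-level
#' human-coded online support-group corpus: 63 participants, 2,631 words
#' each (165,753 words in total), with human-coder prevalences of 1.8%
#' total affect, 0.9% positive and negative emotion, 0.3% anxiety, 0.1%
#' anger and 0.2% sadness. Each token independently receives one human
#' subcategory (the single-label coding scheme); subcategories partition
#' their parent's probability mass, so total affect must equal positive +
#' negative and the specific negative subcategories must not exceed the
#' negative mass (the residual is "other-negative"). The positive mass is
#' split equally across the three positive subcategories.
#'
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @param n_participants Number of participants.
#' @param tokens_per_participant Words per participant (uniform).
#' @param prevalence Named numeric: per-category proportion of words, names
#'   `affect`, `posemo`, `negemo`, `anx`, `anger`, `sad`.
#' @param positive_split Proportions (summing to 1) splitting the positive
#'   mass across positive-feelings, optimism, other-positive.
#' @param heterogeneity Optional beta-distribution precision for
#'   participant-level prevalence effects (`NULL`, the default, disables
#'   them: every participant shares the same prevalences).
#' @param emotion_vocab_size,neutral_vocab_size Pseudo-word vocabulary
#'   sizes per emotion subcategory and for neutral words.
#' @return A list of class `textdx_genconfig`.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 63L,
                             tokens_per_participant = 2631L,
                             prevalence = c(affect = 0.018, posemo = 0.009,
                                            negemo = 0.009, anx = 0.003,
                                            anger = 0.001, sad = 0.002),
                             positive_split = c("positive-feelings" = 1 / 3,
                                                "optimism" = 1 / 3,
                                                "other-positive" = 1 / 3),
                             heterogeneity = NULL,
                             emotion_vocab_size = 40L,
                             neutral_vocab_size = 400L) {
  need <- c("affect", "posemo", "negemo", "anx", "anger", "sad")
  if (!all(need %in% names(prevalence))) {
    tdx_error(paste0("prevalence must name: ", paste(need, collapse = ", ")),
              "textdx_config_error")
  }
  pv <- prevalence[need]
  if (any(pv < 0) || any(pv > 1)) {
    tdx_error("prevalences must lie in [0, 1]", "textdx_config_error")
  }
  if (pv[["anx"]] + pv[["anger"]] + pv[["sad"]] > pv[["negemo"]] + 1e-12) {
    tdx_error("child prevalences exceed negative-emotion prevalence",
              "textdx_config_error")
  }
  if (abs(pv[["posemo"]] + pv[["negemo"]] - pv[["affect"]]) > 1e-12) {
    tdx_error(
      "affect prevalence must equal positive + negative prevalence (the human scheme has no affect-only label)",
      "textdx_config_error")
  }
  if (abs(sum(positive_split) - 1) > 1e-9) {
    tdx_error("positive_split must sum to 1", "textdx_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         tokens_per_participant = as.integer(tokens_per_participant),
         prevalence = pv, positive_split = positive_split,
         heterogeneity = heterogeneity,
         emotion_vocab_size = as.integer(emotion_vocab_size),
         neutral_vocab_size = as.integer(neutral_vocab_size)),
    class = "textdx_genconfig"
  )
}

# subcategory probabilities implied by a config's category prevalences
subcategory_probs <- function(config) {
  pv <- config$prevalence
  pos <- pv[["posemo"]] * config$positive_split
  neg <- c(anxiety = pv[["anx"]], anger = pv[["anger"]], sadness = pv[["sad"]],
           "other-negative" = pv[["negemo"]] -
             (pv[["anx"]] + pv[["anger"]] + pv[["sad"]]))
  p <- c(pos, neg)
  c(p, "not-emotion" = 1 - sum(p))
}

make_vocab <- function(prefix, n) {
  g <- expand.grid(letters, letters, letters, stringsAsFactors = FALSE)
  pool <- paste0(g[[1]], g[[2]], g[[3]])
  paste0(prefix, pool[seq_len(n)])
}

#' Generate a synthetic corpus with known token-level ground truth
#'
#' Each token independently draws a human subcategory at the configured
#' prevalence; emotion tokens take surfaces from a subcategory-specific
#' pseudo-word vocabulary disjoint from the neutral vocabulary, so lexicon
#' behavior can be tested without natural-language confounds. Deterministic
#' given the config seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `textdx_synthetic`: `docs` (token tibble as from
#'   [tokenize_corpus()], all word tokens), `reference` (label tibble,
#'   not-emotion tokens omitted), `truth` (realized per-subcategory and
#'   per-category counts), `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "textdx_genconfig"))
  probs <- subcategory_probs(config)
  subcats <- names(probs)
  n_p <- config$n_participants
  npt <- config$tokens_per_participant
  n <- n_p * npt
  pid <- rep(sprintf("p%03d", seq_len(n_p)), each = npt)

  vocabs <- c(
    lapply(stats::setNames(nm = setdiff(subcats, "not-emotion")), function(s) {
      make_vocab(paste0("em", gsub("-", "", s)), config$emotion_vocab_size)
    }),
    list("not-emotion" = make_vocab("neu", config$neutral_vocab_size))
  )

  withr::local_seed(config$seed)
  if (!is.null(config$heterogeneity) && config$heterogeneity > 0) {
    # participant-level affect multiplier from a beta with mean prevalence
    base <- config$prevalence[["affect"]]
    kappa <- config$heterogeneity
    p_aff <- stats::rbeta(n_p, base * kappa, (1 - base) * kappa)
    mult <- rep(p_aff / base, each = npt)
    draw <- integer(n)
    emo_p <- probs[subcats != "not-emotion"]
    scaled <- outer(mult, emo_p)  # n x 7
    scaled <- pmin(scaled, 1)
    u <- stats::runif(n)
    cum <- t(apply(scaled, 1, cumsum))
    draw <- rowSums(u > cum) + 1L  # index into emo subcats, 8 = not-emotion
    sub <- c(names(emo_p), "not-emotion")[pmin(draw, length(emo_p) + 1L)]
  } else {
    sub <- sample(subcats, n, replace = TRUE, prob = probs)
  }
  surf_idx <- sample.int(config$neutral_vocab_size, n, replace = TRUE)
  surface <- vocabs[["not-emotion"]][surf_idx]
  emo <- sub != "not-emotion"
  if (any(emo)) {
    ei <- sample.int(config$emotion_vocab_size, sum(emo), replace = TRUE)
    sub_emo <- sub[emo]
    repl <- character(sum(emo))
    for (s in unique(sub_emo)) {
      k <- sub_emo == s
      repl[k] <- vocabs[[s]][ei[k]]
    }
    surface[emo] <- repl
  }
  docs <- tibble::tibble(
    participant_id = pid,
    position = rep(seq_len(npt) - 1L, times = n_p),
    surface = surface, norm = surface,
    is_word = TRUE, is_emoticon = FALSE
  )
  reference <- tibble::tibble(
    participant_id = pid[emo],
    position = docs$position[emo],
    surface = surface[emo],
    subcategory = sub[emo]
  )
  truth <- list(
    subcategory_counts = table(factor(sub, levels = subcats)),
    n_tokens = n,
    vocabs = vocabs
  )
  structure(list(docs = docs, reference = reference, truth = truth,
                 config = config),
            class = "textdx_synthetic")
}

#' Built-in emulated tagger operating points
#'
#' Per-category sensitivity/specificity operating points representative of
#' the three published LIWC validation generations ("2001", "2007",
#' "2015"), used to parameterize synthetic taggers.
#'
#' @param version One of "2001", "2007", "2015".
#' @return Tibble: `category`, `sens`, `spec`.
#' @export
operating_points_published <- function(version = c("2001", "2007", "2015")) {
  version <- match.arg(version)
  ops <- list(
    "2001" = cbind(sens = c(0.858, 0.873, 0.822, 0.862, 0.663, 0.699),
                   spec = c(0.967, 0.976, 0.990, 0.998, 0.998, 0.997)),
    "2007" = cbind(sens = c(0.896, 0.913, 0.814, 0.892, 0.679, 0.718),
                   spec = c(0.955, 0.967, 0.987, 0.997, 0.998, 0.997)),
    "2015" = cbind(sens = c(0.904, 0.928, 0.810, 0.883, 0.695, 0.856),
                   spec = c(0.955, 0.967, 0.988, 0.997, 0.999, 0.997))
  )
  m <- ops[[version]]
  tibble::tibble(category = emotion_hierarchy()$id,
                 sens = m[, "sens"], spec = m[, "spec"])
}

check_operating_points <- function(ops, categories) {
  need <- categories$id
  if (!all(need %in% ops$category)) {
    tdx_error("operating points must cover every category",
              "textdx_config_error")
  }
  if (any(ops$sens < 0 | ops$sens > 1 | ops$spec < 0 | ops$spec > 1)) {
    tdx_error("operating points must lie in [0, 1]^2", "textdx_config_error")
  }
  invisible(ops)
}

# Weighted water-filling: thresholds pmax(L, b) with class weights w such
# that sum(w * thr) = t * sum(w). Monotone in b, so solved by uniroot.
solve_waterfill <- function(L, w, t) {
  W <- sum(w)
  if (W == 0) return(pmax(L, t))
  if (sum(w * L) > t * W + 1e-9) return(NULL)  # infeasible
  g <- function(b) sum(w * pmax(L, b)) - t * W
  if (g(0) >= 0) return(L)
  b <- stats::uniroot(g, c(0, 1), tol = 1e-12)$root
  pmax(L, b)
}

# Per-(category, reference-class) positive-prediction thresholds that (a)
# are monotone up the hierarchy, so a single uniform per token yields
# hierarchy-closed predicted sets, and (b) average, with the realized
# class counts as weights, to sens over reference-positive classes and to
# 1-spec over reference-negative classes, so every configured marginal is
# met exactly in expectation. A parent whose configured sensitivity is
# below the weighted mean of its children's detection rates is
# unrealizable under closure and signals a config error.
class_thresholds <- function(ops, class_weights, categories) {
  classes <- names(class_weights)
  pos <- vapply(rollup(classes, categories), function(set) {
    stats::setNames(categories$id %in% set, categories$id)
  }, logical(nrow(categories)))  # category x class
  colnames(pos) <- classes
  s <- stats::setNames(ops$sens, ops$category)
  fp <- stats::setNames(1 - ops$spec, ops$category)
  thr <- matrix(0, nrow(categories), length(classes),
                dimnames = list(categories$id, classes))
  # children before parents: walk ids in reverse-topological order
  depth <- vapply(categories$id, function(id) {
    length(category_ancestors(id, categories))
  }, 0L)
  for (cid in categories$id[order(depth, decreasing = TRUE)]) {
    kids <- categories$id[!is.na(categories$parent) &
                            categories$parent == cid]
    L <- if (length(kids) == 0L) rep(0, length(classes))
         else apply(thr[kids, , drop = FALSE], 2, max)
    for (side in c(TRUE, FALSE)) {
      k <- pos[cid, ] == side
      t_target <- if (side) s[[cid]] else fp[[cid]]
      sol <- solve_waterfill(L[k], class_weights[k], t_target)
      if (is.null(sol)) {
        tdx_error(
          paste0("operating points are hierarchy-incompatible at '", cid,
                 "': children imply a ",
                 if (side) "sensitivity" else "false-positive rate",
                 " above the configured value"),
          "textdx_config_error")
      }
      thr[cid, k] <- sol
    }
  }
  thr
}

#' Generate machine predictions at a dialed-in operating point
#'
#' For every category, a reference-positive token is predicted positive
#' with probability `sens` and a reference-negative token with probability
#' `1 - spec`, independently across tokens. Within a token, all category
#' draws share one uniform, with per-category thresholds that depend on
#' the token's reference subcategory and are solved bottom-up so that (a)
#' a predicted subcategory always implies its ancestors (hierarchy
#' closure) and (b) every configured per-category marginal is met exactly
#' in expectation given the realized subcategory counts. Operating points
#' that closure makes unrealizable (e.g. a parent sensitivity below the
#' weighted mean of its children's) signal a configuration error.
#'
#' @param synthetic A [generate_corpus()] result (or any `textdx_aligned`-
#'   compatible reference: a label tibble plus docs).
#' @param operating_points Tibble `category`, `sens`, `spec` covering every
#'   category (see [operating_points_published()]).
#' @param seed Integer seed for the prediction draws.
#' @param categories Category table.
#' @param build_tagged Build the per-token `tagged` tibble with a
#'   list-column of category sets (needed to feed [run_validation()];
#'   skipping it is faster when only [as_aligned()] metrics are wanted).
#' @return A list of class `textdx_predictions`: `tagged` (token tibble
#'   with `countable` and `categories` columns, directly usable as a tagger
#'   in [run_validation()]; `NULL` unless `build_tagged`), `truth`
#'   (per-category realized tp/fp/fn/tn assignment log), `pred`/`ref`
#'   (logical token x category matrices), `operating_points`, `seed`.
#' @export
generate_predictions <- function(synthetic, operating_points, seed = 1L,
                                 categories = emotion_hierarchy(),
                                 build_tagged = TRUE) {
  check_operating_points(operating_points, categories)
  docs <- synthetic$docs
  ref_sets <- rep(list(character()), nrow(docs))
  key_tok <- paste(docs$participant_id, docs$position)
  key_ref <- paste(synthetic$reference$participant_id,
                   synthetic$reference$position)
  ref_sets[match(key_ref, key_tok)] <-
    rollup(synthetic$reference$subcategory, categories)
  ref <- category_matrix(ref_sets, categories$id)
  cls <- rep("not-emotion", nrow(docs))
  cls[match(key_ref, key_tok)] <- synthetic$reference$subcategory

  w <- table(cls)
  thr <- class_thresholds(operating_points,
                          stats::setNames(as.numeric(w), names(w)),
                          categories)
  cls_i <- match(cls, colnames(thr))
  withr::local_seed(as.integer(seed))
  u <- stats::runif(nrow(docs))
  pred <- matrix(FALSE, nrow(docs), ncol(ref), dimnames = dimnames(ref))
  for (cid in categories$id) {
    pred[, cid] <- u < thr[cid, cls_i]
  }
  truth <- lapply(categories$id, function(cid) {
    confusion_counts(cid,
                     tp = sum(ref[, cid] & pred[, cid]),
                     fp = sum(!ref[, cid] & pred[, cid]),
                     fn = sum(ref[, cid] & !pred[, cid]),
                     tn = sum(!ref[, cid] & !pred[, cid]))
  })
  names(truth) <- categories$id
  tagged <- NULL
  if (build_tagged) {
    tagged <- docs
    tagged$countable <- TRUE
    ids <- categories$id
    tagged$categories <- apply(pred, 1, function(row) ids[row],
                               simplify = FALSE)
  }
  structure(list(tagged = tagged, truth = truth, pred = pred, ref = ref,
                 docs = docs, categories = categories,
                 operating_points = operating_points, seed = seed),
            class = "textdx_predictions")
}

#' Aligned corpus straight from synthetic predictions
#'
#' Wraps the reference/prediction matrices of a [generate_predictions()]
#' result as a `textdx_aligned` object without re-running tagging and
#' alignment; the matrices are identical to what [align()] would produce.
#'
#' @param predictions A `textdx_predictions` object.
#' @return A `textdx_aligned` object.
#' @export
as_aligned <- function(predictions) {
  stopifnot(inherits(predictions, "textdx_predictions"))
  docs <- predictions$docs
  structure(
    list(tokens = docs[, c("participant_id", "position", "surface", "norm")],
         ref = predictions$ref, pred = predictions$pred,
         categories = predictions$categories,
         participants = unique(docs$participant_id),
         total_tokens = nrow(docs)),
    class = "textdx_aligned"
  )
}

#' Generate a mini-lexicon plus a corpus realizing a planted confusion log
#'
#' Builds a small dictionary (exact entries, a stem entry, one context
#' rule, one emoticon) together with a paired corpus and reference
#' annotation constructed so that running the lexicon engine end-to-end
#' reproduces the planted per-category confusion counts exactly. Useful as
#' a self-checking end-to-end fixture.
#'
#' @param seed Integer seed controlling the planted counts.
#' @param n_exact Number of exact emotion entries.
#' @param categories Category table.
#' @return A list of class `textdx_lexfixture`: `lexicon`, `docs`,
#'   `reference`, `truth` (planted per-category confusion log).
#' @export
generate_lexicon <- function(seed = 1L, n_exact = 6L,
                             categories = emotion_hierarchy()) {
  withr::local_seed(as.integer(seed))
  leaves <- c("posemo", "anx", "anger", "sad", "negemo")
  entry_cats <- leaves[1 + (seq_len(n_exact) - 1L) %% length(leaves)]
  exact_words <- make_vocab("lex", n_exact)
  stem_root <- "grie"                    # grie* : "grieves" tp, "griddle" trap
  emoticon <- ":)"

  entries <- tibble::tibble(
    pattern = c(exact_words, stem_root, emoticon),
    is_stem = c(rep(FALSE, n_exact), TRUE, FALSE),
    categories = c(as.list(entry_cats), list("sad"), list("posemo"))
  )
  rules <- list(context_rule("like", words = c("i", "they", "will"),
                             grant = "posemo", window = 1L,
                             suppress_default = TRUE))
  lx <- lexicon(entries, categories = categories, context_rules = rules,
                version_tag = sprintf("mini-%d", seed),
                count_emoticons_as_words = TRUE)

  # map machine leaf category -> a human subcategory that rolls up to it
  sub_for <- c(posemo = "positive-feelings", anx = "anxiety",
               anger = "anger", sad = "sadness", negemo = "other-negative")
  words <- character(); subs <- character()
  plant <- function(w, s) {
    words <<- c(words, w); subs <<- c(subs, s)
  }
  # per exact entry: 1-3 true positives, 0-2 false positives
  for (j in seq_len(n_exact)) {
    for (k in seq_len(sample(3L, 1L))) plant(exact_words[j],
                                             sub_for[[entry_cats[j]]])
    for (k in seq_len(sample(3L, 1L) - 1L)) plant(exact_words[j],
                                                  "not-emotion")
  }
  plant("grieves", "sadness")      # stem tp (extended form)
  plant("griddle", "not-emotion")  # stem trap: planted fp for sad
  plant(":)", "positive-feelings") # emoticon tp
  plant("i", "not-emotion"); plant("like", "positive-feelings") # rule tp
  plant("rain", "not-emotion"); plant("like", "not-emotion")    # rule off: tn
  # false negatives: emotion words absent from the lexicon
  fn_words <- make_vocab("mis", 3L)
  plant(fn_words[1], "anxiety"); plant(fn_words[2], "sadness")
  plant(fn_words[3], "positive-feelings")
  # neutral filler
  neu <- make_vocab("pla", 20L)
  for (w in sample(neu, 30L, replace = TRUE)) plant(w, "not-emotion")

  n <- length(words)
  docs <- tibble::tibble(
    participant_id = "p001", position = seq_len(n) - 1L,
    surface = words, norm = words,
    is_word = words != emoticon, is_emoticon = words == emoticon
  )
  reference <- tibble::tibble(
    participant_id = "p001",
    position = docs$position[subs != "not-emotion"],
    surface = words[subs != "not-emotion"],
    subcategory = subs[subs != "not-emotion"]
  )

  # planted log: emulate the matcher's intended behavior analytically
  pred_sets <- vector("list", n)
  for (i in seq_len(n)) {
    w <- words[i]
    pred_sets[[i]] <-
      if (w %in% exact_words) {
        expand_categories(entry_cats[match(w, exact_words)], categories)
      } else if (w == "like") {
        if (i > 1L && words[i - 1L] %in% c("i", "they", "will"))
          expand_categories("posemo", categories) else character()
      } else if (startsWith(w, stem_root)) {
        expand_categories("sad", categories)
      } else if (w == emoticon) {
        expand_categories("posemo", categories)
      } else character()
  }
  ref_sets <- rollup(subs, categories)
  pm <- category_matrix(pred_sets, categories$id)
  rm_ <- category_matrix(ref_sets, categories$id)
  truth <- lapply(categories$id, function(cid) {
    confusion_counts(cid,
                     tp = sum(rm_[, cid] & pm[, cid]),
                     fp = sum(!rm_[, cid] & pm[, cid]),
                     fn = sum(rm_[, cid] & !pm[, cid]),
                     tn = sum(!rm_[, cid] & !pm[, cid]))
  })
  names(truth) <- categories$id
  structure(list(lexicon = lx, docs = docs, reference = reference,
                 truth = truth),
            class = "textdx_lexfixture")
}

#' Write a synthetic corpus to the pipeline's TSV dialects
#'
#' Writes `corpus.tsv` (participant_id, text — the dialect [read_corpus()]
#' accepts; re-tokenizing it reproduces the generator's token positions
#' because synthetic surfaces are purely alphabetic), `reference.tsv` (see
#' [read_reference()]) and `metadata.json` (seed and config echo).
#'
#' @param synthetic A [generate_corpus()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synthetic, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  texts <- dplyr::summarise(
    dplyr::group_by(synthetic$docs, .data$participant_id),
    text = paste(.data$surface, collapse = " "), .groups = "drop")
  utils::write.table(
    texts, file.path(dir, "corpus.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  write_reference(synthetic$reference, file.path(dir, "reference.tsv"))
  cfg <- synthetic$config
  jsonlite::write_json(
    list(seed = cfg$seed, n_participants = cfg$n_participants,
         tokens_per_participant = cfg$tokens_per_participant,
         prevalence = as.list(cfg$prevalence)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
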