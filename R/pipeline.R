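#' Read a corpus of participant texts
#'
#' Accepts either a directory of per-participant plain-text files (the
#' participant id is the file name without extension) or a single TSV with
#' columns `participant_id`, `text`.
#'
#' @param path Directory or TSV file path.
#' @return Tibble with `participant_id`, `text`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) {
      tdx_error(paste0("no .txt files in corpus directory ", path),
                "textdx_config_error")
    }
    return(tibble::tibble(
      participant_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " ")
      }, "")
    ))
  }
  if (!file.exists(path)) {
    tdx_error(paste0("corpus not found: ", path), "textdx_config_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (!all(c("participant_id", "text") %in% names(df))) {
    tdx_error(paste0(path, ": corpus TSV must have participant_id, text"),
              "textdx_parse_error")
  }
  tibble::as_tibble(df[c("participant_id", "text")])
}

#' Write / read a tagged corpus TSV
#'
#' Columns: participant_id, position, surface, norm, categories
#' (comma-joined ids; empty string for no categories).
#'
#' @param tagged Output of [tag_corpus()].
#' @param path File path.
#' @return `path` (write) or a tagged tibble (read).
#' @export
write_tagged <- function(tagged, path) {
  out <- tagged[, c("participant_id", "position", "surface", "norm")]
  out$categories <- vapply(tagged$categories, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tagged
#' @export
read_tagged <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("participant_id", "position", "surface", "norm", "categories")
  if (!all(need %in% names(df))) {
    tdx_error(paste0(path, ": tagged TSV must have columns ",
                     paste(need, collapse = ", ")), "textdx_parse_error")
  }
  df$position <- as.integer(df$position)
  out <- tibble::as_tibble(df[need[1:4]])
  out$is_word <- TRUE
  out$is_emoticon <- FALSE
  out$countable <- TRUE
  out$categories <- lapply(strsplit(df$categories, ","), function(x) {
    x[nzchar(x)]
  })
  out
}

tagger_to_tagged <- function(tagger, docs) {
  if (inherits(tagger, "textdx_lexicon")) {
    tag_corpus(tagger, docs)
  } else if (inherits(tagger, "textdx_predictions")) {
    if (is.null(tagger$tagged)) {
      tdx_error("predictions were built with build_tagged = FALSE",
                "textdx_config_error")
    }
    tagger$tagged
  } else if (is.data.frame(tagger) && "categories" %in% names(tagger)) {
    tagger
  } else {
    tdx_error("tagger must be a lexicon, predictions, or tagged tibble",
              "textdx_config_error")
  }
}

#' Run the full validation pipeline
#'
#' Tags the corpus with each tagger (dictionary version), aligns machine
#' tags with the human reference coding, and computes the complete
#' diagnostic battery: per-category confusion counts; sensitivity,
#' specificity, PPV and NPV with confidence intervals; F scores; pairwise
#' between-version two-proportion tests with Bonferroni correction (one
#' family for the four count-based metrics, one for F-score comparisons);
#' per-participant percentage summaries; and Pearson correlation matrices
#' between every pair of sources (including human coders).
#'
#' @param docs Token tibble ([tokenize_corpus()] output) shared by all
#'   taggers, or a raw-text tibble (`participant_id`, `text`), which is
#'   tokenized with the union of the taggers' emoticon inventories so
#'   positions are comparable across versions.
#' @param reference Reference-label tibble.
#' @param taggers Named list; each element a [lexicon()], a
#'   `textdx_predictions` object, or a tagged token tibble.
#' @param categories Category table.
#' @param ci_method "wilson" or "wald".
#' @param alpha Family-wise significance level.
#' @param family_metrics Bonferroni family size for sensitivity/
#'   specificity/PPV/NPV comparisons (default 24: 6 categories x 4
#'   version pairs per the two tested metric tables).
#' @param family_f Bonferroni family size for F-score comparisons
#'   (default 6: one per category).
#' @param seed Recorded in the provenance block (the pipeline itself is
#'   deterministic given its inputs).
#' @return An object of class `textdx_report`.
#' @export
run_validation <- function(docs, reference, taggers,
                           categories = emotion_hierarchy(),
                           ci_method = c("wilson", "wald"),
                           alpha = 0.05, family_metrics = 24L,
                           family_f = 6L, seed = NA_integer_) {
  ci_method <- match.arg(ci_method)
  if (length(taggers) == 0L || is.null(names(taggers)) ||
      any(!nzchar(names(taggers)))) {
    tdx_error("taggers must be a nonempty named list", "textdx_config_error")
  }
  if (!"position" %in% names(docs)) {
    emoticons <- unique(unlist(lapply(taggers, function(tg) {
      if (inherits(tg, "textdx_lexicon"))
        tg$entries$pattern[tg$entries$is_emoticon] else character()
    })))
    docs <- tokenize_corpus(docs, emoticons = emoticons)
  }

  versions <- names(taggers)
  aligned <- list(); pct <- list()
  for (v in versions) {
    tagged <- tagger_to_tagged(taggers[[v]], docs)
    aligned[[v]] <- align(reference, tagged, categories)
    pct[[v]] <- category_percentages(tagged, categories)
  }
  pct[["human"]] <- reference_percentages(aligned[[1]])

  metric_rows <- list()
  for (v in versions) {
    for (cid in categories$id) {
      cc <- confusion(aligned[[v]], cid)
      se <- sensitivity(cc, method = ci_method)
      sp <- specificity(cc, method = ci_method)
      pv <- if (cc$tp + cc$fp > 0) ppv(cc, method = ci_method) else NULL
      nv <- npv(cc, method = ci_method)
      f <- if (!is.null(pv) && pv$value + se$value > 0)
        f_score(pv, se)$value else NA_real_
      metric_rows[[length(metric_rows) + 1L]] <- tibble::tibble(
        version = v, category = cid,
        tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
        sensitivity = se$value, sens_lo = se$ci_low, sens_hi = se$ci_high,
        specificity = sp$value, spec_lo = sp$ci_low, spec_hi = sp$ci_high,
        ppv = if (is.null(pv)) NA_real_ else pv$value,
        ppv_lo = if (is.null(pv)) NA_real_ else pv$ci_low,
        ppv_hi = if (is.null(pv)) NA_real_ else pv$ci_high,
        npv = nv$value, npv_lo = nv$ci_low, npv_hi = nv$ci_high,
        f_score = f
      )
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)

  comparisons <- compare_all(metrics, versions, categories$id,
                             alpha = alpha,
                             family_metrics = family_metrics,
                             family_f = family_f)

  pairs <- utils::combn(names(pct), 2, simplify = FALSE)
  correlations <- lapply(pairs, function(pr) {
    tryCatch(pearson_correlation(pct[[pr[1]]], pct[[pr[2]]]),
             textdx_metric_error = function(e) NULL,
             textdx_data_error = function(e) NULL)
  })
  names(correlations) <- vapply(pairs, paste, "", collapse = " vs ")

  summary_tab <- dplyr::bind_rows(lapply(names(pct), function(src) {
    tibble::tibble(source = src, summarize_percentages(pct[[src]]))
  }))

  structure(
    list(metrics = metrics, comparisons = comparisons,
         summary = summary_tab, correlations = correlations,
         percentages = pct,
         provenance = list(
           seed = seed, versions = versions, ci_method = ci_method,
           alpha = alpha, family_metrics = family_metrics,
           family_f = family_f,
           total_tokens = aligned[[1]]$total_tokens,
           n_participants = length(aligned[[1]]$participants),
           config_hash = rlang::hash(list(versions, ci_method, alpha,
                                          family_metrics, family_f, seed))
         )),
    class = "textdx_report"
  )
}

metric_denominator <- function(row, metric) {
  switch(metric,
         sensitivity = row$tp + row$fn,
         specificity = row$tn + row$fp,
         ppv = row$tp + row$fp,
         npv = row$tn + row$fn,
         f_score = row$tp + row$fn,  # reference-group size approximation
         tdx_error(paste0("unknown metric '", metric, "'"),
                   "textdx_config_error"))
}

empty_comparisons <- function() {
  tibble::tibble(metric = character(), category = character(),
                 version_a = character(), version_b = character(),
                 value_a = numeric(), value_b = numeric(),
                 n_a = integer(), n_b = integer(),
                 z = numeric(), p_value = numeric(),
                 alpha_corrected = numeric(), significant = logical())
}

compare_all <- function(metrics, versions, cat_ids, alpha, family_metrics,
                        family_f) {
  if (length(versions) < 2L) return(empty_comparisons())
  vp <- utils::combn(versions, 2, simplify = FALSE)
  rows <- list()
  for (metric in c("sensitivity", "specificity", "ppv", "npv", "f_score")) {
    fam <- if (metric == "f_score") family_f else family_metrics
    for (cid in cat_ids) {
      for (pr in vp) {
        a <- metrics[metrics$version == pr[1] & metrics$category == cid, ]
        b <- metrics[metrics$version == pr[2] & metrics$category == cid, ]
        va <- a[[metric]]; vb <- b[[metric]]
        na_ <- metric_denominator(a, metric)
        nb <- metric_denominator(b, metric)
        if (is.na(va) || is.na(vb) || na_ == 0L || nb == 0L) next
        ct <- tryCatch(
          two_proportion_test(va, na_, vb, nb, alpha = alpha, m = fam),
          textdx_metric_error = function(e) NULL)
        if (is.null(ct)) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          metric = metric, category = cid,
          version_a = pr[1], version_b = pr[2],
          value_a = va, value_b = vb, n_a = na_, n_b = nb,
          z = ct$z, p_value = ct$p_value,
          alpha_corrected = ct$alpha_corrected,
          significant = ct$significant
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_comparisons())
  dplyr::bind_rows(rows)
}

#' Re-test one pairwise version comparison from a report
#'
#' Delegates to [two_proportion_test()] using the denominators recorded in
#' the report's confusion counts and the configured Bonferroni family.
#'
#' @param report A `textdx_report`.
#' @param version_a,version_b Version names present in the report.
#' @param category Category id.
#' @param metric One of "sensitivity", "specificity", "ppv", "npv",
#'   "f_score".
#' @return A `textdx_comparison`.
#' @export
compare_versions <- function(report, version_a, version_b, category,
                             metric = "sensitivity") {
  m <- report$metrics
  for (v in c(version_a, version_b)) {
    if (!v %in% m$version) {
      tdx_error(paste0("unknown version '", v, "'"), "textdx_config_error")
    }
  }
  if (!category %in% m$category) {
    tdx_error(paste0("unknown category '", category, "'"),
              "textdx_config_error")
  }
  a <- m[m$version == version_a & m$category == category, ]
  b <- m[m$version == version_b & m$category == category, ]
  fam <- if (metric == "f_score") report$provenance$family_f
         else report$provenance$family_metrics
  two_proportion_test(a[[metric]], metric_denominator(a, metric),
                      b[[metric]], metric_denominator(b, metric),
                      alpha = report$provenance$alpha, m = fam)
}

#' @export
print.textdx_report <- function(x, ...) {
  cat("<textdx_report>", length(x$provenance$versions), "versions,",
      x$provenance$n_participants, "participants,",
      x$provenance$total_tokens, "tokens\n\n")
  show <- x$metrics[, c("version", "category", "sensitivity", "specificity",
                        "ppv", "npv", "f_score")]
  print(as.data.frame(show), digits = 3)
  nsig <- sum(x$comparisons$significant)
  cat("\n", nrow(x$comparisons), "pairwise comparisons,", nsig,
      "significant after Bonferroni\n")
  invisible(x)
}

report_to_list <- function(report) {
  list(
    provenance = report$provenance,
    metrics = report$metrics,
    comparisons = report$comparisons,
    summary = report$summary,
    correlations = lapply(report$correlations, function(m) {
      if (is.null(m)) NULL else as.data.frame(as.table(m),
                                              stringsAsFactors = FALSE)
    })
  )
}

#' Serialize a report to JSON
#'
#' Deterministic given the report (no timestamps), so identical runs give
#' byte-identical JSON.
#'
#' @param report A `textdx_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE, digits = NA,
                   dataframe = "columns", na = "null")
}

#' Write a report to disk
#'
#' Emits `report.json` plus CSV tables `metrics.csv`, `comparisons.csv`,
#' `summary.csv` mirroring the classic validation-table shapes.
#'
#' @param report A `textdx_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
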