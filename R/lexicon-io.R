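#' Read a lexicon dictionary file
#'
#' The dictionary dialect is plain UTF-8 text, structurally analogous to a
#' LIWC `.dic` file:
#'
#' ```
#' version: mini-2015
#' count_emoticons_as_words: true
#' %
#' affect<TAB>Total affect<TAB>-
#' posemo<TAB>Positive emotion<TAB>affect
#' %
#' happ* posemo
#' cried sad
#' :) posemo
#' %rules
#' like 1 i,they,will posemo true
#' ```
#'
#' Key/value header lines precede the first `%`; category lines
#' (`id<TAB>name<TAB>parent`, `-` for the root) sit between the two `%`
#' separators; entry lines are `pattern cat1 cat2 ...` with a trailing `*`
#' marking a stem; an optional `%rules` section holds context rules as
#' `target window trigger,words grant,cats suppress_default`.
#'
#' @param path File path.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) {
    tdx_error(paste0("lexicon file not found: ", path), "textdx_config_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  perr <- function(i, msg) {
    tdx_error(paste0(path, ":", i, ": ", msg), "textdx_parse_error", line = i)
  }
  sep <- which(trimws(lines) == "%")
  if (length(sep) < 2L) perr(length(lines), "expected two '%' separators")
  rules_at <- which(trimws(lines) == "%rules")

  version <- "custom"; count_emo <- FALSE
  for (i in seq_len(sep[1] - 1L)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) perr(i, "malformed header line")
    if (kv[2] == "version") version <- kv[3]
    else if (kv[2] == "count_emoticons_as_words")
      count_emo <- tolower(kv[3]) %in% c("true", "yes", "1")
    else perr(i, paste0("unknown header key '", kv[2], "'"))
  }

  cat_rows <- list()
  for (i in seq(sep[1] + 1L, sep[2] - 1L)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) != 3L) perr(i, "category line must have 3 tab-separated fields")
    cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
      id = f[1], name = f[2],
      parent = if (f[3] == "-") NA_character_ else f[3]
    )
  }
  categories <- dplyr::bind_rows(cat_rows)
  if (nrow(categories) == 0L) perr(sep[2], "no categories defined")

  entry_end <- if (length(rules_at) > 0L) rules_at[1] - 1L else length(lines)
  ent_rows <- list()
  seen <- character()
  entry_idx <- if (entry_end >= sep[2] + 1L) seq(sep[2] + 1L, entry_end)
               else integer()
  for (i in entry_idx) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (length(f) < 2L) perr(i, "entry line needs a pattern and >=1 category")
    pat <- f[1]
    is_stem <- endsWith(pat, "*")
    if (is_stem) pat <- substr(pat, 1L, nchar(pat) - 1L)
    if (!nzchar(pat)) perr(i, "empty entry pattern")
    key <- paste0(pat, "\r", is_stem)
    if (key %in% seen) perr(i, paste0("duplicate entry '", f[1], "'"))
    seen <- c(seen, key)
    unknown <- setdiff(f[-1], categories$id)
    if (length(unknown) > 0L) {
      perr(i, paste0("unknown category '", unknown[1], "' in entry"))
    }
    ent_rows[[length(ent_rows) + 1L]] <- tibble::tibble(
      pattern = pat, is_stem = is_stem, categories = list(f[-1])
    )
  }
  entries <- dplyr::bind_rows(ent_rows)
  if (nrow(entries) == 0L) {
    entries <- tibble::tibble(pattern = character(), is_stem = logical(),
                              categories = list())
  }

  rules <- list()
  if (length(rules_at) > 0L && rules_at[1] < length(lines)) {
    for (i in seq(rules_at[1] + 1L, length(lines))) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) != 5L) perr(i, "rule line needs 5 fields")
      win <- suppressWarnings(as.integer(f[2]))
      if (is.na(win) || win < 1L || win > 2L) perr(i, "rule window must be 1 or 2")
      grant <- strsplit(f[4], ",")[[1]]
      unknown <- setdiff(grant, categories$id)
      if (length(unknown) > 0L) {
        perr(i, paste0("unknown category '", unknown[1], "' in rule"))
      }
      rules[[length(rules) + 1L]] <- context_rule(
        target = f[1], window = win, words = strsplit(f[3], ",")[[1]],
        grant = grant,
        suppress_default = tolower(f[5]) %in% c("true", "yes", "1")
      )
    }
  }

  withCallingHandlers(
    lexicon(entries, categories = categories, context_rules = rules,
            version_tag = version, count_emoticons_as_words = count_emo),
    textdx_lexicon_error = function(e) {
      tdx_error(paste0(path, ": ", conditionMessage(e)), "textdx_parse_error")
    }
  )
}

#' Write a lexicon dictionary file
#'
#' Inverse of [read_lexicon()]: `read_lexicon(write_lexicon(lx, path))`
#' reproduces the lexicon exactly.
#'
#' @param lexicon A [lexicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  hdr <- c(
    paste0("version: ", lexicon$version_tag),
    paste0("count_emoticons_as_words: ",
           tolower(as.character(lexicon$count_emoticons_as_words)))
  )
  cats <- paste(lexicon$categories$id, lexicon$categories$name,
                ifelse(is.na(lexicon$categories$parent), "-",
                       lexicon$categories$parent),
                sep = "\t")
  e <- lexicon$entries
  ents <- if (nrow(e) > 0L) {
    paste(paste0(e$pattern, ifelse(e$is_stem, "*", "")),
          vapply(e$categories, paste, "", collapse = " "))
  } else character()
  out <- c(hdr, "%", cats, "%", ents)
  if (length(lexicon$context_rules) > 0L) {
    rls <- vapply(lexicon$context_rules, function(r) {
      paste(r$target, r$window, paste(r$words, collapse = ","),
            paste(r$grant, collapse = ","),
            tolower(as.character(r$suppress_default)))
    }, "")
    out <- c(out, "%rules", rls)
  }
  writeLines(enc2utf8(out), path, useBytes = TRUE)
  invisible(path)
}
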