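#' Normalize a disease name for merging and matching
#'
#' The merge rule collapses trivially distinct spellings of one disease:
#' case-fold, drop possessive "'s", replace punctuation by spaces, collapse
#' runs of whitespace. "Alzheimer's Disease" and "alzheimer disease"
#' normalize identically.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_disease_name(c("Alzheimer's disease", "ALZHEIMER DISEASE"))
normalize_disease_name <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "'s\\b", "")
  x <- stringr::str_replace_all(x, "[[:punct:]]+", " ")
  stringr::str_squish(x)
}

new_disease_lexicon <- function(entries, merge_report = NULL) {
  stopifnot(all(c("canonical", "class", "synonyms") %in% names(entries)))
  out <- as_tibble(entries)
  attr(out, "class_set") <- sort(unique(out$class))
  attr(out, "merge_report") <- merge_report
  attr(out, "lexicon_version") <- hash(list(out$canonical, out$class, out$synonyms))
  class(out) <- c("disease_lexicon", class(out))
  out
}

#' The set of disease classes covered by a lexicon
#'
#' @param lexicon A `disease_lexicon`.
#' @return Character vector of class labels.
#' @export
lexicon_classes <- function(lexicon) attr(lexicon, "class_set")

#' Merge a raw disease vocabulary into a non-redundant lexicon
#'
#' Collapses raw `(name, class)` records whose normalized names coincide
#' (see [normalize_disease_name()]) into single canonical entries carrying
#' all source spellings as synonyms. An optional synonym table maps
#' additional variant names onto a preferred name before normalization, and
#' also arbitrates class conflicts: if the same normalized name is recorded
#' under two classes and no synonym mapping resolves it, merging fails with
#' a conflict error listing the offenders.
#'
#' Merging is idempotent: re-merging a merged lexicon's `(canonical, class)`
#' rows changes nothing. The collapses performed are recorded in a merge
#' report available via `merge_report()`.
#'
#' @param raw_terms Data frame with columns `name` and `class`.
#' @param synonym_table Optional data frame with columns `from` and `to`
#'   mapping variant names to a preferred name.
#' @return A `disease_lexicon`: a tibble with columns `canonical`, `class`
#'   and a `synonyms` list-column, plus a merge report attribute.
#' @export
#' @examples
#' raw <- data.frame(
#'   name = c("Alzheimer disease", "alzheimer's disease", "breast cancer"),
#'   class = c("Neurological", "Neurological", "Cancer")
#' )
#' lex <- merge_lexicon(raw)
#' nrow(lex)
merge_lexicon <- function(raw_terms, synonym_table = NULL) {
  if (!is.data.frame(raw_terms) || !all(c("name", "class") %in% names(raw_terms)) ||
      nrow(raw_terms) == 0) {
    stop_validation("`raw_terms` must be a non-empty data frame with columns `name` and `class`.")
  }
  raw <- as_tibble(raw_terms[c("name", "class")])

  if (!is.null(synonym_table)) {
    if (!all(c("from", "to") %in% names(synonym_table))) {
      stop_validation("`synonym_table` must have columns `from` and `to`.")
    }
    map <- setNames(as.character(synonym_table$to),
                    normalize_disease_name(synonym_table$from))
    key <- normalize_disease_name(raw$name)
    mapped <- !is.na(map[key])
    raw$target <- ifelse(mapped, unname(map[key]), raw$name)
  } else {
    raw$target <- raw$name
  }
  raw$norm <- normalize_disease_name(raw$target)

  # class conflicts: one normalized name under two classes, unarbitrated
  conf <- raw |>
    distinct(.data$norm, .data$class) |>
    count(.data$norm) |>
    filter(.data$n > 1)
  if (nrow(conf) > 0) {
    offenders <- raw |>
      filter(.data$norm %in% conf$norm) |>
      distinct(.data$norm, .data$name, .data$class)
    stop_config(
      c("Conflicting class assignments during lexicon merge.",
        stats::setNames(paste0(offenders$name, " -> ", offenders$class), rep("x", nrow(offenders)))),
      offenders = offenders
    )
  }

  merged <- raw |>
    group_by(.data$norm) |>
    summarise(
      canonical = .data$name[1],
      class = .data$class[1],
      synonyms = list(unique(.data$name)),
      n_collapsed = dplyr::n_distinct(.data$name),
      .groups = "drop"
    )

  report <- merged |>
    filter(.data$n_collapsed > 1) |>
    transmute(.data$canonical, .data$class, .data$n_collapsed,
              members = purrr::map_chr(.data$synonyms, paste, collapse = "; "))

  new_disease_lexicon(
    merged |> select("canonical", "class", "synonyms") |> arrange(.data$canonical),
    merge_report = report
  )
}

#' Retrieve the merge report of a lexicon
#'
#' @param lexicon A `disease_lexicon`.
#' @return Tibble of collapsed entries (one row per canonical name that
#'   absorbed more than one raw spelling), or `NULL` for hand-built lexicons.
#' @export
merge_report <- function(lexicon) attr(lexicon, "merge_report")

#' Read / write a lexicon TSV
#'
#' Format: `canonical<TAB>class<TAB>syn1;syn2;...` with a header row.
#'
#' @param path File path.
#' @return `read_lexicon()` returns a `disease_lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop_parse("Empty lexicon file.")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- stringr::str_split(body, "\t")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop_parse(sprintf("Malformed lexicon line %d: expected 3 tab-separated fields.", bad[1] + 1))
  }
  new_disease_lexicon(tibble(
    canonical = purrr::map_chr(parts, 1),
    class = purrr::map_chr(parts, 2),
    synonyms = purrr::map(parts, ~ setdiff(strsplit(.x[3], ";", fixed = TRUE)[[1]], ""))
  ))
}

#' @rdname read_lexicon
#' @param lexicon A `disease_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- c(
    "canonical\tclass\tsynonyms",
    paste(lexicon$canonical, lexicon$class,
          purrr::map_chr(lexicon$synonyms, paste, collapse = ";"),
          sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
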