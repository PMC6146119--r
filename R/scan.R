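new_scan_result <- function(docs, lexicon_version = NA_character_) {
  out <- as_tibble(docs)
  if (!"genes" %in% names(out)) out$genes <- rep(list(character()), nrow(out))
  attr(out, "lexicon_version") <- lexicon_version
  class(out) <- c("scan_result", class(out))
  out
}

#' Read a corpus TSV
#'
#' Two dialects are supported. The raw dialect carries free text,
#' `doc_id<TAB>free text`, and is the input to [scan_documents()]. The scan
#' dialect carries pre-extracted mention lists,
#' `doc_id<TAB>mention1;mention2;...[<TAB>gene1;gene2;...]`, the shape
#' produced by an upstream scanner or an external gene-name recognizer.
#'
#' @param path File path.
#' @param dialect `"raw"` or `"scan"`.
#' @return For `"raw"`, a tibble with columns `doc_id`, `text`; for
#'   `"scan"`, a `scan_result`.
#' @export
read_corpus <- function(path, dialect = c("raw", "scan")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  if (dialect == "raw") {
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop_parse(sprintf("Malformed corpus line %d: expected `doc_id<TAB>text`.", bad[1]))
    }
    out <- tibble(doc_id = purrr::map_chr(parts, 1), text = purrr::map_chr(parts, 2))
  } else {
    bad <- which(!lengths(parts) %in% c(2L, 3L))
    if (length(bad)) {
      stop_parse(sprintf("Malformed corpus line %d: expected 2 or 3 tab-separated fields.", bad[1]))
    }
    split_list <- function(x) setdiff(strsplit(x, ";", fixed = TRUE)[[1]], "")
    out <- new_scan_result(tibble(
      doc_id = purrr::map_chr(parts, 1),
      diseases = purrr::map(parts, ~ split_list(.x[2])),
      genes = purrr::map(parts, ~ if (length(.x) == 3) split_list(.x[3]) else character())
    ))
  }
  if (anyDuplicated(out$doc_id)) {
    stop_parse(sprintf("Duplicate doc_id in corpus: %s",
                       out$doc_id[duplicated(out$doc_id)][1]))
  }
  out
}

#' Write a scan result to TSV (scan dialect)
#'
#' @param scan A `scan_result`.
#' @param path File path.
#' @export
write_scan_result <- function(scan, path) {
  lines <- paste(scan$doc_id,
                 purrr::map_chr(scan$diseases, paste, collapse = ";"),
                 purrr::map_chr(scan$genes, paste, collapse = ";"),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Scan documents for disease mentions
#'
#' Matches every lexicon term (canonical names and synonyms) against each
#' document's text. Matching is case-insensitive at word boundaries on
#' normalized text, longest match first; shorter terms nested inside an
#' accepted longer match are suppressed, so "breast cancer" yields one
#' mention, not an extra "cancer". Documents with zero matches are retained
#' with empty mention sets; dropping them is the job of
#' [filter_hit_documents()].
#'
#' @param corpus Tibble with columns `doc_id` and `text` (raw dialect).
#' @param lexicon A `disease_lexicon`.
#' @return A `scan_result`: tibble with `doc_id`, `diseases` (list-column of
#'   canonical names) and `genes` (empty; gene mentions come from the scan
#'   dialect, not from this scanner).
#' @export
#' @examples
#' lex <- merge_lexicon(data.frame(
#'   name = c("breast cancer", "cancer"), class = c("Cancer", "Cancer")))
#' corpus <- tibble::tibble(doc_id = "d1", text = "Autophagy in breast cancer.")
#' scan_documents(corpus, lex)$diseases[[1]]
scan_documents <- function(corpus, lexicon) {
  if (!all(c("doc_id", "text") %in% names(corpus))) {
    stop_validation("`corpus` must have columns `doc_id` and `text` (raw dialect).")
  }
  if (anyDuplicated(corpus$doc_id)) stop_validation("doc_ids must be unique.")
  if (nrow(lexicon) == 0) stop_validation("Lexicon is empty.")

  terms <- tibble(
    canonical = rep(lexicon$canonical, lengths(lexicon$synonyms) + 1L),
    term = normalize_disease_name(
      unlist(purrr::map2(lexicon$canonical, lexicon$synonyms, c), use.names = FALSE))
  ) |>
    distinct(.data$term, .keep_all = TRUE) |>
    arrange(desc(nchar(.data$term)))
  patterns <- stringr::regex(paste0("\\b", stringr::str_replace_all(terms$term, "([\\W])", "\\\\\\1"), "\\b"))

  match_one <- function(text) {
    norm <- normalize_disease_name(text)
    claimed <- rep(FALSE, nchar(norm))
    hits <- character()
    for (i in seq_len(nrow(terms))) {
      loc <- stringr::str_locate_all(norm, patterns[[i]])[[1]]
      if (nrow(loc) == 0) next
      for (j in seq_len(nrow(loc))) {
        span <- loc[j, 1]:loc[j, 2]
        if (!any(claimed[span])) {
          claimed[span] <- TRUE
          hits <- c(hits, terms$canonical[i])
        }
      }
    }
    unique(hits)
  }

  new_scan_result(
    tibble(doc_id = as.character(corpus$doc_id),
           diseases = purrr::map(corpus$text, match_one)),
    lexicon_version = attr(lexicon, "lexicon_version")
  )
}

#' Keep only documents with at least one disease mention
#'
#' The document funnel (papers in, papers with hits, distinct diseases hit)
#' is recorded in the `funnel` attribute.
#'
#' @param scan A `scan_result`.
#' @return A filtered `scan_result`; `attr(x, "funnel")` holds
#'   `n_documents_in`, `n_documents_retained`, `n_distinct_diseases_hit`.
#' @export
filter_hit_documents <- function(scan) {
  keep <- lengths(scan$diseases) > 0
  out <- new_scan_result(scan[keep, , drop = FALSE],
                         lexicon_version = attr(scan, "lexicon_version"))
  attr(out, "funnel") <- list(
    n_documents_in = nrow(scan),
    n_documents_retained = sum(keep),
    n_distinct_diseases_hit = length(unique(unlist(scan$diseases)))
  )
  out
}

#' Tally lexicon and hit counts per disease class
#'
#' Counts, per class, the number of distinct diseases in the lexicon and the
#' number of distinct diseases hit anywhere in the scanned corpus — the two
#' columns the concentration/retention-ratio statistics compare.
#'
#' @param scan A `scan_result` whose diseases all exist in `lexicon`.
#' @param lexicon A `disease_lexicon`.
#' @return A tibble with columns `class`, `lexicon_count`, `paper_count`,
#'   one row per class in the lexicon's class set.
#' @export
tally_classes <- function(scan, lexicon) {
  hit <- unique(unlist(scan$diseases))
  unknown <- setdiff(hit, lexicon$canonical)
  if (length(unknown)) {
    stop_validation(c("Scan contains diseases absent from the lexicon:",
                      stats::setNames(head(unknown, 5), rep("x", length(head(unknown, 5))))))
  }
  lex_tab <- lexicon |>
    as_tibble() |>
    count(.data$class, name = "lexicon_count")
  hit_tab <- lexicon |>
    as_tibble() |>
    filter(.data$canonical %in% hit) |>
    count(.data$class, name = "paper_count")
  lex_tab |>
    left_join(hit_tab, by = "class") |>
    mutate(paper_count = dplyr::coalesce(.data$paper_count, 0L)) |>
    arrange(.data$class)
}
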