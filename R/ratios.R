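check_count_table <- function(counts) {
  need <- c("class", "lexicon_count", "paper_count")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stop_validation("`counts` must have columns `class`, `lexicon_count`, `paper_count`.")
  }
  if (any(counts$lexicon_count < 0) || any(counts$paper_count < 0)) {
    stop_validation("Counts must be non-negative.")
  }
  if (any(counts$paper_count > counts$lexicon_count)) {
    bad <- counts$class[counts$paper_count > counts$lexicon_count]
    stop_validation(sprintf(
      "paper_count exceeds lexicon_count for: %s (a hit must exist in the lexicon).",
      paste(bad, collapse = ", ")))
  }
  if (sum(counts$lexicon_count) <= 0) stop_compute("Total lexicon count is zero.")
  if (sum(counts$paper_count) <= 0) stop_compute("All paper counts are zero.")
  invisible(counts)
}

#' Concentration and retention ratios per disease class
#'
#' For class i with `paper_count` hits among `lexicon_count` lexicon
#' diseases, the concentration ratio is the class's share among hit diseases
#' divided by its share in the lexicon,
#' \deqn{CR_i = \frac{paper_i / \sum_j paper_j}{lexicon_i / \sum_j lexicon_j},}
#' and the retention ratio is the within-class survival fraction,
#' \deqn{RR_i = paper_i / lexicon_i \in [0, 1].}
#' CR = 1 is the neutral value (class composition unchanged); CR > 1 marks
#' enrichment of the class among the diseases found in the corpus. Both are
#' undefined (`NA`, never silently 0) for classes with `lexicon_count` 0.
#'
#' Rows may equally be individual diseases rather than classes: the
#' statistics only see the count columns, so a per-disease table gives
#' per-disease ratios.
#'
#' @param counts Data frame with columns `class`, `lexicon_count`,
#'   `paper_count` (e.g. from [tally_classes()], or the packaged count
#'   fixture with its columns renamed).
#' @return A `class_ratios` tibble adding `lexicon_fraction`,
#'   `paper_fraction`, `cr`, `rr`.
#' @export
#' @examples
#' t1 <- load_fixture("table1_counts")
#' r <- class_ratios(data.frame(class = t1$class,
#'                              lexicon_count = t1$filtered_count,
#'                              paper_count = t1$ad_count))
#' r[r$class == "Cancer", c("cr", "rr")]
class_ratios <- function(counts) {
  check_count_table(counts)
  out <- as_tibble(counts) |>
    mutate(
      lexicon_fraction = .data$lexicon_count / sum(.data$lexicon_count),
      paper_fraction = .data$paper_count / sum(.data$paper_count),
      cr = ifelse(.data$lexicon_count > 0,
                  .data$paper_fraction / .data$lexicon_fraction, NA_real_),
      rr = ifelse(.data$lexicon_count > 0,
                  .data$paper_count / .data$lexicon_count, NA_real_)
    )
  class(out) <- c("class_ratios", class(out))
  out
}

#' Rate table of class composition across count columns
#'
#' Formats a counts table the way printed composition tables are laid out:
#' for every count column, a companion rate column gives
#' `100 * count / column total`, rounded half-up to 2 decimals, and a
#' `Total` row closes the table with each rate at 100.
#'
#' @param counts Data frame with a `class` column; every other numeric
#'   column is treated as a count column.
#' @return Tibble with, per count column, `<name>` and `<name>_rate`
#'   columns, plus the `Total` row.
#' @export
#' @examples
#' rate_table(load_fixture("table1_counts"))
rate_table <- function(counts) {
  if (!is.data.frame(counts) || !"class" %in% names(counts)) {
    stop_validation("`counts` must have a `class` column.")
  }
  count_cols <- names(counts)[vapply(counts, is.numeric, logical(1))]
  if (!length(count_cols)) stop_validation("No numeric count columns found.")
  out <- tibble(class = as.character(counts$class))
  totals <- tibble(class = "Total")
  for (cc in count_cols) {
    v <- counts[[cc]]
    if (any(v < 0)) stop_validation("Counts must be non-negative.")
    tot <- sum(v)
    if (tot <= 0) stop_compute(sprintf("Column `%s` sums to zero.", cc))
    out[[cc]] <- v
    out[[paste0(cc, "_rate")]] <- round_half_up(100 * v / tot, 2)
    totals[[cc]] <- tot
    totals[[paste0(cc, "_rate")]] <- 100
  }
  bind_rows(out, totals)
}
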