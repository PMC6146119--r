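#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% hash .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats phyper rpois qpois dpois runif rnorm rbinom setNames
#'   as.dist hclust qlogis plogis median
#' @importFrom utils head combn
NULL

# classed conditions so callers/tests can dispatch on failure kind
stop_config <- function(msg, ...) abort(msg, class = "autolit_config_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "autolit_validation_error", ...)
stop_parse <- function(msg, ...) abort(msg, class = "autolit_parse_error", ...)
stop_lookup <- function(msg, ...) abort(msg, class = "autolit_lookup_error", ...)
stop_compute <- function(msg, ...) abort(msg, class = "autolit_computation_error", ...)

#' Round half away from zero
#'
#' Printed rate tables in the field round 2.3809... to 2.38 and 17.1957...
#' to 17.20, i.e. decimal round-half-up, which differs from [base::round()]
#' (round-half-even) on exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Wilcoxon/Mann-Whitney AUC of scores for positives vs negatives.
# Used for recovery diagnostics; ties get half credit.
rank_auc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Deterministically derive a per-stage seed from a global seed so stages
# can be re-run in isolation. Kept below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

path_fixture <- function(file) {
  system.file("extdata", file, package = "autolit", mustWork = TRUE)
}
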