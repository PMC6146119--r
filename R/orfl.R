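#' Configuration for positive-unlabeled random-forest scoring
#'
#' @param n_iterations Number of negative-resampling iterations. The
#'   default, 100 000, matches the scale used for genome-wide scoring; tests
#'   and examples use a few hundred to a few thousand, which is enough for
#'   score frequencies to stabilize to within a few percent.
#' @param negatives_per_iteration Either `"match-positives"` (default:
#'   balanced classes, one sampled negative per positive) or a positive
#'   integer.
#' @param trees_per_forest Trees per random forest (default 100).
#' @param mtry Features tried per split; `NULL` = floor(sqrt(p)), the
#'   conventional classification default.
#' @param vote_threshold Forest vote fraction at or above which a gene is
#'   called positive in an iteration; default 0.5 (majority vote).
#' @param seed Integer seed governing every random draw of the run.
#' @return An `orfl_config` list.
#' @export
orfl_config <- function(n_iterations = 100000,
                        negatives_per_iteration = "match-positives",
                        trees_per_forest = 100,
                        mtry = NULL,
                        vote_threshold = 0.5,
                        seed = 1) {
  if (!is_count(n_iterations) || n_iterations < 1) {
    stop_config("`n_iterations` must be a positive integer.")
  }
  if (!(identical(negatives_per_iteration, "match-positives") ||
        (is_count(negatives_per_iteration) && negatives_per_iteration >= 1))) {
    stop_config("`negatives_per_iteration` must be \"match-positives\" or a positive integer.")
  }
  if (!is_count(trees_per_forest) || trees_per_forest < 1) {
    stop_config("`trees_per_forest` must be a positive integer.")
  }
  if (!is.numeric(vote_threshold) || length(vote_threshold) != 1 ||
      is.na(vote_threshold) || vote_threshold <= 0 || vote_threshold >= 1) {
    stop_config("`vote_threshold` must lie strictly between 0 and 1.")
  }
  if (!is_count(seed)) stop_config("`seed` must be an integer.")
  structure(list(
    n_iterations = as.integer(n_iterations),
    negatives_per_iteration = negatives_per_iteration,
    trees_per_forest = as.integer(trees_per_forest),
    mtry = mtry,
    vote_threshold = vote_threshold,
    seed = as.integer(seed)
  ), class = "orfl_config")
}

features_to_matrix <- function(features) {
  if (is.matrix(features)) {
    if (is.null(rownames(features))) stop_validation("Feature matrix needs gene rownames.")
    return(features)
  }
  if (!is.data.frame(features) || !"gene" %in% names(features)) {
    stop_validation("`features` must be a data frame with a `gene` column (or a named matrix).")
  }
  genes <- as.character(features$gene)
  if (anyDuplicated(genes)) {
    stop_validation(sprintf("Duplicate gene symbols: %s",
                            paste(head(unique(genes[duplicated(genes)]), 5), collapse = ", ")))
  }
  x <- as.matrix(features[setdiff(names(features), "gene")])
  if (!is.numeric(x)) stop_validation("All feature columns must be numeric.")
  rownames(x) <- genes
  x
}

#' Positive-unlabeled gene scoring by bagged negative resampling
#'
#' Scores every unlabeled gene for membership in the positive class by the
#' frequency with which repeated random forests call it positive. Each
#' iteration samples a pseudo-negative set uniformly without replacement
#' from the unlabeled genes, fits a probability random forest on positives
#' (label 1) versus the sampled negatives (label 0), and classifies every
#' unlabeled gene *not* used as a training negative in that iteration (a
#' training point is never scored by its own iteration). A gene's
#' possibility score is
#' (number of iterations calling it positive) / (number of iterations it was
#' eligible), so it lies in `[0, 1]`; higher means more consistently
#' indistinguishable from the known positives. Known positives define the
#' labels and receive no score.
#'
#' Missing feature values are median-imputed per feature before fitting
#' (count recorded in run metadata). The whole run is deterministic given
#' the config seed.
#'
#' @param features Gene-by-feature data: a data frame with a `gene` column
#'   and numeric feature columns (or a numeric matrix with gene rownames).
#' @param positives Character vector of positive gene symbols (all must be
#'   present in `features`; at least 2).
#' @param config An [orfl_config()].
#' @return An `orfl_scores` tibble (`gene`, `score`, `n_called`,
#'   `n_eligible`), sorted by decreasing score, with run metadata in
#'   attributes; see [glance.orfl_scores()].
#' @export
#' @examples
#' sim <- generate_features(feature_spec(n_genes = 120, n_features = 10,
#'   n_informative = 4, effect_size = 3, n_positives = 15, seed = 1))
#' sc <- orfl_fit_score(sim$features, sim$positives,
#'   orfl_config(n_iterations = 50, trees_per_forest = 50, seed = 1))
#' head(sc, 3)
orfl_fit_score <- function(features, positives, config = orfl_config()) {
  if (!inherits(config, "orfl_config")) stop_config("`config` must come from orfl_config().")
  x <- features_to_matrix(features)
  genes <- rownames(x)
  positives <- unique(as.character(positives))
  missing <- setdiff(positives, genes)
  if (length(missing)) {
    stop_validation(c("Positive genes absent from the feature matrix:",
                      stats::setNames(head(missing, 10), rep("x", length(head(missing, 10))))))
  }
  if (length(positives) < 2) stop_validation("Need at least 2 positive genes.")

  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- median(x[, j], na.rm = TRUE)
    }
    inform(sprintf("Median-imputed %d missing feature value(s).", n_imputed))
  }

  unlabeled <- setdiff(genes, positives)
  n_neg <- if (identical(config$negatives_per_iteration, "match-positives")) {
    length(positives)
  } else {
    config$negatives_per_iteration
  }
  if (length(unlabeled) <= n_neg) {
    stop_config(sprintf(
      "Need more unlabeled genes (%d) than negatives per iteration (%d).",
      length(unlabeled), n_neg))
  }

  xpos <- x[positives, , drop = FALSE]
  xun <- x[unlabeled, , drop = FALSE]
  nu <- length(unlabeled)
  y <- factor(rep(c("1", "0"), c(length(positives), n_neg)), levels = c("0", "1"))
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))

  n_called <- n_eligible <- integer(nu)
  set.seed(config$seed)
  iter_seeds <- sample.int(2147483646L, config$n_iterations, replace = TRUE)
  for (b in seq_len(config$n_iterations)) {
    neg_idx <- sample.int(nu, n_neg)
    fit <- ranger::ranger(
      x = rbind(xpos, xun[neg_idx, , drop = FALSE]), y = y,
      num.trees = config$trees_per_forest, mtry = mtry,
      probability = TRUE, num.threads = 1, seed = iter_seeds[b],
      verbose = FALSE)
    pr <- predict(fit, xun, num.threads = 1, verbose = FALSE)$predictions[, "1"]
    eligible <- rep(TRUE, nu)
    eligible[neg_idx] <- FALSE
    n_eligible <- n_eligible + eligible
    n_called <- n_called + (eligible & pr >= config$vote_threshold)
  }

  out <- tibble(
    gene = unlabeled,
    score = ifelse(n_eligible > 0, n_called / n_eligible, NA_real_),
    n_called = n_called,
    n_eligible = n_eligible
  ) |>
    arrange(desc(.data$score), .data$gene)
  attr(out, "run") <- list(
    config = config,
    n_genes = length(genes),
    n_positives = length(positives),
    n_unlabeled = nu,
    negatives_per_iteration = n_neg,
    n_imputed = n_imputed,
    positives_hash = hash(sort(positives))
  )
  class(out) <- c("orfl_scores", class(out))
  out
}

#' @rdname orfl_fit_score
#' @param x An `orfl_scores` object.
#' @param ... Unused.
#' @export
glance.orfl_scores <- function(x, ...) {
  run <- attr(x, "run")
  tibble(
    n_genes = run$n_genes, n_positives = run$n_positives,
    n_unlabeled = run$n_unlabeled,
    n_iterations = run$config$n_iterations,
    negatives_per_iteration = run$negatives_per_iteration,
    trees_per_forest = run$config$trees_per_forest,
    vote_threshold = run$config$vote_threshold,
    seed = run$config$seed, n_imputed = run$n_imputed,
    positives_hash = run$positives_hash
  )
}

#' @export
tidy.orfl_scores <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Score histogram with bimodality summary
#'
#' Histograms the possibility scores over `[0, 1]`, plus a refined
#' histogram over `[0.9, 1]` where genome-wide runs show fine structure
#' near the top of the scale, and reports local maxima of both (a bin is a
#' mode when its count exceeds both neighbours').
#'
#' @param scores An `orfl_scores` (or a data frame with a `score` column).
#' @param bins Number of bins for each histogram (default 50).
#' @return A `score_distribution`: list of `histogram`, `refined` (tibbles
#'   with `lower`, `upper`, `mid`, `count`) and `modes` (tibble with
#'   `window`, `mid`, `count`).
#' @export
score_distribution <- function(scores, bins = 50) {
  s <- scores$score[!is.na(scores$score)]
  if (!length(s)) stop_validation("No non-missing scores to histogram.")
  if (!is_count(bins) || bins < 2) stop_validation("`bins` must be an integer >= 2.")

  hist_over <- function(lo, hi) {
    br <- seq(lo, hi, length.out = bins + 1)
    v <- s[s >= lo & s <= hi]
    cnt <- if (length(v)) {
      idx <- pmin(bins, pmax(1L, findInterval(v, br, rightmost.closed = TRUE)))
      tabulate(idx, bins)
    } else integer(bins)
    tibble(lower = br[-length(br)], upper = br[-1],
           mid = (br[-length(br)] + br[-1]) / 2, count = cnt)
  }
  modes_of <- function(h, window) {
    cnt <- h$count
    up <- c(-Inf, cnt[-length(cnt)])
    dn <- c(cnt[-1], -Inf)
    idx <- which(cnt > up & cnt > dn)
    tibble(window = window, mid = h$mid[idx], count = cnt[idx])
  }
  full <- hist_over(0, 1)
  refined <- hist_over(0.9, 1)
  structure(list(
    histogram = full, refined = refined,
    modes = bind_rows(modes_of(full, "[0,1]"), modes_of(refined, "[0.9,1]"))
  ), class = "score_distribution")
}

#' @export
tidy.score_distribution <- function(x, ...) x$histogram

#' Partition scored genes into threshold groups
#'
#' Cutpoints define left-closed intervals `[c_k, c_{k+1})`; the top group is
#' closed, so with the default cutpoints (0.999, 0.9997, 1) the groups are
#' `[0.999, 0.9997)`, `[0.9997, 1)` and `{1}`. Genes below the lowest
#' cutpoint are left ungrouped (`NA`); empty groups are retained as factor
#' levels, not errors.
#'
#' @param scores An `orfl_scores` (or data frame with `gene`, `score`).
#' @param cutpoints Strictly increasing numeric vector within `[0, 1]`.
#' @return The input rows with an added `group` factor column.
#' @export
#' @examples
#' threshold_groups(tibble::tibble(gene = c("a", "b", "c"),
#'                                 score = c(0.9991, 0.9998, 1)))
threshold_groups <- function(scores, cutpoints = c(0.999, 0.9997, 1)) {
  if (!is.numeric(cutpoints) || length(cutpoints) < 1 || anyNA(cutpoints) ||
      any(cutpoints < 0) || any(cutpoints > 1) || is.unsorted(cutpoints, strictly = TRUE)) {
    stop_validation("`cutpoints` must be strictly increasing within [0, 1].")
  }
  k <- length(cutpoints)
  labels <- c(
    if (k > 1) sprintf("[%g,%g)", cutpoints[-k], cutpoints[-1]),
    sprintf("[%g,%g]", cutpoints[k], max(cutpoints[k], 1))
  )
  grp <- cut(scores$score, breaks = c(cutpoints, Inf), right = FALSE, labels = labels)
  out <- as_tibble(scores)
  out$group <- grp
  out
}
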