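fast_config <- function(n_iterations, seed = 1, trees = 50) {
  orfl_config(n_iterations = n_iterations, trees_per_forest = trees, seed = seed)
}

test_that("planted genes sharing the positives' signature occupy the top ranks", {
  # positives and 10 planted unlabeled genes share a clean signature;
  # everything else is noise
  set.seed(5)
  n <- 150
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(sprintf("g%03d", 1:n), sprintf("f%02d", 1:10)))
  positives <- sprintf("g%03d", 1:15)
  planted <- sprintf("g%03d", 16:25)
  x[c(positives, planted), 1] <- x[c(positives, planted), 1] + 6
  scores <- orfl_fit_score(tibble::as_tibble(x, rownames = "gene"), positives,
                           fast_config(300, seed = 2))
  expect_setequal(scores$gene[1:10], planted)
  expect_true(all(scores$score[1:10] > 0.9))
})

test_that("identical data and config give identical scores", {
  sim <- generate_features(feature_spec(n_genes = 80, n_features = 8,
                                        n_informative = 3, effect_size = 2,
                                        n_positives = 10, seed = 3))
  a <- orfl_fit_score(sim$features, sim$positives, fast_config(40, seed = 9))
  b <- orfl_fit_score(sim$features, sim$positives, fast_config(40, seed = 9))
  expect_identical(tidy(a), tidy(b))
})

test_that("constant features leave all scores near chance", {
  feats <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          f1 = 1, f2 = 0, f3 = 2)
  scores <- orfl_fit_score(feats, sprintf("g%03d", 1:10),
                           fast_config(1000, seed = 4, trees = 25))
  expect_lt(max(scores$score) - min(scores$score), 0.2)
})

test_that("a single iteration gives only 0/1/unevaluated scores", {
  sim <- generate_features(feature_spec(n_genes = 40, n_features = 5, n_informative = 2,
                                        n_positives = 5, seed = 6))
  scores <- orfl_fit_score(sim$features, sim$positives, fast_config(1, seed = 1))
  expect_true(all(scores$score %in% c(0, 1) | is.na(scores$score)))
})

test_that("score frequencies converge as iterations double", {
  sim <- generate_features(feature_spec(n_genes = 60, n_features = 5,
                                        n_informative = 2, effect_size = 1,
                                        n_positives = 8, seed = 7))
  s1 <- orfl_fit_score(sim$features, sim$positives, fast_config(750, seed = 1, trees = 25))
  s2 <- orfl_fit_score(sim$features, sim$positives, fast_config(1500, seed = 2, trees = 25))
  d <- abs(s1$score[match(s2$gene, s1$gene)] - s2$score)
  expect_gte(mean(d < 0.05, na.rm = TRUE), 0.95)
})

test_that("validation and configuration errors name the problem", {
  sim <- generate_features(feature_spec(n_genes = 30, n_features = 4, n_informative = 2,
                                        n_positives = 4, seed = 8))
  err <- expect_error(
    orfl_fit_score(sim$features, c(sim$positives, "NOT_A_GENE"), fast_config(5)),
    class = "autolit_validation_error")
  expect_match(conditionMessage(err), "NOT_A_GENE")
  expect_error(
    orfl_fit_score(sim$features, sim$positives,
                   orfl_config(n_iterations = 5, negatives_per_iteration = 26)),
    class = "autolit_config_error")
  expect_error(orfl_config(vote_threshold = 1), class = "autolit_config_error")
  expect_error(orfl_config(n_iterations = 0), class = "autolit_config_error")
})

test_that("missing feature values are median-imputed with a message", {
  sim <- generate_features(feature_spec(n_genes = 40, n_features = 4, n_informative = 2,
                                        n_positives = 5, seed = 9))
  feats <- sim$features
  feats$f001[3] <- NA
  expect_message(
    scores <- orfl_fit_score(feats, sim$positives, fast_config(5)),
    "imputed 1")
  expect_equal(glance(scores)$n_imputed, 1)
})

test_that("score histograms detect planted bimodality", {
  set.seed(12)
  scores <- tibble::tibble(
    gene = sprintf("g%04d", 1:1000),
    score = c(stats::rbeta(800, 2, 18), stats::rbeta(200, 60, 1)))
  dist <- score_distribution(scores, bins = 20)
  full_modes <- dist$modes[dist$modes$window == "[0,1]", ]
  expect_true(any(full_modes$mid <= 0.2))
  expect_true(any(full_modes$mid >= 0.9))
  expect_equal(sum(dist$histogram$count), 1000)

  # all-equal scores occupy a single bin
  one <- score_distribution(tibble::tibble(gene = "g", score = rep(0.4, 5)), bins = 10)
  expect_equal(sum(one$histogram$count > 0), 1)
  expect_error(score_distribution(tibble::tibble(gene = "g", score = NA_real_)),
               class = "autolit_validation_error")
})

test_that("threshold groups use left-closed intervals with a closed top", {
  g <- threshold_groups(tibble::tibble(gene = c("a", "b", "c", "d"),
                                       score = c(0.9991, 0.9997, 1, 0.5)))
  expect_equal(as.character(g$group),
               c("[0.999,0.9997)", "[0.9997,1)", "[1,1]", NA))
  # boundary score 0.9997 goes to the middle group
  expect_equal(as.character(g$group[g$gene == "b"]), "[0.9997,1)")
  # no gene above the lowest cutpoint: empty groups reported, not errors
  none <- threshold_groups(tibble::tibble(gene = "x", score = 0.1))
  expect_true(is.na(none$group))
  expect_equal(levels(none$group), c("[0.999,0.9997)", "[0.9997,1)", "[1,1]"))
  expect_error(threshold_groups(g, cutpoints = c(0.9, 0.5)),
               class = "autolit_validation_error")
})
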