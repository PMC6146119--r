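test_that("fixed seeds give identical generated outputs", {
  lex <- toy_lexicon()
  spec <- corpus_spec(200, setNames(rep(1, 6), LETTERS[1:6]),
                      comention_boost = data.frame(class_a = "A", class_b = "B",
                                                   boost = 3),
                      seed = 10)
  expect_identical(generate_corpus(spec, lex)$diseases,
                   generate_corpus(spec, lex)$diseases)
  fs <- feature_spec(n_genes = 50, n_positives = 5, seed = 4)
  expect_identical(generate_features(fs), generate_features(fs))
  expect_identical(generate_toy_ontology(2, 3, 8, seed = 6),
                   generate_toy_ontology(2, 3, 8, seed = 6))
})

test_that("equal class weights give equal mention fractions within binomial noise", {
  lex <- toy_lexicon()
  sc <- generate_corpus(corpus_spec(10000, setNames(rep(1, 6), LETTERS[1:6]),
                                    seed = 21), lex)
  cls_of <- setNames(lex$class, lex$canonical)
  mentions <- table(factor(cls_of[unlist(sc$diseases)], LETTERS[1:6]))
  n <- sum(mentions)
  p <- 1 / 6
  expect_true(all(abs(mentions / n - p) < 4 * sqrt(p * (1 - p) / n)))
})

test_that("a boosted pair co-occurs in excess of independence and is detected", {
  lex <- toy_lexicon()
  spec <- corpus_spec(5000, setNames(rep(1, 6), LETTERS[1:6]),
                      comention_boost = data.frame(class_a = "A", class_b = "B",
                                                   boost = 5),
                      seed = 7)
  sc <- generate_corpus(spec, lex)
  cls_of <- setNames(lex$class, lex$canonical)
  pres <- vapply(LETTERS[1:6],
                 function(cl) vapply(sc$diseases,
                                     function(d) any(cls_of[d] == cl), logical(1)),
                 logical(nrow(sc)))
  joint <- mean(pres[, "A"] & pres[, "B"])
  expect_gt(joint, mean(pres[, "A"]) * mean(pres[, "B"]))
  assoc <- pairwise_association(sc, lex, "universe")
  p_ab <- assoc$p[assoc$class_a == "A" & assoc$class_b == "B"]
  expect_lt(p_ab, 0.01)
})

test_that("invalid corpus specs are configuration errors", {
  lex <- toy_lexicon()
  expect_error(corpus_spec(0, c(A = 1)), class = "autolit_config_error")
  expect_error(corpus_spec(10, c(A = 1), mentions_per_doc = 0),
               class = "autolit_config_error")
  expect_error(
    corpus_spec(10, c(A = 1, Z = 1),
                comention_boost = data.frame(class_a = "A", class_b = "B",
                                             boost = 0.5)),
    class = "autolit_config_error")
  expect_error(
    generate_corpus(corpus_spec(10, c(A = 1, NotAClass = 1), seed = 1), lex),
    class = "autolit_config_error")
})

test_that("null features show no positive/background separation", {
  # two-sample t on each column should be non-significant at alpha = 0.01
  # for at least 95% of columns across seeds
  pvals <- unlist(lapply(1:5, function(s) {
    sim <- generate_features(feature_spec(n_genes = 120, n_features = 20,
                                          n_informative = 10, effect_size = 0,
                                          n_positives = 20, seed = s))
    x <- as.matrix(sim$features[-1])
    pos <- sim$features$gene %in% sim$positives
    apply(x, 2, function(v) stats::t.test(v[pos], v[!pos])$p.value)
  }))
  expect_gte(mean(pvals >= 0.01), 0.95)
})

test_that("informative columns are shifted by the stated effect size", {
  sim <- generate_features(feature_spec(n_genes = 4000, n_features = 6,
                                        n_informative = 3, effect_size = 1.5,
                                        n_positives = 2000, seed = 8))
  x <- as.matrix(sim$features[-1])
  pos <- sim$features$gene %in% sim$positives
  shifts <- colMeans(x[pos, ]) - colMeans(x[!pos, ])
  expect_equal(unname(shifts[1:3]), rep(1.5, 3), tolerance = 0.1)
  expect_equal(unname(shifts[4:6]), rep(0, 3), tolerance = 0.1)
})

test_that("degenerate feature specs are configuration errors", {
  expect_error(feature_spec(n_genes = 100, n_positives = 100),
               class = "autolit_config_error")
  expect_error(feature_spec(n_genes = 100, n_features = 5, n_informative = 6),
               class = "autolit_config_error")
})

test_that("toy ontologies have the perfect-tree term count", {
  toy <- generate_toy_ontology(depth = 3, branching = 2, n_genes = 5, seed = 1)
  expect_length(toy$dag$terms, 15)  # 2^4 - 1
  toy3 <- generate_toy_ontology(depth = 2, branching = 3, n_genes = 5, seed = 1)
  expect_length(toy3$dag$terms, 13) # 1 + 3 + 9
  # every gene annotated to at least one term, all terms exist
  expect_true(all(unique(toy$annotations$gene) == sprintf("g%04d", 1:5)))
  expect_true(all(toy$annotations$term %in% toy$dag$terms))
})

test_that("single-level ontology gives zero similarity across distinct leaves", {
  toy <- generate_toy_ontology(depth = 1, branching = 2, n_genes = 6, seed = 3)
  leaves <- setdiff(toy$dag$terms, toy$dag$root)
  ann <- tibble::tibble(gene = c("ga", "gb"), term = leaves[1:2])
  ic <- compute_ic(toy$dag, propagate_annotations(toy$dag, ann))
  # only shared ancestor is the root, whose IC is 0
  expect_equal(gene_similarity("ga", "gb", toy$dag, ic, ann), 0)
})

test_that("identical leaf annotation sets give gene similarity 1", {
  toy <- generate_toy_ontology(depth = 2, branching = 2, n_genes = 4, seed = 2)
  ann <- tibble::tibble(gene = c("gx", "gx", "gy", "gy"),
                        term = rep(tail(toy$dag$terms, 2), 2))
  ann <- dplyr::bind_rows(ann, toy$annotations)
  ic <- compute_ic(toy$dag, propagate_annotations(toy$dag, ann))
  expect_equal(gene_similarity("gx", "gy", toy$dag, ic, ann), 1)
})

test_that("packaged fixtures carry the documented totals", {
  t1 <- load_fixture("table1_counts")
  expect_equal(nrow(t1), 22)
  expect_equal(sum(t1$original_count), 6215)
  expect_equal(sum(t1$filtered_count), 2557)
  expect_equal(sum(t1$ad_count), 378)
  expect_equal(t1$ad_count[t1$class == "Cancer"], 65L)
  expect_equal(unname(unlist(t1[t1$class == "Urogenital disease", -1])),
               c(10L, 5L, 2L))
  adgs <- load_fixture("table2_adgs")
  expect_length(adgs, 61)
  expect_true(all(c("AKT2", "BECN1", "WRN") %in% adgs))
  expect_error(load_fixture("nope"), class = "autolit_lookup_error")
})
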