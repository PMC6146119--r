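test_that("annotation propagation follows the true-path rule and is idempotent", {
  ch <- chain_dag()
  pa <- propagate_annotations(ch$dag, tibble::tibble(gene = "g1", term = "B"))
  expect_setequal(pa$term, c("root", "A", "B"))
  expect_equal(propagate_annotations(ch$dag, pa), pa)
  empty <- propagate_annotations(ch$dag, tibble::tibble(gene = character(),
                                                        term = character()))
  expect_equal(nrow(empty), 0)
  expect_error(
    propagate_annotations(ch$dag, tibble::tibble(gene = "g", term = "nope")),
    class = "autolit_validation_error")
})

test_that("information content matches closed forms", {
  ch <- chain_dag()
  ic <- compute_ic(ch$dag, propagate_annotations(ch$dag, ch$ann))
  icv <- setNames(ic$ic, ic$term)
  expect_equal(unname(icv["root"]), 0)
  expect_equal(unname(icv["A"]), log(2))  # 2 of 4 genes
  expect_equal(unname(icv["B"]), log(4))  # 1 of 4 genes
  # zero-annotation terms are flagged, not infinite
  dag2 <- autolit:::new_ontology_dag(c("r", "x"), list(r = character(), x = "r"))
  ic2 <- compute_ic(dag2, tibble::tibble(gene = "g", term = "r"))
  expect_true(is.na(ic2$ic[ic2$term == "x"]))
})

test_that("IC never decreases from parent to child", {
  for (s in 1:5) {
    dag <- random_toy_dag(10, seed = s)
    ann <- random_annotations(dag, 12, seed = s + 50)
    ic <- compute_ic(dag, propagate_annotations(dag, ann))
    icv <- setNames(ic$ic, ic$term)
    for (child in dag$terms) {
      for (parent in dag$parents[[child]]) {
        if (!is.na(icv[child]) && !is.na(icv[parent])) {
          expect_gte(icv[child], icv[parent])
        }
      }
    }
  }
})

test_that("Lin similarity closed forms hold on the chain ontology", {
  ch <- chain_dag()
  ic <- compute_ic(ch$dag, propagate_annotations(ch$dag, ch$ann))
  # identical informative terms
  expect_equal(lin_term_similarity("B", "B", ch$dag, ic), 1)
  # chain: MICA(A, B) = A, sim = 2 ln2 / (ln2 + ln4) = 2/3 exactly
  expect_equal(lin_term_similarity("A", "B", ch$dag, ic), 2 / 3, tolerance = 1e-12)
  # both root-like: convention 0
  expect_equal(lin_term_similarity("root", "root", ch$dag, ic), 0)
})

test_that("siblings whose only shared ancestor is the root have similarity 0", {
  dag <- autolit:::new_ontology_dag(
    c("r", "a", "b"), list(r = character(), a = "r", b = "r"))
  ann <- tibble::tibble(gene = c("g1", "g2", "g3"), term = c("a", "b", "r"))
  ic <- compute_ic(dag, propagate_annotations(dag, ann))
  expect_equal(lin_term_similarity("a", "b", dag, ic), 0)
})

test_that("Lin similarity is symmetric and bounded on random DAGs, with MICA matching the oracle", {
  for (s in 1:6) {
    dag <- random_toy_dag(sample(5:12, 1), seed = s)
    ann <- random_annotations(dag, 10, seed = s + 20)
    ic <- compute_ic(dag, propagate_annotations(dag, ann))
    icv <- setNames(ic$ic, ic$term)
    anc <- autolit:::term_ancestors(dag)
    defined <- ic$term[!is.na(ic$ic)]
    set.seed(s)
    for (i in 1:10) {
      ts <- sample(defined, 2, replace = TRUE)
      sim <- lin_term_similarity(ts[1], ts[2], dag, ic)
      expect_gte(sim, 0); expect_lte(sim, 1)
      expect_equal(sim, lin_term_similarity(ts[2], ts[1], dag, ic))
      # MICA IC from the brute-force climb oracle
      mica_ic <- enum_mica_ic(ts[1], ts[2], dag, icv)
      denom <- icv[ts[1]] + icv[ts[2]]
      expected <- if (denom == 0) 0 else 2 * mica_ic / denom
      expect_equal(sim, unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("gene-level best-match average reduces correctly", {
  ch <- chain_dag()
  ic <- compute_ic(ch$dag, propagate_annotations(ch$dag, ch$ann))
  ann <- tibble::tibble(gene = c("u", "v"), term = c("A", "B"))
  # single-term genes reduce to the term similarity
  expect_equal(gene_similarity("u", "v", ch$dag, ic, ann), 2 / 3, tolerance = 1e-12)
  expect_equal(gene_similarity("u", "u", ch$dag, ic, ann), 1)
  # unannotated gene is flagged undefined
  expect_true(is.na(gene_similarity("u", "ghost", ch$dag, ic, ann)))
})

test_that("funSimMax takes the larger directional average", {
  dag <- autolit:::new_ontology_dag(
    c("r", "a", "b", "c"), list(r = character(), a = "r", b = "r", c = "a"))
  ann_ic <- tibble::tibble(gene = sprintf("g%d", 1:8),
                           term = c("a", "a", "b", "b", "c", "r", "r", "r"))
  ic <- compute_ic(dag, propagate_annotations(dag, ann_ic))
  ann <- tibble::tibble(gene = c("x", "y", "y"), term = c("c", "c", "b"))
  bma <- gene_similarity("x", "y", dag, ic, ann, method = "bma")
  fsm <- gene_similarity("x", "y", dag, ic, ann, method = "funSimMax")
  expect_gte(fsm, bma)
  expect_equal(fsm, 1)  # direction x->y attains 1 via the shared term c
})

test_that("group consistency separates signal groups from unrelated groups", {
  toy <- generate_toy_ontology(depth = 3, branching = 2, n_genes = 2, seed = 13)
  leaves <- setdiff(toy$dag$terms, unique(unlist(toy$dag$parents)))
  ref_leaves <- leaves[1:2]
  other_leaves <- leaves[5:8]
  reference <- sprintf("ref%02d", 1:5)
  group_a <- sprintf("ga%02d", 1:4)   # shares the reference's leaves
  group_b <- sprintf("gb%02d", 1:4)   # annotated elsewhere
  set.seed(3)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = reference, term = sample(ref_leaves, 5, replace = TRUE)),
    tibble::tibble(gene = group_a, term = sample(ref_leaves, 4, replace = TRUE)),
    tibble::tibble(gene = group_b, term = sample(other_leaves, 4, replace = TRUE)))
  ic <- compute_ic(toy$dag, propagate_annotations(toy$dag, ann))
  gc <- group_consistency(list(A = group_a, B = group_b), reference,
                          toy$dag, ic, ann, n_background = 50, n_boot = 50,
                          seed = 4)
  expect_gt(gc$cross_mean[gc$group == "A"], gc$cross_mean[gc$group == "B"])
  bg <- glance(gc)
  expect_gte(bg$background_mean, 0)
  expect_lte(bg$background_mean, 1)
  # a group equal to the reference has cross similarity 1 when every
  # reference gene shares a single informative leaf
  ann_same <- dplyr::bind_rows(
    tibble::tibble(gene = c(reference, "z1"), term = leaves[1]),
    tibble::tibble(gene = "z2", term = leaves[2]))  # keeps leaf 1 informative
  ic_same <- compute_ic(toy$dag, propagate_annotations(toy$dag, ann_same))
  gc_same <- group_consistency(list(S = reference), reference, toy$dag,
                               ic_same, ann_same, n_background = 20,
                               n_boot = 20, seed = 5)
  expect_equal(gc_same$cross_mean, 1)
  # empty groups are reported undefined, not errors
  gc_empty <- group_consistency(list(E = character()), reference, toy$dag,
                                ic, ann, n_background = 20, n_boot = 20, seed = 6)
  expect_true(is.na(gc_empty$cross_mean))
})

test_that("the OBO-subset reader builds a validated DAG", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "namespace: toy", "",
    "[Term]", "id: T:2", "name: mid", "namespace: toy", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: leaf", "namespace: toy", "is_a: T:2", ""), path)
  dag <- read_obo(path)
  expect_equal(dag$root, "T:1")
  expect_equal(dag$parents[["T:3"]], "T:2")

  toy <- generate_toy_ontology(2, 2, 3, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".obo")
  write_obo(toy$dag, p2)
  back <- read_obo(p2)
  expect_setequal(back$terms, toy$dag$terms)
  expect_equal(back$parents[toy$dag$terms], toy$dag$parents)

  # two roots violate the single-root invariant
  writeLines(c("[Term]", "id: a", "", "[Term]", "id: b"), path)
  expect_error(read_obo(path), class = "autolit_validation_error")
  # multi-namespace files must be pre-split
  writeLines(c("[Term]", "id: a", "namespace: one", "",
               "[Term]", "id: b", "namespace: two", "is_a: a"), path)
  expect_error(read_obo(path), class = "autolit_validation_error")
})
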