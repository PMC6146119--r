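# shared builders for small test objects

toy_lexicon <- function(n_classes = 6, per_class = 5) {
  classes <- LETTERS[seq_len(n_classes)]
  merge_lexicon(data.frame(
    name = paste("disease", rep(classes, each = per_class), seq_len(per_class)),
    class = rep(classes, each = per_class)
  ))
}

# lexicon over the 22 packaged disease classes
table1_lexicon <- function(per_class = 5) {
  classes <- load_fixture("table1_counts")$class
  merge_lexicon(data.frame(
    name = paste(rep(tolower(classes), each = per_class), "disorder",
                 seq_len(per_class)),
    class = rep(classes, each = per_class)
  ))
}

# chain ontology root -> A -> B with gene annotations giving
# IC(A) = ln 2 and IC(B) = ln 4
chain_dag <- function() {
  dag <- autolit:::new_ontology_dag(
    c("root", "A", "B"),
    list(root = character(), A = "root", B = "A"))
  ann <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("B", "A", "root", "root"))
  list(dag = dag, ann = ann)
}

# random small DAG: a tree with random extra is-a edges (still acyclic)
random_toy_dag <- function(n_terms, seed) {
  set.seed(seed)
  terms <- sprintf("t%02d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- terms
  parents[[1]] <- character()
  for (i in seq_len(n_terms)[-1]) {
    parents[[i]] <- terms[sample.int(i - 1, 1)]
    if (i > 2 && runif(1) < 0.3) {
      extra <- terms[sample.int(i - 1, 1)]
      parents[[i]] <- unique(c(parents[[i]], extra))
    }
  }
  autolit:::new_ontology_dag(terms, parents)
}

random_annotations <- function(dag, n_genes, seed) {
  set.seed(seed)
  tibble::tibble(
    gene = rep(sprintf("g%02d", seq_len(n_genes)), each = 2),
    term = sample(dag$terms, 2 * n_genes, replace = TRUE)
  ) |> dplyr::distinct()
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw k items from N with M marked, P(at least n marked)
enum_upper_tail <- function(N, M, n, k = n) {
  if (n == 0) return(1)
  draws <- combn(N, k)
  mean(colSums(draws <= M) >= n)
}

# brute-force MICA by enumerating all common ancestors (climbing loops,
# independent of the package's topological-order implementation)
enum_mica_ic <- function(t1, t2, dag, icv) {
  climb <- function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
    }
    seen
  }
  common <- intersect(climb(t1), climb(t2))
  common <- common[!is.na(icv[common])]
  if (!length(common)) return(NA_real_)
  max(icv[common])
}
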