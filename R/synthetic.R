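#' Specification for a synthetic literature corpus
#'
#' Describes a corpus generator whose documents each mention at least one
#' disease: the per-document mention count is zero-truncated Poisson
#' (emulating a corpus pre-filtered to disease-mentioning papers), each
#' mention's class is drawn from the normalized `class_weights`, the
#' disease within a class is uniform, and chosen class pairs can be given a
#' co-mention excess via `comention_boost`.
#'
#' A boost of b for pair (A, B) makes the pair's joint mention probability
#' about b times the independent baseline: with probability
#' `min(1, (b - 1) * p_joint)` — where `p_joint` is the joint probability a
#' document would mention both classes under independent draws — the
#' document is forced to mention one disease from each of A and B, its
#' remaining mentions drawn independently. Marginals stay approximately
#' intact for moderate boosts.
#'
#' @param n_documents Number of documents (>= 1).
#' @param class_weights Named non-negative numeric vector: relative mention
#'   propensity per disease class. Must cover classes present in the target
#'   lexicon.
#' @param comention_boost Data frame with columns `class_a`, `class_b`,
#'   `boost` (values >= 1), or `NULL` for no planted co-mention structure.
#' @param mentions_per_doc Rate of the underlying Poisson before zero
#'   truncation (default 2.5, a realistic handful of disease mentions per
#'   abstract).
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_documents, class_weights, comention_boost = NULL,
                        mentions_per_doc = 2.5, seed = 1) {
  if (!is_count(n_documents) || n_documents < 1) {
    stop_config("`n_documents` must be a positive integer.")
  }
  if (is.null(names(class_weights)) || any(!nzchar(names(class_weights))) ||
      !is.numeric(class_weights) || any(class_weights < 0) || sum(class_weights) <= 0) {
    stop_config("`class_weights` must be a named non-negative vector with positive sum.")
  }
  if (!is.null(comention_boost)) {
    if (!is.data.frame(comention_boost) ||
        !all(c("class_a", "class_b", "boost") %in% names(comention_boost))) {
      stop_config("`comention_boost` needs columns `class_a`, `class_b`, `boost`.")
    }
    if (any(comention_boost$boost < 1)) stop_config("Boost values must be >= 1.")
  }
  if (!is.numeric(mentions_per_doc) || mentions_per_doc <= 0) {
    stop_config("`mentions_per_doc` must be positive.")
  }
  if (!is_count(seed)) stop_config("`seed` must be an integer.")
  structure(list(
    n_documents = as.integer(n_documents),
    class_weights = class_weights / sum(class_weights),
    comention_boost = comention_boost,
    mentions_per_doc = mentions_per_doc,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

# P(a document mentions both classes) under independent multinomial draws,
# averaged over the zero-truncated Poisson mention count
joint_mention_prob <- function(pa, pb, lambda, kmax = 100) {
  k <- seq_len(kmax)
  w <- dpois(k, lambda) / (1 - dpois(0, lambda))
  sum(w * (1 - (1 - pa)^k - (1 - pb)^k + pmax(0, 1 - pa - pb)^k))
}

#' Generate a synthetic scanned corpus
#'
#' Draws per-document disease mention sets with the structure described in
#' [corpus_spec()]. Output is a `scan_result` (mention sets, not free
#' text), ready for [tally_classes()] and [pairwise_association()]. Every
#' document mentions at least one disease by construction.
#'
#' @param spec A [corpus_spec()].
#' @param lexicon A `disease_lexicon` supplying diseases per class; every
#'   class named in the spec must exist in the lexicon.
#' @return A `scan_result` with `spec$n_documents` rows.
#' @export
#' @examples
#' lex <- merge_lexicon(data.frame(
#'   name = paste("disease", 1:6), class = rep(c("A", "B", "C"), 2)))
#' sc <- generate_corpus(corpus_spec(100, c(A = 1, B = 1, C = 1), seed = 1), lex)
#' nrow(sc)
generate_corpus <- function(spec, lexicon) {
  if (!inherits(spec, "corpus_spec")) stop_config("`spec` must come from corpus_spec().")
  if (nrow(lexicon) == 0) stop_validation("Lexicon is empty.")
  classes <- names(spec$class_weights)
  unknown <- setdiff(classes, lexicon_classes(lexicon))
  if (length(unknown)) {
    stop_config(sprintf("Classes in spec not present in lexicon: %s",
                        paste(unknown, collapse = ", ")))
  }
  boosted <- spec$comention_boost
  if (!is.null(boosted)) {
    unknown <- setdiff(c(boosted$class_a, boosted$class_b), classes)
    if (length(unknown)) {
      stop_config(sprintf("Boosted classes missing from class_weights: %s",
                          paste(unknown, collapse = ", ")))
    }
  }
  diseases_by_class <- split(lexicon$canonical, lexicon$class)[classes]
  w <- spec$class_weights
  lambda <- spec$mentions_per_doc
  ndoc <- spec$n_documents

  set.seed(spec$seed)
  # zero-truncated Poisson via inverse cdf on u in (P(0), 1)
  k <- qpois(runif(ndoc, dpois(0, lambda), 1), lambda)

  forced <- vector("list", ndoc)
  if (!is.null(boosted) && nrow(boosted) > 0) {
    for (r in seq_len(nrow(boosted))) {
      pa <- w[boosted$class_a[r]]; pb <- w[boosted$class_b[r]]
      pi_r <- min(1, (boosted$boost[r] - 1) * joint_mention_prob(pa, pb, lambda))
      hit <- which(runif(ndoc) < pi_r)
      for (d in hit) {
        forced[[d]] <- c(forced[[d]], boosted$class_a[r], boosted$class_b[r])
      }
    }
  }
  n_forced <- lengths(forced)
  k <- pmax(k, n_forced)
  n_free <- k - n_forced
  free_cls <- sample(classes, sum(n_free), replace = TRUE, prob = w)
  doc_of_free <- rep(seq_len(ndoc), n_free)

  # vectorized uniform disease choice within each mention's class
  pick_many <- function(cls_vec) {
    out <- character(length(cls_vec))
    for (cl in unique(cls_vec)) {
      idx <- which(cls_vec == cl)
      pool <- diseases_by_class[[cl]]
      out[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
    out
  }
  free_dis <- pick_many(free_cls)
  forced_dis <- lapply(forced, function(cls) if (length(cls)) pick_many(cls) else character())
  free_split <- split(free_dis, factor(doc_of_free, levels = seq_len(ndoc)))
  diseases <- purrr::map(seq_len(ndoc), function(d) {
    unique(c(forced_dis[[d]], free_split[[d]]))
  })

  new_scan_result(
    tibble(doc_id = sprintf("doc%06d", seq_len(ndoc)), diseases = diseases),
    lexicon_version = attr(lexicon, "lexicon_version")
  )
}

#' Specification for a synthetic gene feature matrix
#'
#' Emulates a gene-by-feature panel of epigenomic and transcription-factor
#' binding-site signals in which a subset of features separates a positive
#' gene set from the background: informative features have their mean
#' shifted by `effect_size` standard deviations in positives.
#'
#' @param n_genes Number of genes.
#' @param n_features Number of features (default 50, a realistic panel of
#'   histone-mark and TFBS summary signals).
#' @param n_informative Number of features carrying signal, in
#'   `[0, n_features]`.
#' @param effect_size Standardized mean shift of informative features in
#'   positives.
#' @param n_positives Number of positive genes (< `n_genes`).
#' @param binary If `TRUE`, features are Bernoulli (presence/absence
#'   signals) with the informative-feature success probability shifted by
#'   `effect_size` on the log-odds scale, instead of Gaussian.
#' @param seed Integer seed.
#' @return A `feature_spec` list.
#' @export
feature_spec <- function(n_genes, n_features = 50, n_informative = 10,
                         effect_size = 2, n_positives = 60,
                         binary = FALSE, seed = 1) {
  if (!is_count(n_genes) || n_genes < 2) stop_config("`n_genes` must be an integer >= 2.")
  if (!is_count(n_features) || n_features < 1) stop_config("`n_features` must be a positive integer.")
  if (!is_count(n_informative) || n_informative < 0 || n_informative > n_features) {
    stop_config("`n_informative` must lie in [0, n_features].")
  }
  if (!is_count(n_positives) || n_positives < 1 || n_positives >= n_genes) {
    stop_config("`n_positives` must be a positive integer smaller than `n_genes`.")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 || is.na(effect_size)) {
    stop_config("`effect_size` must be a number.")
  }
  if (!is_count(seed)) stop_config("`seed` must be an integer.")
  structure(list(
    n_genes = as.integer(n_genes), n_features = as.integer(n_features),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    n_positives = as.integer(n_positives), binary = isTRUE(binary),
    seed = as.integer(seed)
  ), class = "feature_spec")
}

#' Generate a synthetic gene feature matrix with a planted positive set
#'
#' @param spec A [feature_spec()].
#' @return List with `features` (tibble: `gene` column + feature columns
#'   `f001`, ...) and `positives` (character vector of planted positive
#'   genes). The first `n_informative` feature columns carry the signal.
#' @export
#' @examples
#' sim <- generate_features(feature_spec(n_genes = 100, n_positives = 10, seed = 1))
#' dim(sim$features)
generate_features <- function(spec) {
  if (!inherits(spec, "feature_spec")) stop_config("`spec` must come from feature_spec().")
  set.seed(spec$seed)
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  positives <- sort(sample(genes, spec$n_positives))
  is_pos <- genes %in% positives
  if (spec$binary) {
    p0 <- 0.3
    p1 <- plogis(qlogis(p0) + spec$effect_size)
    x <- matrix(rbinom(spec$n_genes * spec$n_features, 1, p0),
                spec$n_genes, spec$n_features)
    if (spec$n_informative > 0) {
      x[is_pos, seq_len(spec$n_informative)] <-
        rbinom(sum(is_pos) * spec$n_informative, 1, p1)
    }
  } else {
    x <- matrix(rnorm(spec$n_genes * spec$n_features),
                spec$n_genes, spec$n_features)
    if (spec$n_informative > 0) {
      x[is_pos, seq_len(spec$n_informative)] <-
        x[is_pos, seq_len(spec$n_informative)] + spec$effect_size
    }
  }
  colnames(x) <- sprintf("f%03d", seq_len(spec$n_features))
  features <- bind_cols(tibble(gene = genes), as_tibble(x))
  list(features = features, positives = positives)
}

#' Generate a toy ontology with annotations
#'
#' Builds a perfect is-a tree with `branching` children per term down to
#' `depth` levels below the root (`(branching^(depth+1) - 1)/(branching - 1)`
#' terms) and annotates each gene directly to one or two random leaf terms,
#' so annotation frequencies — and hence information content — are
#' well-defined after propagation.
#'
#' @param depth Levels below the root (>= 1).
#' @param branching Children per internal term (>= 1).
#' @param n_genes Number of genes to annotate.
#' @param seed Integer seed.
#' @return List with `dag` (an `ontology_dag`) and `annotations` (tibble
#'   `gene`, `term` of direct leaf annotations).
#' @export
#' @examples
#' toy <- generate_toy_ontology(depth = 3, branching = 2, n_genes = 10, seed = 1)
#' length(toy$dag$terms)
generate_toy_ontology <- function(depth, branching, n_genes, seed = 1) {
  if (!is_count(depth) || depth < 1) stop_config("`depth` must be a positive integer.")
  if (!is_count(branching) || branching < 1) stop_config("`branching` must be a positive integer.")
  if (!is_count(n_genes) || n_genes < 1) stop_config("`n_genes` must be a positive integer.")
  if (!is_count(seed)) stop_config("`seed` must be an integer.")

  terms <- "T:0001"
  parents <- list(`T:0001` = character())
  level <- list("T:0001")
  nxt <- 2L
  for (d in seq_len(depth)) {
    new_level <- character()
    for (p in level[[d]]) {
      for (b in seq_len(branching)) {
        id <- sprintf("T:%04d", nxt); nxt <- nxt + 1L
        parents[[id]] <- p
        new_level <- c(new_level, id)
      }
    }
    level[[d + 1]] <- new_level
    terms <- c(terms, new_level)
  }
  dag <- new_ontology_dag(terms, parents, namespace = "toy")
  leaves <- level[[depth + 1]]

  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  annotations <- purrr::map(genes, function(g) {
    n_terms <- sample(1:min(2, length(leaves)), 1)
    tibble(gene = g, term = sample(leaves, n_terms))
  }) |> bind_rows()
  list(dag = dag, annotations = annotations)
}

#' Write a toy ontology to OBO-subset format
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  chunk <- function(t) {
    pars <- dag$parents[[t]]
    c("[Term]", paste0("id: ", t), paste0("name: ", t),
      paste0("namespace: ", dag$namespace %||% "toy"),
      if (length(pars)) paste0("is_a: ", pars), "")
  }
  writeLines(c("format-version: 1.2", "",
               unlist(purrr::map(dag$terms, chunk))), path, useBytes = TRUE)
  invisible(path)
}

#' Load a packaged fixture table
#'
#' Two tables from the original study ship with the package as TSV/text:
#' `"table1_counts"` — per-class counts of the 22 disease classes in the
#' original vocabulary (6215 names), the merged lexicon (2557 diseases)
#' and the diseases hit in autophagy papers (378); and `"table2_adgs"` —
#' the 61 curated autophagy-disease gene symbols used as the positive set.
#'
#' @param name `"table1_counts"` or `"table2_adgs"`.
#' @return For `"table1_counts"`, a tibble with columns `class`,
#'   `original_count`, `filtered_count`, `ad_count`; for `"table2_adgs"`, a
#'   character vector of 61 gene symbols.
#' @export
#' @examples
#' sum(load_fixture("table1_counts")$ad_count)
#' length(load_fixture("table2_adgs"))
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("table1_counts", "table2_adgs")) {
    stop_lookup("Unknown fixture; available: table1_counts, table2_adgs.")
  }
  if (name == "table1_counts") {
    lines <- readLines(path_fixture("table1_counts.tsv"), encoding = "UTF-8")
    parts <- stringr::str_split(lines[-1], "\t")
    tibble(
      class = purrr::map_chr(parts, 1),
      original_count = as.integer(purrr::map_chr(parts, 2)),
      filtered_count = as.integer(purrr::map_chr(parts, 3)),
      ad_count = as.integer(purrr::map_chr(parts, 4))
    )
  } else {
    readLines(path_fixture("table2_adgs.txt"), encoding = "UTF-8")
  }
}
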