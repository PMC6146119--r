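dag_graph <- function(terms, parents) {
  edges <- data.frame(
    from = rep(names(parents), lengths(parents)),
    to = unlist(parents, use.names = FALSE) %||% character(0)
  )
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = terms))
}

new_ontology_dag <- function(terms, parents, namespace = NA_character_) {
  # parents: named list, term -> character vector of parent term ids
  all_parents <- unique(unlist(parents))
  unknown <- setdiff(all_parents, terms)
  if (length(unknown)) {
    stop_validation(sprintf("is_a parents not defined as terms: %s",
                            paste(head(unknown, 5), collapse = ", ")))
  }
  roots <- terms[lengths(parents[terms]) == 0]
  if (length(roots) != 1) {
    stop_validation(sprintf(
      "Ontology must have exactly one root per namespace (found %d: %s). Multi-namespace inputs must be pre-split.",
      length(roots), paste(head(roots, 5), collapse = ", ")))
  }
  g <- dag_graph(terms, parents)
  if (!igraph::is_dag(g)) stop_validation("Ontology contains a cycle.")
  structure(list(terms = terms, parents = parents[terms], root = roots,
                 namespace = namespace),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, root %s\n", length(x$terms), x$root))
  invisible(x)
}

#' Read a minimal OBO-subset ontology
#'
#' Parses only `[Term]` stanzas with `id:`, `name:`, `namespace:` and
#' `is_a:` lines (trailing `! comments` stripped) — the subset needed to
#' build an is-a DAG for information-content similarity. Exactly one
#' namespace and one root are required; richer OBO files must be pre-split.
#'
#' @param path Path to the OBO-like file.
#' @return An `ontology_dag`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- stringr::str_trim(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  is_a = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- stringr::str_split_fixed(ln, ":\\s*", 2)
      key <- kv[1]; val <- stringr::str_trim(sub("!.*$", "", kv[2]))
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a" && nzchar(val)) {
        cur$is_a <- c(cur$is_a, strsplit(val, "\\s+")[[1]][1])
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop_parse("No [Term] stanzas found.")
  ns <- unique(stats::na.omit(vapply(terms, `[[`, character(1), "namespace")))
  if (length(ns) > 1) {
    stop_validation(sprintf("Multiple namespaces present (%s); pre-split the file.",
                            paste(ns, collapse = ", ")))
  }
  ids <- names(terms)
  new_ontology_dag(ids, lapply(terms, `[[`, "is_a"),
                   namespace = if (length(ns)) ns else NA_character_)
}

# all ancestors of each term, inclusive of the term itself (the reflexive
# closure is what MICA and annotation propagation both want)
term_ancestors <- function(dag) {
  anc <- vector("list", length(dag$terms))
  names(anc) <- dag$terms
  # topological order root-first so parents are always resolved
  ord <- rev(names(igraph::topo_sort(dag_graph(dag$terms, dag$parents), mode = "out")))
  for (t in ord) {
    anc[[t]] <- unique(c(t, unlist(anc[dag$parents[[t]]], use.names = FALSE)))
  }
  anc
}

check_annotations <- function(dag, ann) {
  if (!is.data.frame(ann) || !all(c("gene", "term") %in% names(ann))) {
    stop_validation("Annotations must be a data frame with columns `gene`, `term`.")
  }
  unknown <- setdiff(unique(ann$term), dag$terms)
  if (length(unknown)) {
    stop_validation(sprintf("Annotation terms absent from the ontology: %s",
                            paste(head(unknown, 5), collapse = ", ")))
  }
  invisible(ann)
}

#' Propagate gene annotations to ancestor terms
#'
#' The true-path rule: a gene annotated to a term is implicitly annotated
#' to every ancestor of that term. Information-content computation requires
#' propagated annotations; propagation is explicit here, never implicit,
#' and idempotent.
#'
#' @param dag An `ontology_dag`.
#' @param ann Data frame with columns `gene`, `term` (direct annotations).
#' @return Tibble of distinct `(gene, term)` rows after propagation.
#' @export
propagate_annotations <- function(dag, ann) {
  check_annotations(dag, ann)
  if (nrow(ann) == 0) return(tibble(gene = character(), term = character()))
  anc <- term_ancestors(dag)
  as_tibble(ann) |>
    mutate(term = anc[.data$term]) |>
    tidyr::unnest("term") |>
    distinct(.data$gene, .data$term) |>
    arrange(.data$gene, .data$term)
}

#' Information content of ontology terms
#'
#' For propagated annotations, `IC(t) = -ln(n_t / n_root)` where `n_t` is
#' the number of genes annotated to `t`. The root's IC is 0 by definition;
#' terms annotated to no gene have undefined IC (`NA`, flagged, and
#' excluded from MICA candidacy downstream).
#'
#' @param dag An `ontology_dag`.
#' @param ann Propagated annotations (see [propagate_annotations()]).
#' @return An `ic_table` tibble: `term`, `n_genes`, `ic`.
#' @export
compute_ic <- function(dag, ann) {
  check_annotations(dag, ann)
  if (nrow(ann) == 0) stop_validation("Need at least one annotated gene.")
  cnt <- as_tibble(ann) |> count(.data$term, name = "n_genes")
  out <- tibble(term = dag$terms) |>
    left_join(cnt, by = "term") |>
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))
  n_root <- out$n_genes[out$term == dag$root]
  if (n_root == 0) stop_validation("No gene reaches the root; are annotations propagated?")
  out |> mutate(ic = ifelse(.data$n_genes > 0, -log(.data$n_genes / n_root), NA_real_))
}

ic_lookup <- function(ic) setNames(ic$ic, ic$term)

#' Lin similarity between two ontology terms
#'
#' `sim(t1, t2) = 2 IC(MICA) / (IC(t1) + IC(t2))`, where the MICA is the
#' common ancestor (reflexive) with maximal information content. Bounded in
#' `[0, 1]`; defined as 0 when both terms carry zero information (root-like),
#' and 1 for identical informative terms.
#'
#' @param t1,t2 Term ids.
#' @param dag An `ontology_dag`.
#' @param ic An `ic_table` from [compute_ic()].
#' @return Similarity in `[0, 1]`.
#' @export
lin_term_similarity <- function(t1, t2, dag, ic) {
  anc <- term_ancestors(dag)
  lin_from_ancestors(t1, t2, anc, ic_lookup(ic))
}

lin_from_ancestors <- function(t1, t2, anc, icv) {
  for (t in c(t1, t2)) {
    if (!t %in% names(anc)) stop_validation(sprintf("Unknown term: %s", t))
    if (is.na(icv[t])) stop_validation(sprintf("Term %s has undefined IC.", t))
  }
  common <- intersect(anc[[t1]], anc[[t2]])
  common <- common[!is.na(icv[common])]
  if (!length(common)) {
    stop_validation("Terms share no common ancestor (single-root invariant violated).")
  }
  denom <- icv[t1] + icv[t2]
  if (denom == 0) return(0)
  unname(2 * max(icv[common]) / denom)
}

#' Functional similarity between two genes
#'
#' Combines term-level Lin similarities over the genes' direct annotation
#' sets. The default, the symmetric best-match average (BMA), averages each
#' gene's per-term best match against the other gene's terms and then
#' averages the two directions; `"funSimMax"` takes the maximum of the two
#' directional averages instead.
#'
#' @param g1,g2 Gene identifiers.
#' @param dag An `ontology_dag`.
#' @param ic An `ic_table` (from propagated annotations).
#' @param ann Direct annotations (`gene`, `term`).
#' @param method `"bma"` (default) or `"funSimMax"`.
#' @return Similarity in `[0, 1]`, or `NA` if either gene is unannotated.
#' @export
gene_similarity <- function(g1, g2, dag, ic, ann, method = c("bma", "funSimMax")) {
  method <- match.arg(method)
  anc <- term_ancestors(dag)
  icv <- ic_lookup(ic)
  gene_sim_impl(g1, g2, anc, icv, split(ann$term, ann$gene), method)
}

gene_sim_impl <- function(g1, g2, anc, icv, ann_split, method) {
  t1 <- unique(ann_split[[g1]]); t2 <- unique(ann_split[[g2]])
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) return(NA_real_)
  sim <- outer(t1, t2, Vectorize(function(a, b) lin_from_ancestors(a, b, anc, icv)))
  d1 <- mean(apply(sim, 1, max))
  d2 <- mean(apply(sim, 2, max))
  if (method == "bma") (d1 + d2) / 2 else max(d1, d2)
}

#' Function-consistency of gene groups against a reference set
#'
#' For each group of (typically predicted) genes, computes the mean
#' gene-level similarity of group members to a reference set (cross
#' similarity, all group x reference pairs) and among themselves (within
#' similarity), with percentile bootstrap confidence intervals over the
#' pair similarities. A background mean over random annotated-gene pairs
#' from the supplied annotation universe is recomputed alongside — it is a
#' property of the annotation corpus in use, not a universal constant.
#'
#' @param groups Named list of character vectors of genes.
#' @param reference Character vector of reference genes.
#' @param dag An `ontology_dag`.
#' @param ic An `ic_table` (propagated-annotation IC).
#' @param ann Direct annotations (`gene`, `term`).
#' @param method Gene-level combination, as in [gene_similarity()].
#' @param n_background Number of random background pairs (default 200).
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for background sampling and bootstrap.
#' @return A `group_consistency` tibble: per group, `n_genes`,
#'   `cross_mean`, `cross_lo`, `cross_hi`, `within_mean`, `within_lo`,
#'   `within_hi` (undefined summaries are `NA`); the background mean and CI
#'   are in the `background` attribute and in [glance.group_consistency()].
#' @export
group_consistency <- function(groups, reference, dag, ic, ann,
                              method = c("bma", "funSimMax"),
                              n_background = 200, n_boot = 200,
                              conf = 0.95, seed = 1) {
  method <- match.arg(method)
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop_validation("`groups` must be a named list of gene vectors.")
  }
  anc <- term_ancestors(dag)
  icv <- ic_lookup(ic)
  ann_split <- split(ann$term, ann$gene)
  sim_cache <- new.env(parent = emptyenv())
  psim <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    v <- gene_sim_impl(a, b, anc, icv, ann_split, method)
    sim_cache[[key]] <- v
    v
  }
  pair_sims <- function(ga, gb, exclude_self = FALSE) {
    pairs <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
    if (exclude_self) pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
    if (!nrow(pairs)) return(numeric())
    purrr::map2_dbl(pairs$a, pairs$b, psim)
  }
  boot_ci <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1))
    a <- (1 - conf) / 2
    c(mean(v), unname(stats::quantile(bm, c(a, 1 - a))))
  }

  set.seed(seed)
  rows <- purrr::imap(groups, function(g, nm) {
    g <- unique(g)
    cross <- boot_ci(pair_sims(g, setdiff(reference, character(0))))
    within <- boot_ci(pair_sims(g, g, exclude_self = TRUE))
    tibble(group = nm, n_genes = length(g),
           cross_mean = cross[1], cross_lo = cross[2], cross_hi = cross[3],
           within_mean = within[1], within_lo = within[2], within_hi = within[3])
  })
  universe <- names(ann_split)
  bg_vals <- if (length(universe) >= 2) {
    purrr::map_dbl(seq_len(n_background), function(i) {
      gg <- sample(universe, 2)
      psim(gg[1], gg[2])
    })
  } else numeric()
  bg <- boot_ci(bg_vals)

  out <- bind_rows(rows)
  attr(out, "background") <- list(mean = bg[1], lo = bg[2], hi = bg[3],
                                  n_pairs = length(bg_vals))
  attr(out, "method") <- method
  class(out) <- c("group_consistency", class(out))
  out
}

#' @rdname group_consistency
#' @param x A `group_consistency` object.
#' @param ... Unused.
#' @export
glance.group_consistency <- function(x, ...) {
  bg <- attr(x, "background")
  tibble(background_mean = bg$mean, background_lo = bg$lo,
         background_hi = bg$hi, n_background_pairs = bg$n_pairs,
         method = attr(x, "method"))
}
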