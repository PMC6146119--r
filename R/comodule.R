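doc_class_presence <- function(scan, lexicon) {
  classes <- lexicon_classes(lexicon)
  cls_of <- setNames(lexicon$class, lexicon$canonical)
  pres <- matrix(FALSE, nrow(scan), length(classes),
                 dimnames = list(scan$doc_id, classes))
  doc_idx <- rep(seq_len(nrow(scan)), lengths(scan$diseases))
  dis <- unlist(scan$diseases)
  if (length(dis)) {
    unknown <- setdiff(dis, names(cls_of))
    if (length(unknown)) {
      stop_validation(sprintf("Diseases absent from lexicon: %s",
                              paste(head(unknown, 5), collapse = ", ")))
    }
    pres[cbind(doc_idx, match(cls_of[dis], classes))] <- TRUE
  }
  pres
}

#' Pairwise disease-class association by co-mention
#'
#' For every unordered pair of disease classes, counts documents mentioning
#' each class and both classes, and applies the cumulative hypergeometric
#' upper-tail test ([hypergeom_upper_tail()]). Two parameterizations are
#' available:
#' \describe{
#'   \item{`"literal"`}{`N` = documents mentioning a or b, `M` = documents
#'     mentioning a, draw size = overlap `n`. This draw model is asymmetric
#'     in (a, b); the reported p is the conservative symmetrization
#'     `max(p(a->b), p(b->a))`, and both directed values are kept.}
#'   \item{`"universe"`}{the standard 2x2 co-occurrence test: `N` = all
#'     documents, `M` = documents mentioning a, draw size = documents
#'     mentioning b, observed = overlap. Symmetric in (a, b); this is the
#'     parameterization with controlled type-I error and the one to prefer
#'     for new analyses.}
#' }
#' No multiple-testing correction is applied by default;
#' `p_adjust = "BH"` adds a Benjamini-Hochberg-adjusted column.
#'
#' @param scan A `scan_result`.
#' @param lexicon The `disease_lexicon` used for the scan.
#' @param parameterization `"literal"` (default) or `"universe"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A `pair_association` tibble with one row per unordered pair:
#'   `class_a`, `class_b`, `n_a`, `n_b`, `n_ab`, `p` (and `p_directed_ab`,
#'   `p_directed_ba` for the literal form; `p_adj` if requested). Pairs
#'   involving a class absent from every document have `p = NA`. Attributes
#'   record the parameterization, class set and document count; see
#'   [pair_matrix()].
#' @export
pairwise_association <- function(scan, lexicon,
                                 parameterization = c("literal", "universe"),
                                 p_adjust = c("none", "BH")) {
  parameterization <- match.arg(parameterization)
  p_adjust <- match.arg(p_adjust)
  if (nrow(scan) == 0) stop_validation("Scan result is empty.")
  pres <- doc_class_presence(scan, lexicon)
  classes <- colnames(pres)
  ndoc <- nrow(pres)
  m <- colSums(pres)
  cross <- crossprod(pres)  # co-mention counts

  pairs <- as_tibble(t(combn(classes, 2)), .name_repair = ~ c("class_a", "class_b"))
  pairs <- pairs |>
    mutate(
      n_a = as.integer(m[.data$class_a]),
      n_b = as.integer(m[.data$class_b]),
      n_ab = as.integer(cross[cbind(.data$class_a, .data$class_b)]),
      n_union = .data$n_a + .data$n_b - .data$n_ab
    )

  defined <- pairs$n_a > 0 & pairs$n_b > 0
  p <- rep(NA_real_, nrow(pairs))
  if (parameterization == "literal") {
    pab <- pba <- rep(NA_real_, nrow(pairs))
    d <- which(defined)
    pab[d] <- hypergeom_upper_tail(pairs$n_union[d], pairs$n_a[d], pairs$n_ab[d])
    pba[d] <- hypergeom_upper_tail(pairs$n_union[d], pairs$n_b[d], pairs$n_ab[d])
    p <- pmax(pab, pba)
    pairs$p_directed_ab <- pab
    pairs$p_directed_ba <- pba
  } else {
    d <- which(defined)
    p[d] <- hypergeom_upper_tail(ndoc, pairs$n_a[d], pairs$n_ab[d], k = pairs$n_b[d])
  }
  pairs$p <- p
  if (p_adjust == "BH") pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")

  attr(pairs, "classes") <- classes
  attr(pairs, "parameterization") <- parameterization
  attr(pairs, "p_adjust") <- p_adjust
  attr(pairs, "n_documents") <- ndoc
  class(pairs) <- c("pair_association", class(pairs))
  pairs
}

#' Square matrices of a pairwise association result
#'
#' @param assoc A `pair_association`.
#' @param what `"p"` for p-values (diagonal `NA`) or `"significance"` for
#'   `1 - p`, the display scale on which 1 is maximally significant.
#' @return Symmetric numeric matrix over the class set.
#' @export
pair_matrix <- function(assoc, what = c("p", "significance")) {
  what <- match.arg(what)
  classes <- attr(assoc, "classes")
  mat <- matrix(NA_real_, length(classes), length(classes),
                dimnames = list(classes, classes))
  mat[cbind(assoc$class_a, assoc$class_b)] <- assoc$p
  mat[cbind(assoc$class_b, assoc$class_a)] <- assoc$p
  if (what == "significance") mat <- 1 - mat
  mat
}

#' Extract modules of mutually associated disease classes
#'
#' Builds a graph over classes with an edge wherever the pair's p-value is
#' below `alpha`; modules are the connected components with at least two
#' members. An average-linkage hierarchical ordering of the significance
#' matrix is also returned for heatmap display (membership is defined by
#' the components, not the dendrogram).
#'
#' @param assoc A `pair_association`.
#' @param alpha Significance threshold in (0, 1).
#' @return A `comodule_set`: list with `modules` (list of character
#'   vectors), `ordering` (class ordering for display), `alpha`, and
#'   `method` metadata.
#' @export
extract_modules <- function(assoc, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_validation("`alpha` must be a single number in (0, 1).")
  }
  classes <- attr(assoc, "classes")
  edges <- assoc |> filter(!is.na(.data$p), .data$p < alpha)
  g <- igraph::graph_from_data_frame(
    edges[c("class_a", "class_b")], directed = FALSE,
    vertices = data.frame(name = classes))
  comp <- igraph::components(g)
  members <- split(classes, comp$membership)
  modules <- unname(members[lengths(members) >= 2])
  modules <- modules[order(-lengths(modules))]

  pm <- pair_matrix(assoc, "p")
  pm[is.na(pm)] <- 1
  diag(pm) <- 0
  ordering <- classes[hclust(as.dist(pm), method = "average")$order]

  structure(
    list(modules = modules, ordering = ordering, alpha = alpha,
         method = "connected components of the alpha-thresholded graph",
         parameterization = attr(assoc, "parameterization")),
    class = "comodule_set")
}

#' @export
print.comodule_set <- function(x, ...) {
  cat(sprintf("<comodule_set> %d module(s) at alpha = %g (%s)\n",
              length(x$modules), x$alpha, x$method))
  for (i in seq_along(x$modules)) {
    cat(sprintf("  Module %d: %s\n", i, paste(x$modules[[i]], collapse = ", ")))
  }
  invisible(x)
}
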