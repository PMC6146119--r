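#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class concentration and retention ratios
#'
#' Bar charts of CR (with the neutral line at 1) and RR per class, the
#' standard display for class-composition shifts.
#'
#' @param object A `class_ratios` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_ratios <- function(object, ...) {
  long <- object |>
    select("class", "cr", "rr") |>
    tidyr::pivot_longer(c("cr", "rr"), names_to = "measure", values_to = "value") |>
    mutate(measure = dplyr::recode(.data$measure,
                                   cr = "Concentration ratio",
                                   rr = "Retention ratio"))
  ref <- tibble(measure = "Concentration ratio", y = 1)
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$class, .data$value),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = 2, colour = "red3") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Heatmap of pairwise co-mention significance
#'
#' Tiles show `1 - p` (1 = maximally significant), with classes in the
#' average-linkage display order so associated blocks sit together.
#'
#' @param object A `pair_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_association <- function(object, ...) {
  ordering <- extract_modules(object, alpha = 0.05)$ordering
  m <- pair_matrix(object, "significance")
  long <- as_tibble(m, rownames = "class_a") |>
    tidyr::pivot_longer(-"class_a", names_to = "class_b", values_to = "significance") |>
    mutate(class_a = factor(.data$class_a, ordering),
           class_b = factor(.data$class_b, ordering))
  ggplot2::ggplot(long, ggplot2::aes(.data$class_a, .data$class_b,
                                     fill = .data$significance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - p") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Histogram of possibility scores
#'
#' Full `[0, 1]` histogram alongside the refined `[0.9, 1]` view in which
#' near-top structure (score shelves used as grouping thresholds) becomes
#' visible.
#'
#' @param object An `orfl_scores` or `score_distribution`.
#' @param bins Bins per panel when `object` is `orfl_scores`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orfl_scores <- function(object, bins = 50, ...) {
  autoplot(score_distribution(object, bins = bins))
}

#' @rdname autoplot.orfl_scores
#' @export
autoplot.score_distribution <- function(object, ...) {
  long <- bind_rows(
    object$histogram |> mutate(window = "scores in [0,1]"),
    object$refined |> mutate(window = "refined [0.9,1]")
  ) |>
    mutate(window = factor(.data$window, c("scores in [0,1]", "refined [0.9,1]")))
  ggplot2::ggplot(long, ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                     ymin = 0, ymax = .data$count)) +
    ggplot2::geom_rect(fill = "grey35") +
    ggplot2::facet_wrap(~window, scales = "free") +
    ggplot2::labs(x = "possibility score", y = "genes")
}

#' Plot group function-consistency against the background
#'
#' Group means with bootstrap CIs; the dashed line is the background mean
#' similarity over random annotated-gene pairs.
#'
#' @param object A `group_consistency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_consistency <- function(object, ...) {
  bg <- attr(object, "background")
  long <- object |>
    tidyr::pivot_longer(cols = c("cross_mean", "within_mean"),
                        names_to = "kind", values_to = "mean") |>
    mutate(lo = ifelse(.data$kind == "cross_mean", .data$cross_lo, .data$within_lo),
           hi = ifelse(.data$kind == "cross_mean", .data$cross_hi, .data$within_hi),
           kind = dplyr::recode(.data$kind, cross_mean = "vs reference",
                                within_mean = "within group"))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$mean, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           position = ggplot2::position_dodge(0.9), width = 0.2) +
    ggplot2::geom_hline(yintercept = bg$mean, linetype = 2) +
    ggplot2::labs(x = NULL, y = "mean Lin similarity", fill = NULL)
}
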