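#' Volcano plot of differential marker expression
#'
#' Mean expression difference (IR minus rest, sd units) against
#' -log10 Bonferroni p, with highlighted markers labelled.
#'
#' @param object a [marker_volcano()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot volcano_result
#' @export
autoplot.volcano_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  params <- attr(object, "params")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = -log10(pmax(.data$bonferroni_p,
                                                   1e-300)),
                                   colour = .data$highlighted)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(params$highlight_alpha),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * params$fold_cut,
                        linetype = 3, colour = "grey70") +
    ggplot2::geom_text(data = df[df$highlighted, , drop = FALSE],
                       ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean difference (IR - rest, sd units)",
                  y = expression(-log[10] ~ "Bonferroni p"),
                  colour = "highlighted") +
    ggplot2::theme_minimal()
}

#' Plot a partial-correlation graph
#'
#' Nodes on a circle; selected edges drawn with width proportional to
#' |pcor|, blue for positive and red for inhibitory associations.
#'
#' @param object a `pcor_graph`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pcor_graph
#' @export
autoplot.pcor_graph <- function(object, ...) {
  nodes <- object$nodes
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[-1L]
  pos <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  edges <- object$edges
  if (nrow(edges) > 0L) {
    edges <- dplyr::mutate(
      edges,
      x1 = pos$x[match(.data$node1, pos$node)],
      y1 = pos$y[match(.data$node1, pos$node)],
      x2 = pos$x[match(.data$node2, pos$node)],
      y2 = pos$y[match(.data$node2, pos$node)])
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, colour = .data$sign,
                   linewidth = abs(.data$pcor)))
  }
  p +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.15, .data$y * 1.15,
                                    label = .data$node), size = 3.5) +
    ggplot2::scale_colour_manual(values = c(positive = "steelblue",
                                            inhibitory = "firebrick")) +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "association")
}

#' Kaplan-Meier curves by subgroup
#'
#' Product-limit survival curves per subgroup alias, with censoring marks.
#'
#' @param clinical clinical tibble.
#' @param groups subgroup labels (see [km_median()]).
#' @param endpoint `"os"` or `"pfs"`.
#' @return A ggplot object.
#' @export
plot_km <- function(clinical, groups, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  g <- resolve_groups(groups, clinical$sample_id)
  time <- clinical[[paste0(endpoint, "_months")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  strata <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  df <- tibble::tibble(time = fit$time, surv = fit$surv,
                       censored = fit$n.censor > 0, group = strata)
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, censored = FALSE,
                   group = unique(strata)), df)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$censored, , drop = FALSE], shape = 3,
                        show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("months (%s)", toupper(endpoint)),
                  y = "survival probability", colour = "subgroup") +
    ggplot2::theme_minimal()
}
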