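#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IR antigen logistic fit
#'
#' One row per retained term with estimate, standard error, Wald statistic
#' and p-value, in the usual regression-table shape.
#'
#' @param x an `ir_logistic_fit`.
#' @param ... unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy ir_logistic_fit
#' @export
tidy.ir_logistic_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s),
                 estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"],
                 statistic = s[, "z value"],
                 p_value = s[, "Pr(>|z|)"])
}

#' @rdname tidy.ir_logistic_fit
#' @return For `glance()`: a one-row tibble with `bic`, `n_antigens`,
#'   `n`, `deviance`, `null_deviance`, `separation`.
#' @method glance ir_logistic_fit
#' @export
glance.ir_logistic_fit <- function(x, ...) {
  tibble::tibble(bic = x$bic, n_antigens = length(x$coefficients),
                 n = x$n, deviance = stats::deviance(x$model),
                 null_deviance = x$model$null.deviance,
                 separation = x$separation)
}

#' Tidy a partial-correlation graph
#'
#' @param x a `pcor_graph`.
#' @param all return every node pair rather than only selected edges.
#' @param ... unused.
#' @return The edge tibble (`node1`, `node2`, `pcor`, `sign`, `p`, `q`).
#' @method tidy pcor_graph
#' @export
tidy.pcor_graph <- function(x, all = FALSE, ...) {
  if (all) x$all_pairs else x$edges
}

#' @rdname tidy.pcor_graph
#' @return For `glance()`: one row with node/edge counts and the selection
#'   settings.
#' @method glance pcor_graph
#' @export
glance.pcor_graph <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_samples = x$n, fdr_level = x$metadata$fdr_level,
                 hard_threshold = x$metadata$hard_threshold,
                 shrinkage_lambda = x$metadata$shrinkage_lambda)
}

#' Tidy a subgroup assignment
#'
#' @param x a `subgroup_assignment`.
#' @param ... unused.
#' @return The label tibble (`sample_id`, `subgroup`, `alias`).
#' @method tidy subgroup_assignment
#' @export
tidy.subgroup_assignment <- function(x, ...) x$labels

#' @rdname tidy.subgroup_assignment
#' @method glance subgroup_assignment
#' @export
glance.subgroup_assignment <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$labels), k = nrow(x$centers),
                 n_genes = length(x$gene_set),
                 iterations = x$iterations %||% NA_integer_)
}
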