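#' Univariate proportional-hazards screen over a gene panel
#'
#' Fits one Cox proportional-hazards model per panel gene (no covariates,
#' no time truncation) against the chosen endpoint and reports the hazard
#' ratio per 1-sd expression with its 95% Wald interval and the
#' partial-likelihood score test p-value. Ties in event times are handled by
#' the Efron approximation. Constant genes cannot carry a hazard signal and
#' are returned flagged with `score_p = 1`; panel genes absent from the
#' expression table are listed in the `skipped` attribute.
#'
#' @param m scaled expression table ([scale_center()]).
#' @param clinical clinical tibble with `sample_id`, `<endpoint>_months`,
#'   `<endpoint>_event` columns.
#' @param panel a [gene_panel()] or character vector of gene symbols.
#' @param endpoint `"os"` (overall survival) or `"pfs"`.
#' @return A tibble with columns `gene`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `score_p`, `n_used`, `flag`.
#' @export
cox_screen <- function(m, clinical, panel, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  genes <- if (inherits(panel, "gene_panel") || is.data.frame(panel)) {
    unique(panel$gene)
  } else {
    unique(as.character(panel))
  }
  time <- clinical[[paste0(endpoint, "_months")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  if (is.null(time) || is.null(event)) {
    stop("clinical table lacks ", endpoint, " columns")
  }
  if (sum(event, na.rm = TRUE) == 0) {
    stop("endpoint ", endpoint, " has no observed events")
  }
  v <- expr_values(m)
  idx <- match(clinical$sample_id, colnames(v))
  if (anyNA(idx)) stop("clinical samples missing from expression table")
  v <- v[, idx, drop = FALSE]
  present <- intersect(genes, rownames(v))
  skipped <- setdiff(genes, present)
  surv <- survival::Surv(time, event)
  res <- purrr::map_dfr(present, function(g) {
    x <- v[g, ]
    if (stats::sd(x) < .Machine$double.eps^0.5) {
      return(tibble::tibble(gene = g, hazard_ratio = 1, ci_low = 1,
                            ci_high = 1, score_p = 1,
                            n_used = length(x), flag = "constant"))
    }
    fit <- survival::coxph(surv ~ x, ties = "efron")
    s <- summary(fit)
    tibble::tibble(gene = g,
                   hazard_ratio = unname(s$conf.int[1L, "exp(coef)"]),
                   ci_low = unname(s$conf.int[1L, "lower .95"]),
                   ci_high = unname(s$conf.int[1L, "upper .95"]),
                   score_p = unname(s$sctest["pvalue"]),
                   n_used = s$n, flag = NA_character_)
  })
  attr(res, "skipped") <- skipped
  res
}

#' Expected false positives and the corresponding FDR estimate
#'
#' Under the global null every test rejects with probability `alpha`, so a
#' screen of `n_tests` genes expects `n_tests * alpha` false positives; at
#' an observed hit count the plug-in FDR estimate is expected false
#' positives over hits.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha per-test significance level in (0, 1).
#' @param observed_hits optional observed number of rejections.
#' @return A tibble with `expected_fp` and (if `observed_hits` given)
#'   `fdr_estimate`.
#' @export
expected_false_positives <- function(n_tests, alpha, observed_hits = NULL) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  out <- tibble::tibble(n_tests = n_tests, alpha = alpha,
                        expected_fp = n_tests * alpha)
  if (!is.null(observed_hits)) {
    out$observed_hits <- observed_hits
    out$fdr_estimate <- out$expected_fp / pmax(1, observed_hits)
  }
  out
}

#' Genes reproduced between a discovery and a validation screen
#'
#' A gene is reproduced when it is significant at `alpha` in both screens
#' and its hazard ratio points in the same direction (both protective or
#' both adverse).
#'
#' @param discovery,validation [cox_screen()] results over the same gene
#'   universe.
#' @param alpha score-test significance level.
#' @return Tibble of reproduced genes with both screens' statistics.
#' @export
validate_hits <- function(discovery, validation, alpha = 0.05) {
  joined <- dplyr::inner_join(discovery, validation, by = "gene",
                              suffix = c("_disc", "_val"))
  dplyr::filter(joined,
                .data$score_p_disc < alpha,
                .data$score_p_val < alpha,
                sign(log(.data$hazard_ratio_disc)) ==
                  sign(log(.data$hazard_ratio_val)))
}

#' Kaplan-Meier median survival per group
#'
#' Product-limit medians with 95% log-log confidence intervals per group.
#' When the survival curve never crosses one half the median is undefined
#' and reported as `NA` with an open-ended upper bound.
#'
#' @param clinical clinical tibble.
#' @param groups a [cluster_subgroups()] assignment, or a data frame with
#'   `sample_id` and a label column (its second column), or a named vector.
#' @param endpoint `"os"` or `"pfs"`.
#' @return Tibble with `group`, `n`, `events`, `median_months`,
#'   `median_ci_low`, `median_ci_high`.
#' @export
km_median <- function(clinical, groups, endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  g <- resolve_groups(groups, clinical$sample_id)
  if (any(table(g) == 0L)) stop("empty group in Kaplan-Meier summary")
  time <- clinical[[paste0(endpoint, "_months")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1L, dimnames = list("g=all", names(tab)))
  tibble::tibble(
    group = sub("^g=", "", rownames(tab)),
    n = unname(tab[, "records"]),
    events = unname(tab[, "events"]),
    median_months = unname(tab[, "median"]),
    median_ci_low = unname(tab[, "0.95LCL"]),
    median_ci_high = unname(tab[, "0.95UCL"])
  )
}

# accept subgroup assignments, two-column data frames or named vectors,
# aligned to the clinical sample order
resolve_groups <- function(groups, sample_id) {
  if (inherits(groups, "subgroup_assignment")) {
    groups <- groups$labels[, c("sample_id", "alias")]
  }
  if (is.data.frame(groups)) {
    idx <- match(sample_id, groups$sample_id)
    if (anyNA(idx)) stop("group labels missing for some samples")
    return(as.character(groups[[2L]][idx]))
  }
  if (!is.null(names(groups))) {
    idx <- match(sample_id, names(groups))
    if (anyNA(idx)) stop("group labels missing for some samples")
    return(as.character(groups[idx]))
  }
  stopifnot(length(groups) == length(sample_id))
  as.character(groups)
}
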