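#' Discover prognosis subgroups by hierarchical clustering
#'
#' Samples are clustered by complete-linkage agglomerative clustering under
#' Euclidean distance over the supplied gene set (typically the validated
#' prognostic genes), and the tree is cut at `k` groups. Groups are numbered
#' by decreasing mean expression of their centre over the gene set, and
#' given the display aliases `purple` (highest, the immunoreactive-like
#' subgroup), `yellow`, `green` (also known as `aqua`) and `orange`
#' (lowest); aliases beyond four fall back to `group5`, `group6`, ....
#'
#' @param m scaled expression table.
#' @param gene_set character vector of clustering genes, all present in `m`.
#' @param k number of subgroups (default 4).
#' @return An object of class `subgroup_assignment`: a list with `labels`
#'   (tibble `sample_id`, `subgroup`, `alias`), `centers` (k x gene matrix
#'   of per-group means), `gene_set` and `alias_map`.
#' @export
cluster_subgroups <- function(m, gene_set, k = 4) {
  missing <- setdiff(gene_set, m$gene)
  if (length(missing) > 0L) {
    stop("clustering genes absent from expression table: ",
         paste(missing, collapse = ", "))
  }
  x <- t(expr_values(m)[gene_set, , drop = FALSE])  # samples x genes
  if (k > nrow(x)) stop("k exceeds the number of samples")
  raw <- if (k == 1L) {
    rep(1L, nrow(x))
  } else {
    stats::cutree(stats::hclust(stats::dist(x), method = "complete"), k = k)
  }
  centers <- group_centers(x, raw, k)
  ord <- order(rowMeans(centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)        # old id -> rank-ordered id
  new_subgroup_assignment(
    sample_id = rownames(x),
    subgroup = relabel[raw],
    centers = centers[ord, , drop = FALSE],
    gene_set = gene_set
  )
}

group_centers <- function(x, labels, k) {
  centers <- matrix(NA_real_, k, ncol(x),
                    dimnames = list(seq_len(k), colnames(x)))
  for (g in seq_len(k)) {
    if (any(labels == g)) {
      centers[g, ] <- colMeans(x[labels == g, , drop = FALSE])
    }
  }
  centers
}

subgroup_aliases <- function(k) {
  base <- c("purple", "yellow", "green", "orange")
  if (k <= 4L) base[seq_len(k)] else c(base, paste0("group", 5:k))[seq_len(k)]
}

new_subgroup_assignment <- function(sample_id, subgroup, centers, gene_set,
                                    iterations = NULL) {
  k <- nrow(centers)
  aliases <- subgroup_aliases(k)
  rownames(centers) <- aliases
  alias_map <- stats::setNames(aliases, seq_len(k))
  structure(list(
    labels = tibble::tibble(sample_id = sample_id,
                            subgroup = as.integer(subgroup),
                            alias = aliases[subgroup]),
    centers = centers,
    gene_set = gene_set,
    alias_map = alias_map,
    alias_synonyms = c(aqua = "green"),
    iterations = iterations
  ), class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat("Subgroup assignment:", nrow(x$labels), "samples,",
      nrow(x$centers), "groups over", length(x$gene_set), "genes\n")
  print(table(x$labels$alias))
  invisible(x)
}

#' Within/between group sum-of-squares ratio
#'
#' The clustering-quality criterion used to choose the number of prognosis
#' subgroups: total within-group sum of squares divided by between-group
#' sum of squares, computed over the assignment's gene set. Lower is
#' better-separated; a single group has no between-group variation and is
#' reported as `Inf`.
#'
#' @param m scaled expression table.
#' @param assignment a `subgroup_assignment`.
#' @return Nonnegative real (possibly `Inf`).
#' @export
wb_ss_ratio <- function(m, assignment) {
  x <- t(expr_values(m)[assignment$gene_set, , drop = FALSE])
  lab <- assignment$labels$subgroup[match(rownames(x),
                                          assignment$labels$sample_id)]
  grand <- colMeans(x)
  within <- 0; between <- 0
  for (g in unique(lab)) {
    xg <- x[lab == g, , drop = FALSE]
    cg <- colMeans(xg)
    within <- within + sum(sweep(xg, 2L, cg)^2)
    between <- between + nrow(xg) * sum((cg - grand)^2)
  }
  if (between == 0) Inf else within / between
}

#' Transfer subgroup labels to a validation cohort
#'
#' Runs Lloyd k-means on the validation samples initialised at the
#' discovery cluster centres; each converged cluster inherits the label
#' (and alias) of the centre that seeded it, so subgroup identity carries
#' across cohorts. Iterates to at most `max_iter` passes or until no centre
#' moves more than `tol`. A cluster left empty keeps its seeding centre
#' (with a warning) rather than being dropped.
#'
#' @param assignment discovery `subgroup_assignment` supplying the centres.
#' @param m_val scaled validation expression table containing the
#'   assignment's gene set.
#' @param max_iter,tol Lloyd iteration controls.
#' @return A `subgroup_assignment` for the validation samples; element
#'   `iterations` records the number of Lloyd passes.
#' @export
transfer_subgroups <- function(assignment, m_val, max_iter = 300,
                               tol = 1e-6) {
  missing <- setdiff(assignment$gene_set, m_val$gene)
  if (length(missing) > 0L) {
    stop("validation table lacks clustering genes: ",
         paste(missing, collapse = ", "))
  }
  x <- t(expr_values(m_val)[assignment$gene_set, , drop = FALSE])
  centers <- assignment$centers[, colnames(x), drop = FALSE]
  k <- nrow(centers)
  lab <- nearest_center(x, centers)
  iter <- 0L
  while (iter < max_iter) {
    new_centers <- centers
    for (g in seq_len(k)) {
      if (any(lab == g)) {
        new_centers[g, ] <- colMeans(x[lab == g, , drop = FALSE])
      }
    }
    move <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    new_lab <- nearest_center(x, centers)
    iter <- iter + 1L
    if (move <= tol && all(new_lab == lab)) break
    lab <- new_lab
  }
  empty <- setdiff(seq_len(k), unique(lab))
  if (length(empty) > 0L) {
    warning("empty cluster(s) after transfer: ",
            paste(rownames(assignment$centers)[empty], collapse = ", "))
  }
  new_subgroup_assignment(rownames(x), lab, centers,
                          assignment$gene_set, iterations = iter)
}

nearest_center <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Study-stratified log-rank test across subgroups
#'
#' Sums observed-minus-expected event counts within each stratum (study)
#' and reports the k-group log-rank chi-square with k - 1 degrees of
#' freedom. With a single stratum this reduces to the ordinary log-rank
#' test.
#'
#' @param clinical clinical tibble with survival columns and the stratum
#'   column.
#' @param groups subgroup labels (see [km_median()] for accepted forms).
#' @param strata name of the stratum column in `clinical` (default
#'   `"study"`), or `NULL` for an unstratified test.
#' @param endpoint `"os"` or `"pfs"`.
#' @return Tibble with `chi_square`, `df`, `p`, `strata_used`.
#' @export
stratified_logrank <- function(clinical, groups, strata = "study",
                               endpoint = c("os", "pfs")) {
  endpoint <- match.arg(endpoint)
  g <- factor(resolve_groups(groups, clinical$sample_id))
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 nonempty groups")
  time <- clinical[[paste0(endpoint, "_months")]]
  event <- clinical[[paste0(endpoint, "_event")]]
  if (is.null(strata)) {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g)
    strata_used <- 1L
  } else {
    st <- factor(clinical[[strata]])
    fit <- survival::survdiff(survival::Surv(time, event) ~ g +
                                survival::strata(st))
    strata_used <- nlevels(st)
  }
  df <- nlevels(g) - 1L
  tibble::tibble(chi_square = fit$chisq, df = df,
                 p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                 strata_used = strata_used)
}

#' Cross-tabulate subgroups against a clinical covariate
#'
#' For a categorical covariate, builds the subgroup-by-level contingency
#' table and tests association by chi-square (falling back to Fisher's
#' exact test when any expected cell count is below 5). For a numeric
#' covariate, reports per-group means and a one-way ANOVA p-value. Because
#' covariates may be missing for some samples, per-cell shares are reported
#' against both denominators: the full subgroup size (`pct_of_group`) and
#' the classified-only count (`pct_of_classified`).
#'
#' @param assignment a `subgroup_assignment` (or label data frame).
#' @param data tibble with `sample_id` and the covariate column.
#' @param var name of the covariate column in `data`.
#' @return A list of class `subgroup_xtab`: for categorical covariates,
#'   `counts`, `pct_of_group`, `pct_of_classified`, `group_n`,
#'   `n_classified`, `p`, `method`; for numeric ones, `means`, `p`,
#'   `method`.
#' @export
cross_tabulate <- function(assignment, data, var) {
  labels <- if (inherits(assignment, "subgroup_assignment")) {
    assignment$labels
  } else {
    tibble::tibble(sample_id = assignment$sample_id,
                   alias = as.character(assignment[[2L]]))
  }
  stopifnot(var %in% names(data))
  merged <- dplyr::left_join(labels, data[, c("sample_id", var)],
                             by = "sample_id")
  value <- merged[[var]]
  if (all(is.na(value))) stop("covariate ", var, " is entirely missing")
  group <- factor(merged$alias, levels = unique(labels$alias))
  if (is.numeric(value)) {
    means <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(group = group, value = value), group),
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE), .groups = "drop")
    p <- stats::anova(stats::lm(value ~ group))[["Pr(>F)"]][1L]
    out <- list(means = means, p = p, method = "one-way ANOVA", var = var)
  } else {
    keep <- !is.na(value)
    tab <- table(group = group[keep], level = factor(value[keep]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                    error = function(e) {
                      stats::fisher.test(tab, simulate.p.value = TRUE,
                                         B = 1e5)$p.value
                    })
      method <- "Fisher exact"
    } else {
      p <- stats::chisq.test(tab)$p.value
      method <- "chi-square"
    }
    group_n <- table(group)
    out <- list(counts = tab,
                pct_of_group = sweep(tab, 1L, as.numeric(group_n), "/") * 100,
                pct_of_classified = sweep(tab, 1L, pmax(1, rowSums(tab)),
                                          "/") * 100,
                group_n = group_n,
                n_classified = rowSums(tab),
                p = p, method = method, var = var)
  }
  structure(out, class = "subgroup_xtab")
}

#' @export
print.subgroup_xtab <- function(x, ...) {
  cat("Association between subgroups and", x$var,
      sprintf("(%s, p = %.3g)\n", x$method, x$p))
  if (!is.null(x$counts)) print(x$counts) else print(x$means)
  invisible(x)
}
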