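#' Average immune classes into metagene profiles
#'
#' A metagene is the unweighted per-sample mean of the z-scored member
#' genes of one immune class (CD4, CD8, CD3, MHCI, MHCII, ...). Averaging
#' stabilises the class signal before graphical-model estimation at the
#' small subgroup sizes where per-gene partial correlations are noisy.
#'
#' @param m scaled expression table.
#' @param panel a [gene_panel()]; one metagene is built per category with
#'   at least one member present in `m`.
#' @param categories categories to build; default all non-antigen classes
#'   present in the panel.
#' @return A scaled expression table whose `gene` column holds metagene
#'   (class) names.
#' @export
metagene_average <- function(m, panel,
                             categories = setdiff(unique(panel$category),
                                                  "ct_antigen")) {
  v <- expr_values(m)
  rows <- lapply(categories, function(cl) {
    members <- intersect(panel$gene[panel$category == cl], rownames(v))
    if (length(members) == 0L) {
      stop("metagene class has no member genes in the table: ", cl)
    }
    colMeans(v[members, , drop = FALSE])
  })
  out <- expr_table(do.call(rbind, rows), gene_ids = categories)
  attr(out, "scaled") <- is_scaled(m)
  out
}

#' Shrinkage estimate of the partial correlation matrix
#'
#' Shrinks the sample correlation matrix toward the identity,
#' `R* = (1 - lambda) R + lambda I`, and converts its inverse `Omega` to
#' partial correlations `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)`.
#' With `lambda = "auto"` the shrinkage intensity is the analytic
#' variance-minimising value for correlation shrinkage toward the
#' identity (the ratio of the summed estimated variances of the
#' off-diagonal correlations to their summed squares, clipped to [0, 1]),
#' which guarantees a positive-definite `R*` whenever `lambda > 0`.
#'
#' @param x numeric matrix, samples in rows and variables in columns, or a
#'   scaled expression table (genes become variables).
#' @param lambda shrinkage intensity in \[0, 1\], or `"auto"`.
#' @return A list with `pcor` (symmetric, unit diagonal), `lambda_used`
#'   and `n` (sample count).
#' @export
shrinkage_partial_correlation <- function(x, lambda = "auto") {
  if (inherits(x, "expr_tbl")) x <- t(expr_values(x))
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2L) stop("need at least 2 variables")
  if (n < 4L) stop("need at least 4 samples")
  r <- stats::cor(x)
  if (identical(lambda, "auto")) {
    lambda <- estimate_shrinkage_lambda(x, r)
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  r_star <- (1 - lambda) * r
  diag(r_star) <- 1
  omega <- if (lambda > 0) solve(r_star) else {
    # unshrunk: use the pseudo-inverse so exactly singular fixtures and
    # the n > p case are both served
    sv <- svd(r_star)
    pos <- sv$d > max(dim(r_star)) * .Machine$double.eps * max(sv$d)
    sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
  }
  d <- sqrt(diag(omega))
  pcor <- -omega / outer(d, d)
  diag(pcor) <- 1
  pcor <- (pcor + t(pcor)) / 2
  dimnames(pcor) <- dimnames(r)
  list(pcor = pcor, lambda_used = lambda, n = n)
}

# analytic variance-minimising shrinkage intensity toward the identity:
# lambda* = sum_{i != j} Var-hat(r_ij) / sum_{i != j} r_ij^2
estimate_shrinkage_lambda <- function(x, r = stats::cor(x)) {
  n <- nrow(x)
  z <- scale(x)                     # standardized columns
  num <- 0
  w_bar_factor <- n / (n - 1)^3
  p <- ncol(x)
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      w <- z[, i] * z[, j]
      num <- num + w_bar_factor * sum((w - mean(w))^2)
    }
  }
  den <- sum(r[upper.tri(r)]^2)
  if (den < 1e-12) return(1)
  max(0, min(1, num / den))
}

#' Select graph edges by FDR and hard threshold
#'
#' Each off-diagonal partial correlation is converted to a p-value through
#' the t-approximation (`t = pcor * sqrt(df / (1 - pcor^2))` with
#' `df = n - 2 - (p - 2)`, the residual degrees of freedom after
#' conditioning on the remaining nodes), Benjamini-Hochberg q-values are
#' computed over all candidate edges, and an edge is kept only when its
#' q-value is below `fdr_level` **and** its absolute partial correlation
#' reaches `hard_threshold`. Edge signs distinguish positive association
#' from inhibitory (negative) association.
#'
#' @param pcor symmetric partial-correlation matrix with unit diagonal, or
#'   the list returned by [shrinkage_partial_correlation()].
#' @param n number of samples behind `pcor` (taken from the list if given).
#' @param fdr_level Benjamini-Hochberg level (default 0.05).
#' @param hard_threshold minimum |pcor| (default 0.1).
#' @return An object of class `pcor_graph`: list with `nodes`, `pcor`,
#'   `edges` (tibble `node1`, `node2`, `pcor`, `sign`, `p`, `q`), `n` and
#'   the selection `metadata`.
#' @export
edge_select <- function(pcor, n = NULL, fdr_level = 0.05,
                        hard_threshold = 0.1) {
  lambda_used <- NA_real_
  if (is.list(pcor) && !is.null(pcor$pcor)) {
    if (is.null(n)) n <- pcor$n
    lambda_used <- pcor$lambda_used
    pcor <- pcor$pcor
  }
  stopifnot(is.matrix(pcor), nrow(pcor) == ncol(pcor))
  p <- nrow(pcor)
  df <- n - 2L - (p - 2L)
  if (df <= 0L) stop("too few samples for the partial-correlation t-test")
  nodes <- rownames(pcor)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  idx <- which(upper.tri(pcor), arr.ind = TRUE)
  r <- pcor[idx]
  r_c <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r_c * sqrt(df / (1 - r_c^2))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  q <- stats::p.adjust(pval, method = "BH")
  edges <- tibble::tibble(
    node1 = nodes[idx[, 1L]], node2 = nodes[idx[, 2L]],
    pcor = r, sign = ifelse(r >= 0, "positive", "inhibitory"),
    p = pval, q = q
  )
  keep <- dplyr::filter(edges, .data$q < fdr_level,
                        abs(.data$pcor) >= hard_threshold)
  structure(list(nodes = nodes, pcor = pcor, edges = keep,
                 all_pairs = edges, n = n,
                 metadata = list(fdr_level = fdr_level,
                                 hard_threshold = hard_threshold,
                                 df = df, shrinkage_lambda = lambda_used)),
            class = "pcor_graph")
}

#' @export
print.pcor_graph <- function(x, ...) {
  cat("Partial-correlation graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (FDR", x$metadata$fdr_level,
      ", |pcor| >=", x$metadata$hard_threshold, ", n =", x$n, ")\n")
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

#' Estimate a subgroup's partial-correlation graph in one call
#'
#' Convenience wrapper: build metagene profiles, estimate the shrinkage
#' partial-correlation matrix, and select edges.
#'
#' @inheritParams metagene_average
#' @inheritParams edge_select
#' @param extra_genes individual genes added as their own nodes alongside
#'   the metagenes (e.g. the RFX transcription factors).
#' @param lambda shrinkage intensity or `"auto"`.
#' @return A `pcor_graph`.
#' @export
immune_ggm <- function(m, panel, categories = setdiff(unique(panel$category),
                                                      "ct_antigen"),
                       extra_genes = character(0), lambda = "auto",
                       fdr_level = 0.05, hard_threshold = 0.1) {
  prof <- metagene_average(m, panel, categories)
  if (length(extra_genes) > 0L) {
    v <- expr_values(m)
    missing <- setdiff(extra_genes, rownames(v))
    if (length(missing) > 0L) {
      stop("extra node genes absent: ", paste(missing, collapse = ", "))
    }
    prof <- expr_table(rbind(expr_values(prof),
                             v[extra_genes, , drop = FALSE]))
  }
  fit <- shrinkage_partial_correlation(prof, lambda = lambda)
  edge_select(fit, fdr_level = fdr_level, hard_threshold = hard_threshold)
}

#' Compare two subgroup graphs edge by edge
#'
#' Partitions the union of selected edges into those shared by both graphs
#' and those specific to either, keeping each edge's sign — e.g. to show a
#' CD4-MHCII coupling present in the good-prognosis subgroup only.
#'
#' @param g_good,g_poor `pcor_graph` objects over the same node set.
#' @return Tibble with `node1`, `node2`, `status`
#'   (`shared`/`good_only`/`poor_only`), and each graph's pcor and sign.
#' @export
compare_graphs <- function(g_good, g_poor) {
  if (!setequal(g_good$nodes, g_poor$nodes)) {
    stop("graphs are defined over different node sets")
  }
  key <- function(e) paste(pmin(e$node1, e$node2), pmax(e$node1, e$node2))
  eg <- g_good$edges; ep <- g_poor$edges
  eg$.key <- key(eg); ep$.key <- key(ep)
  merged <- dplyr::full_join(eg, ep, by = ".key",
                             suffix = c("_good", "_poor"))
  tibble::tibble(
    node1 = dplyr::coalesce(merged$node1_good, merged$node1_poor),
    node2 = dplyr::coalesce(merged$node2_good, merged$node2_poor),
    status = dplyr::case_when(
      !is.na(merged$pcor_good) & !is.na(merged$pcor_poor) ~ "shared",
      !is.na(merged$pcor_good) ~ "good_only",
      TRUE ~ "poor_only"),
    pcor_good = merged$pcor_good, sign_good = merged$sign_good,
    pcor_poor = merged$pcor_poor, sign_poor = merged$sign_poor
  )
}
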