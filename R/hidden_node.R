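#' Partial-correlation test by residual regression
#'
#' Residualises genes `a` and `b` on the conditioning set by least squares,
#' correlates the residuals, and tests the partial correlation with the
#' usual t statistic on `n - |conditioning| - 2` degrees of freedom
#' (standard linear-model / added-variable theory). With an empty
#' conditioning set this is the plain Pearson correlation test. Collinear
#' conditioning columns are dropped (by the QR rank decision) with a
#' warning rather than failing.
#'
#' @param m scaled expression table.
#' @param a,b gene symbols in `m`.
#' @param conditioning character vector of conditioning genes (may be
#'   empty); must exclude `a` and `b`.
#' @return Tibble with `pcor`, `p`, `df`, `n_conditioning`.
#' @export
partial_cor_test <- function(m, a, b, conditioning = character(0)) {
  if (a %in% conditioning || b %in% conditioning) {
    stop("conditioning set must exclude the tested pair")
  }
  v <- expr_values(m)
  missing <- setdiff(c(a, b, conditioning), rownames(v))
  if (length(missing) > 0L) {
    stop("genes absent from expression table: ",
         paste(missing, collapse = ", "))
  }
  n <- ncol(v)
  xa <- v[a, ]; xb <- v[b, ]
  k <- 0L
  if (length(conditioning) > 0L) {
    z <- cbind(1, t(v[conditioning, , drop = FALSE]))
    qrz <- qr(z)
    if (qrz$rank < ncol(z)) {
      dropped <- colnames(z)[qrz$pivot[-seq_len(qrz$rank)]]
      warning("collinear conditioning columns dropped: ",
              paste(setdiff(dropped, ""), collapse = ", "))
    }
    xa <- qr.resid(qrz, xa)
    xb <- qr.resid(qrz, xb)
    k <- qrz$rank - 1L          # conditioning genes actually used
  } else {
    xa <- xa - mean(xa)
    xb <- xb - mean(xb)
  }
  df <- n - k - 2L
  if (df <= 0L) stop("not enough samples for the conditioning set size")
  r <- sum(xa * xb) / sqrt(sum(xa^2) * sum(xb^2))
  r_c <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r_c * sqrt(df / (1 - r_c^2))
  tibble::tibble(pcor = r, p = 2 * stats::pt(abs(tstat), df,
                                             lower.tail = FALSE),
                 df = df, n_conditioning = k)
}

#' Scan a candidate pool for latent mediators of an edge
#'
#' For an unexpected graph edge A-B, a hidden node X must satisfy three
#' conditions: (i) A and B become conditionally independent given X
#' (partial-correlation p above `alpha_ci`); (ii) A and X remain dependent
#' given the declared conditioning set; (iii) B and X remain dependent
#' given the same set — (ii) and (iii) Bonferroni-corrected over the pool
#' size. Conditioning for (ii)/(iii) defaults to the graph's other node
#' profiles if supplied (conditioning on the full transcriptome would
#' exhaust the degrees of freedom at subgroup sample sizes). Passing
#' candidates are ranked by `rank_score = p_ci - max(p_ax, p_bx)`
#' (descending), favouring strong induced independence together with
#' strong dependence on both endpoints.
#'
#' @param m scaled expression table.
#' @param edge character pair `c(A, B)`.
#' @param pool candidate genes (excluding A and B).
#' @param alpha_ci level for the conditional-independence condition (i).
#' @param alpha_dep level for conditions (ii)/(iii) before Bonferroni
#'   division by the pool size.
#' @param conditioning genes conditioned on in (ii)/(iii) (the candidate
#'   itself and the edge endpoints are handled automatically); default
#'   empty, i.e. marginal dependence.
#' @return Tibble of class `hidden_node_scan`: one row per candidate with
#'   `candidate`, `p_ci`, `p_ax`, `p_bx`, `passes`, `rank_score`, sorted
#'   with passing candidates first by decreasing `rank_score`.
#' @export
search_hidden_nodes <- function(m, edge, pool, alpha_ci = 0.05,
                                alpha_dep = 0.05,
                                conditioning = character(0)) {
  stopifnot(length(edge) == 2L)
  a <- edge[1L]; b <- edge[2L]
  pool <- setdiff(unique(pool), c(a, b))
  if (length(pool) == 0L) stop("candidate pool is empty")
  alpha_dep_adj <- alpha_dep / length(pool)
  rows <- purrr::map_dfr(pool, function(x) {
    cond_rest <- setdiff(conditioning, c(a, b, x))
    p_ci <- partial_cor_test(m, a, b, conditioning = x)$p
    p_ax <- partial_cor_test(m, a, x, conditioning = cond_rest)$p
    p_bx <- partial_cor_test(m, b, x, conditioning = cond_rest)$p
    tibble::tibble(candidate = x, p_ci = p_ci, p_ax = p_ax, p_bx = p_bx)
  })
  rows$passes <- rows$p_ci > alpha_ci &
    rows$p_ax < alpha_dep_adj & rows$p_bx < alpha_dep_adj
  rows$rank_score <- rows$p_ci - pmax(rows$p_ax, rows$p_bx)
  out <- dplyr::arrange(rows, dplyr::desc(.data$passes),
                        dplyr::desc(.data$rank_score))
  attr(out, "params") <- list(edge = c(a, b), alpha_ci = alpha_ci,
                              alpha_dep = alpha_dep,
                              alpha_dep_adjusted = alpha_dep_adj,
                              conditioning = conditioning,
                              pool_size = length(pool))
  class(out) <- unique(c("hidden_node_scan", class(out)))
  out
}
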