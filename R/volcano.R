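#' Volcano-style differential expression of literature markers
#'
#' Tests each marker for differential expression between the immunoreactive
#' (IR) subgroup and all other samples with a Welch two-sample t-test,
#' applies Bonferroni correction over the marker set, and highlights
#' markers that are both statistically strong (Bonferroni p below
#' `highlight_alpha`) and biologically extreme (|mean difference| at least
#' `fold_cut` sd units).
#'
#' @param m scaled expression table.
#' @param ir IR labels: a `subgroup_assignment` (purple = IR), a data frame
#'   with `sample_id` and a logical `ir` column, or a named logical vector.
#' @param markers character vector of marker genes.
#' @param highlight_alpha Bonferroni significance mark (default 0.001).
#' @param fold_cut minimum |mean difference| in sd units (default 0.5).
#' @return Tibble of class `volcano_result` with columns `gene`,
#'   `mean_diff` (IR mean minus rest mean), `t_p`, `bonferroni_p`,
#'   `highlighted`; markers absent from `m` are listed in the `skipped`
#'   attribute.
#' @export
marker_volcano <- function(m, ir, markers, highlight_alpha = 0.001,
                           fold_cut = 0.5) {
  v <- expr_values(m)
  is_ir <- resolve_ir(ir, colnames(v))
  if (sum(is_ir) < 2L || sum(!is_ir) < 2L) {
    stop("both the IR group and its complement need at least 2 samples")
  }
  present <- intersect(markers, rownames(v))
  skipped <- setdiff(markers, present)
  n_tested <- length(present)
  res <- purrr::map_dfr(present, function(g) {
    x <- v[g, is_ir]; y <- v[g, !is_ir]
    tt <- stats::t.test(x, y)
    tibble::tibble(gene = g, mean_diff = mean(x) - mean(y),
                   t_p = tt$p.value)
  })
  res$bonferroni_p <- pmin(1, res$t_p * n_tested)
  res$highlighted <- res$bonferroni_p < highlight_alpha &
    abs(res$mean_diff) >= fold_cut
  attr(res, "skipped") <- skipped
  attr(res, "params") <- list(highlight_alpha = highlight_alpha,
                              fold_cut = fold_cut, n_tested = n_tested)
  class(res) <- unique(c("volcano_result", class(res)))
  res
}

# IR labels in any of the accepted forms -> logical vector over sample_ids
resolve_ir <- function(ir, sample_ids) {
  if (inherits(ir, "subgroup_assignment")) {
    ir <- tibble::tibble(sample_id = ir$labels$sample_id,
                         ir = ir$labels$alias == "purple")
  }
  if (is.data.frame(ir)) {
    idx <- match(sample_ids, ir$sample_id)
    if (anyNA(idx)) stop("IR labels missing for some samples")
    val <- ir$ir[idx]
  } else {
    idx <- match(sample_ids, names(ir))
    if (anyNA(idx)) stop("IR labels missing for some samples")
    val <- ir[idx]
  }
  if (!is.logical(val)) val <- val %in% c("IR", "purple", "TRUE", "1")
  val
}
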