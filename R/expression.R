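#' Expression tables
#'
#' An expression table in this package is a tibble whose first column,
#' `gene`, holds official gene symbols (or probe identifiers before
#' collapsing) and whose remaining columns are numeric log-scale expression
#' values, one column per sample. The attribute `scaled` records whether
#' rows have been z-scored by [scale_center()].
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of row identifiers.
#' @param sample_ids character vector of column identifiers.
#' @return A tibble of class `expr_tbl`.
#' @export
expr_table <- function(values, gene_ids = rownames(values),
                       sample_ids = colnames(values)) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values),
            length(gene_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- as.character(sample_ids)
  out <- dplyr::bind_cols(tibble::tibble(gene = as.character(gene_ids)), out)
  new_expr_tbl(out, scaled = FALSE)
}

new_expr_tbl <- function(tbl, scaled = FALSE) {
  structure(tbl, class = unique(c("expr_tbl", class(tbl))), scaled = scaled)
}

#' @rdname expr_table
#' @param m an expression table.
#' @export
expr_values <- function(m) {
  v <- as.matrix(m[, setdiff(names(m), "gene"), drop = FALSE])
  rownames(v) <- m$gene
  v
}

#' @rdname expr_table
#' @export
expr_samples <- function(m) setdiff(names(m), "gene")

#' @rdname expr_table
#' @export
is_scaled <- function(m) isTRUE(attr(m, "scaled"))

expr_from_values <- function(v, scaled = FALSE) {
  new_expr_tbl(expr_table(v), scaled = scaled)
}

#' Read a tab-separated expression table
#'
#' Reads a genes-or-probes by samples TSV (header row of sample identifiers,
#' first column of probe/gene identifiers, `NA` for missing) and optionally
#' collapses probes to gene symbols with a probe-to-gene mapping table.
#' Unmapped probes are dropped and counted in the attached `log` attribute.
#'
#' @param path path to the TSV file.
#' @param mapping optional data frame with columns `probe` and `gene`.
#' @param method probe collapse method, see [collapse_probes()].
#' @return An expression table; attribute `log` records dropped-probe counts.
#' @export
read_expression <- function(path, mapping = NULL,
                            method = c("mean", "max_mean_probe")) {
  lines <- readr::read_lines(path)
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  bad <- which(lengths(fields) != width)
  if (length(bad) > 0L) {
    stop("ragged expression table: line ", bad[1L], " has ",
         lengths(fields)[bad[1L]], " fields, expected ", width)
  }
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  body <- fields[-1L]
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L)),
                  nrow = length(body), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  broken <- which(is.na(num) & !(cells %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(broken) > 0L) {
    stop("non-numeric value ", dQuote(cells[broken[1L, , drop = FALSE]]),
         " at data row ", broken[1L, 1L], ", column ", broken[1L, 2L] + 1L,
         " of ", path)
  }
  rownames(num) <- ids
  colnames(num) <- sample_ids
  m <- expr_table(num)
  if (!is.null(mapping)) {
    m <- collapse_probes(m, mapping, method = match.arg(method))
  }
  m
}

#' Write an expression table to TSV
#'
#' @param m expression table.
#' @param path output path; tab-separated, `NA` for missing values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(m)), path, na = "NA")
  invisible(path)
}

#' Collapse probe rows to gene symbols
#'
#' Probes mapping to the same official symbol are combined into a single
#' row, either by averaging the probe rows (`mean`, the default) or by
#' keeping the probe with the highest mean expression (`max_mean_probe`).
#' Probes absent from the mapping are dropped; the count is recorded in the
#' returned table's `log` attribute.
#'
#' @param m expression table keyed by probe identifiers.
#' @param mapping data frame with columns `probe` and `gene`.
#' @param method `"mean"` or `"max_mean_probe"`.
#' @return Expression table with one row per gene.
#' @export
collapse_probes <- function(m, mapping, method = c("mean", "max_mean_probe")) {
  method <- match.arg(method)
  stopifnot(all(c("probe", "gene") %in% names(mapping)))
  map <- dplyr::distinct(tibble::as_tibble(mapping[, c("probe", "gene")]))
  v <- expr_values(m)
  keep <- rownames(v) %in% map$probe
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no probes in the expression table match the mapping")
  v <- v[keep, , drop = FALSE]
  gene_of <- map$gene[match(rownames(v), map$probe)]
  groups <- split(seq_len(nrow(v)), gene_of)
  rows <- lapply(groups, function(idx) {
    block <- v[idx, , drop = FALSE]
    if (method == "mean" || length(idx) == 1L) {
      colMeans(block)
    } else {
      block[which.max(rowMeans(block)), ]
    }
  })
  out <- expr_table(do.call(rbind, rows), gene_ids = names(groups))
  attr(out, "log") <- list(dropped_unmapped = n_dropped,
                           collapse_method = method)
  out
}

#' Z-score expression rows, optionally within study
#'
#' Each gene row is centred to mean zero and scaled to unit standard
#' deviation; with `per_study = TRUE` this is done independently within
#' each study block so that cross-platform cohorts are comparable in
#' relative-expression units. Constant rows cannot be scaled: they are set
#' to zero (keeping panel indices stable) and reported via a warning and the
#' `zeroed_genes` attribute.
#'
#' @param m unscaled expression table.
#' @param study optional data frame with columns `sample_id` and `study`;
#'   required when `per_study = TRUE`.
#' @param per_study z-score within each study block rather than globally.
#' @return A scaled expression table (`is_scaled()` is `TRUE`).
#' @export
scale_center <- function(m, study = NULL, per_study = FALSE) {
  v <- expr_values(m)
  blocks <- if (per_study) {
    stopifnot(!is.null(study), all(colnames(v) %in% study$sample_id))
    split(colnames(v), study$study[match(colnames(v), study$sample_id)])
  } else {
    list(all = colnames(v))
  }
  zeroed <- character(0)
  for (samples in blocks) {
    block <- v[, samples, drop = FALSE]
    mu <- rowMeans(block)
    sd <- apply(block, 1L, stats::sd)
    const <- sd < .Machine$double.eps^0.5
    sd[const] <- 1
    z <- (block - mu) / sd
    z[const, ] <- 0
    v[, samples] <- z
    zeroed <- union(zeroed, rownames(v)[const])
  }
  if (length(zeroed) > 0L) {
    warning("constant expression rows set to zero: ",
            paste(zeroed, collapse = ", "))
  }
  out <- expr_from_values(v, scaled = TRUE)
  attr(out, "zeroed_genes") <- zeroed
  out
}

#' Merge replicate sample columns
#'
#' Samples whose expression profiles are near-duplicates are averaged into a
#' single column, the remediation used when one series banks several arrays
#' per patient. Columns are merged when their Pearson correlation is at
#' least `cor_threshold`; if a patient-id table is supplied, additionally
#' only when they declare the same patient. Merging is by connected
#' components of the qualifying-pair graph, so a trio of mutually similar
#' arrays collapses to one averaged column.
#'
#' @param m unscaled expression table.
#' @param cor_threshold correlation cut in (0, 1); default 0.95.
#' @param patient optional data frame with columns `sample_id`, `patient_id`.
#' @return Expression table with merged columns; the `merge_log` attribute
#'   lists each merged group and its new column name (the first member's).
#' @export
merge_replicates <- function(m, cor_threshold = 0.95, patient = NULL) {
  if (!is.numeric(cor_threshold) || cor_threshold <= 0 || cor_threshold >= 1) {
    stop("cor_threshold must lie strictly between 0 and 1")
  }
  v <- expr_values(m)
  n <- ncol(v)
  comp <- seq_len(n)                      # union-find over sample columns
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  cc <- suppressWarnings(stats::cor(v))
  pid <- if (!is.null(patient)) {
    patient$patient_id[match(colnames(v), patient$sample_id)]
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      same_patient <- is.null(pid) ||
        (!is.na(pid[i]) && !is.na(pid[j]) && pid[i] == pid[j])
      if (same_patient && !is.na(cc[i, j]) && cc[i, j] >= cor_threshold) {
        comp[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  merged <- lapply(groups, function(idx) rowMeans(v[, idx, drop = FALSE]))
  out_v <- do.call(cbind, merged)
  colnames(out_v) <- vapply(groups, function(idx) colnames(v)[idx[1L]], "")
  out_v <- out_v[, order(vapply(groups, min, integer(1))), drop = FALSE]
  out <- expr_table(out_v, gene_ids = rownames(v))
  merge_log <- purrr::map(purrr::keep(groups, ~ length(.x) > 1L),
                          ~ colnames(v)[.x])
  attr(out, "merge_log") <- unname(merge_log)
  out
}

#' Quantile rank of a gene's mean expression
#'
#' The rank of the gene's mean expression among the mean expression of all
#' genes in the table, divided by the number of genes (midranks for ties).
#' Used to check whether lymphocyte-specific markers sit in the background
#' (noise) part of the expression distribution in a tissue, e.g. that
#' immune surface markers rank low in pure tumour cell lines.
#'
#' @param m expression table (raw or scaled).
#' @param gene gene symbol present in `m`.
#' @return A fraction in (0, 1].
#' @export
quantile_rank <- function(m, gene) {
  if (!gene %in% m$gene) stop("gene not present in expression table: ", gene)
  means <- rowMeans(expr_values(m))
  unname(rank(means, ties.method = "average")[match(gene, m$gene)] /
           length(means))
}
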