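#' Gene panels
#'
#' A gene panel is a tibble with columns `gene` and `category`, tagging each
#' symbol with its immune class. Recognised categories are the antigen
#' presentation and T-cell receptor classes used throughout the pipeline:
#' `MHCI`, `MHCII`, `CD3`, `CD4`, `CD8`, `coregulator`, `lymphocyte_marker`
#' and `ct_antigen` (cancer-testis antigens).
#'
#' @param gene character vector of official gene symbols.
#' @param category character vector of categories, recycled if length 1.
#' @return A tibble of class `gene_panel`.
#' @export
gene_panel <- function(gene, category) {
  if (length(category) == 1L) category <- rep(category, length(gene))
  stopifnot(length(gene) == length(category))
  bad <- setdiff(unique(category), panel_categories())
  if (length(bad) > 0L) {
    stop("unknown panel categories: ", paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(gene = as.character(gene),
                        category = as.character(category))
  dup <- dplyr::count(out, .data$category, .data$gene) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate symbols within a category: ",
         paste(dup$gene, collapse = ", "))
  }
  structure(out, class = unique(c("gene_panel", class(out))))
}

#' @rdname gene_panel
#' @export
panel_categories <- function() {
  c("MHCI", "MHCII", "CD3", "CD4", "CD8", "coregulator",
    "lymphocyte_marker", "ct_antigen")
}

#' @rdname gene_panel
#' @param panel a gene panel.
#' @param categories categories to keep.
#' @export
panel_subset <- function(panel, categories) {
  dplyr::filter(panel, .data$category %in% categories)
}

#' Read a gene panel from a two-column TSV
#'
#' @param path TSV with columns `gene` and `category`.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  gene_panel(tbl$gene, tbl$category)
}

#' Default immune and cancer-testis antigen panel
#'
#' A 64-gene immune panel (antigen presentation and processing, T-cell
#' receptor complex and co-regulatory surface molecules, lymphocyte
#' markers) plus 98 cancer-testis (CT) antigen symbols. Named CT antigens
#' cover those recurrently discussed for the immunoreactive subgroup
#' (CEP290, CTNNA2, TMEFF1, TEX15, ZNF164, MAGEA3, ...); the remainder are
#' filled from the MAGE/GAGE/SSX/CTAG families plus synthetic `CTX##`
#' placeholders so the panel size matches a realistic array footprint.
#'
#' @return A [gene_panel()] with 162 entries.
#' @export
default_gene_panel <- function() {
  mhci <- c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G",
            "B2M", "TAP1", "TAP2", "TAPBP", "PSMB8", "PSMB9",
            "PDIA3", "CALR", "CANX", "ERAP1")
  mhcii <- c("HLA-DOA", "HLA-DOB", "HLA-DRA", "HLA-DRB1", "HLA-DPA1",
             "HLA-DPB1", "HLA-DQA1", "HLA-DQB1", "HLA-DMA", "HLA-DMB",
             "CD74", "CIITA", "RFX5", "RFXANK", "RFXAP", "CTSS")
  cd3 <- c("CD3D", "CD3E", "CD3G", "CD247", "LCK", "ZAP70")
  cd4 <- c("CD4", "IL7R", "CD40LG", "ICOS")
  cd8 <- c("CD8A", "CD8B", "GZMB", "PRF1")
  coreg <- c("CD28", "CTLA4", "PDCD1", "CD274", "PDCD1LG2", "LAG3",
             "HAVCR2", "TNFRSF9")
  lymph <- c("PTPRC", "CD2", "CD7", "CD14", "CD19", "CD33", "CD1D",
             "FCGR1A", "FCGR3B", "NCAM1")
  ct_named <- c("CEP290", "CTNNA2", "TMEFF1", "TEX15", "ZNF164", "MAGEA3",
                "ZNF165", "CEP55", "ATAD2", "CTAGE5", "CTAG1B", "CTAG2",
                "MAGEA1", "MAGEA4", "MAGEA6", "MAGEA10", "MAGEA12",
                "MAGEB2", "MAGEC1", "MAGEC2", "GAGE1", "GAGE2A", "GAGE4",
                "PAGE1", "XAGE1A", "SSX1", "SSX2", "SSX4", "PRAME",
                "SPANXA1", "SPANXB1", "SPA17", "SYCP1", "TSP50", "PIWIL2",
                "AKAP3", "AKAP4", "ODF1", "ODF2", "TPTE", "LDHC", "TSSK6",
                "CALR3", "DDX43", "DDX53", "FATE1", "HORMAD1", "IL13RA2",
                "LEMD1", "LUZP4", "MORC1", "NXF2", "PASD1", "PLAC1",
                "POTEA", "RQCD1", "SAGE1", "SPO11", "TDRD1", "TEX14")
  ctx <- sprintf("CTX%02d", seq_len(98L - length(ct_named)))
  gene_panel(
    gene = c(mhci, mhcii, cd3, cd4, cd8, coreg, lymph, ct_named, ctx),
    category = c(rep("MHCI", length(mhci)), rep("MHCII", length(mhcii)),
                 rep("CD3", length(cd3)), rep("CD4", length(cd4)),
                 rep("CD8", length(cd8)), rep("coregulator", length(coreg)),
                 rep("lymphocyte_marker", length(lymph)),
                 rep("ct_antigen", 98L))
  )
}
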