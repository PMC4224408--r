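# Shared fixture builders (all generated in code; no stored data).

# Scaled expression table from a genes x samples value matrix.
scaled_expr <- function(v) {
  m <- expr_table(v)
  suppressWarnings(scale_center(m))
}

# Wrap a matrix whose rows are already z-scored.
expr_from_scaled <- function(v) {
  m <- expr_table(v)
  attr(m, "scaled") <- TRUE
  m
}

# Four Gaussian blobs in `d` dimensions: tight clusters (sd 0.1) around
# centres 3 apart, the separable configuration used for clustering checks.
make_blobs <- function(n_per = 30, d = 5, sd = 0.1, spacing = 3,
                       seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(0, 4, d)
    for (g in 1:4) centers[g, g] <- spacing
    x <- do.call(rbind, lapply(1:4, function(g) {
      matrix(stats::rnorm(n_per * d, sd = sd), n_per, d,
             byrow = TRUE) + matrix(centers[g, ], n_per, d, byrow = TRUE)
    }))
    rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
    colnames(x) <- paste0("G", seq_len(d))
    list(x = x, truth = rep(1:4, each = n_per), centers = centers)
  })
}

blob_expr <- function(blobs) {
  expr_table(t(blobs$x))  # genes x samples
}

# Group-mean centre matrix for hand-built subgroup assignments.
group_centers_for_test <- function(x, lab) {
  k <- max(lab)
  centers <- t(vapply(seq_len(k), function(g) {
    colMeans(x[lab == g, , drop = FALSE])
  }, numeric(ncol(x))))
  colnames(centers) <- colnames(x)
  centers
}

# Per-sample expansion of printed subgroup-by-class counts.
counts_to_samples <- function(counts) {
  # counts: tibble with subgroup, level (NA allowed), n
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), ]
  tibble::tibble(
    sample_id = sprintf("T%03d", seq_len(nrow(rows))),
    subgroup = rows$subgroup,
    level = rows$level
  )
}

read_counts_fixture <- function(file) {
  counts <- readr::read_tsv(
    system.file("extdata", file, package = "immunoreact"),
    col_types = readr::cols(subgroup = "c", level = "c", n = "i"))
  counts_to_samples(counts)
}

# The published discovery-cohort cross-tabulation of the four derived
# subgroups against the external molecular subtype label (counts as
# printed; unclassified samples carried as NA).
tcga_class_fixture <- function() {
  read_counts_fixture("tcga_subgroup_class_counts.tsv")
}

# Orange-subgroup proliferative composition: 31 of 37 classified.
orange_proliferative_fixture <- function() {
  read_counts_fixture("orange_proliferative_counts.tsv")
}

# Small multi-gene survival cohort with planted prognostic genes:
# exponential survival whose log-hazard is beta' x.
make_survival_cohort <- function(n, n_genes, active, beta, seed,
                                 base_rate = log(2) / 40, censor = 120) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%04d", seq_len(n))))
    lp <- drop(beta %*% x[active, , drop = FALSE])
    t_true <- stats::rexp(n, rate = base_rate * exp(lp))
    clinical <- tibble::tibble(
      sample_id = colnames(x),
      study = "sim",
      os_months = pmin(t_true, censor),
      os_event = as.integer(t_true <= censor)
    )
    list(expr = scaled_expr(x), clinical = clinical)
  })
}
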