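test_that("well-separated blobs are partitioned exactly", {
  blobs <- make_blobs(seed = 31)
  asg <- cluster_subgroups(expr_from_scaled(t(blobs$x)),
                           gene_set = colnames(blobs$x), k = 4)
  expect_equal(ari(tidy(asg)$subgroup, blobs$truth), 1)
  # permutation of sample order only renames clusters
  perm <- withr::with_seed(1, sample(nrow(blobs$x)))
  asg_p <- cluster_subgroups(expr_from_scaled(t(blobs$x[perm, ])),
                             gene_set = colnames(blobs$x), k = 4)
  lab_p <- tidy(asg_p)
  lab_p <- lab_p$subgroup[match(tidy(asg)$sample_id, lab_p$sample_id)]
  expect_equal(ari(lab_p, tidy(asg)$subgroup), 1)
})

test_that("degenerate clustering inputs behave predictably", {
  blobs <- make_blobs(n_per = 5, seed = 2)
  m <- expr_from_scaled(t(blobs$x))
  one <- cluster_subgroups(m, colnames(blobs$x), k = 1)
  expect_equal(unname(one$centers[1, ]), unname(colMeans(blobs$x)))
  expect_error(cluster_subgroups(m, colnames(blobs$x), k = 100), "exceeds")
  expect_error(cluster_subgroups(m, c("G1", "NOPE")), "NOPE")

  # duplicated samples always co-cluster
  x <- blobs$x
  x[2, ] <- x[1, ]
  asg <- cluster_subgroups(expr_from_scaled(t(x)), colnames(x), k = 4)
  lab <- tidy(asg)
  expect_equal(lab$subgroup[1], lab$subgroup[2])
})

test_that("within/between SS ratio matches a double-loop oracle", {
  withr::with_seed(7, {
    x <- matrix(rnorm(30), 10, 3,
                dimnames = list(sprintf("S%02d", 1:10), paste0("G", 1:3)))
    lab <- rep(1:2, each = 5)
    asg <- structure(list(
      labels = tibble::tibble(sample_id = rownames(x), subgroup = lab,
                              alias = c("purple", "yellow")[lab]),
      centers = group_centers_for_test(x, lab),
      gene_set = colnames(x)), class = "subgroup_assignment")
    expect_equal(wb_ss_ratio(expr_from_scaled(t(x)), asg),
                 oracle_wb_ss(x, lab), tolerance = 1e-10)
  })

  blobs <- make_blobs(seed = 5)
  asg <- cluster_subgroups(expr_from_scaled(t(blobs$x)),
                           colnames(blobs$x), k = 4)
  expect_lt(wb_ss_ratio(expr_from_scaled(t(blobs$x)), asg), 0.05)
  one <- cluster_subgroups(expr_from_scaled(t(blobs$x)),
                           colnames(blobs$x), k = 1)
  expect_equal(wb_ss_ratio(expr_from_scaled(t(blobs$x)), one), Inf)

  # random labels on a single homogeneous blob separate almost nothing
  withr::with_seed(8, {
    x1 <- matrix(rnorm(400), 100, 4,
                 dimnames = list(sprintf("S%03d", 1:100), paste0("G", 1:4)))
    lab1 <- sample(1:2, 100, replace = TRUE)
    asg1 <- structure(list(
      labels = tibble::tibble(sample_id = rownames(x1), subgroup = lab1,
                              alias = c("purple", "yellow")[lab1]),
      centers = group_centers_for_test(x1, lab1),
      gene_set = colnames(x1)), class = "subgroup_assignment")
    expect_gt(wb_ss_ratio(expr_from_scaled(t(x1)), asg1), 1)
  })
})

test_that("label transfer is seed-consistent and accurate on blob pairs", {
  blobs <- make_blobs(seed = 51)
  m <- expr_from_scaled(t(blobs$x))
  asg <- cluster_subgroups(m, colnames(blobs$x), k = 4)

  # with zero Lloyd iterations, transfer = nearest-centre labels
  back <- transfer_subgroups(asg, m, max_iter = 0)
  d2 <- as.matrix(dist(rbind(asg$centers, blobs$x)))[-(1:4), 1:4]
  expect_equal(tidy(back)$subgroup, unname(apply(d2, 1, which.min)))
  expect_equal(tidy(back)$subgroup, tidy(asg)$subgroup)

  val <- make_blobs(seed = 52)
  trans <- transfer_subgroups(asg, expr_from_scaled(t(val$x)))
  # map each truth cluster to the alias the discovery run gave it
  truth_alias <- vapply(1:4, function(g) {
    tidy(asg)$alias[which(blobs$truth == g)[1]]
  }, character(1))
  agreement <- mean(tidy(trans)$alias == truth_alias[val$truth])
  expect_gte(agreement, 0.95)
  expect_error(transfer_subgroups(asg, expr_from_scaled(
    t(blobs$x[, 1:3]))), "lacks")
})

test_that("clusters left empty after transfer are retained with a warning", {
  blobs <- make_blobs(seed = 61)
  asg <- cluster_subgroups(expr_from_scaled(t(blobs$x)),
                           colnames(blobs$x), k = 4)
  # validation data drawn around only three of the four centres
  val <- make_blobs(seed = 62)
  keep <- val$truth != 4
  expect_warning(
    trans <- transfer_subgroups(asg, expr_from_scaled(t(val$x[keep, ]))),
    "empty cluster")
  expect_equal(nrow(trans$centers), 4L)
  expect_equal(sort(unique(tidy(trans)$subgroup)),
               sort(unique(tidy(asg)$subgroup[blobs$truth != 4])))
})

test_that("stratified log-rank reduces to the classic test with one stratum", {
  withr::with_seed(14, {
    n <- 80
    g <- rep(c("a", "b"), each = n / 2)
    time <- rexp(n, ifelse(g == "a", 1, 2))
    clin <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), study = "only",
                           os_months = time, os_event = 1L)
    res <- stratified_logrank(clin, tibble::tibble(sample_id = clin$sample_id,
                                                   group = g))
    oracle <- oracle_logrank(time, rep(1L, n), g)
    expect_equal(res$chi_square, oracle$chisq, tolerance = 1e-9)
    expect_equal(res$p, oracle$p, tolerance = 1e-9)
    expect_equal(res$df, 1L)
    expect_error(stratified_logrank(
      clin, tibble::tibble(sample_id = clin$sample_id, group = "a")),
      "2 nonempty groups")
  })
})

test_that("a halved hazard is detected by the stratified test", {
  cc <- simulate_cohort(sim_config(study_sizes = c(a = 200, b = 200),
                                   n_background_genes = 20, seed = 23))
  grp <- tibble::tibble(sample_id = cc$truth$ir_labels$sample_id,
                        group = ifelse(cc$truth$ir_labels$ir, "IR", "rest"))
  res <- stratified_logrank(cc$clinical, grp, strata = "study")
  expect_lt(res$p, 0.05)
  expect_equal(res$strata_used, 2L)
})

test_that("cross-tabulation reproduces the published subgroup shares", {
  fix <- tcga_class_fixture()
  asg <- fix[, c("sample_id", "subgroup")]
  xt <- cross_tabulate(asg, fix[, c("sample_id", "level")], "level")
  expect_equal(round(xt$pct_of_group["purple", "Immunoreactive"]), 69)
  expect_lt(xt$p, 0.001)
  expect_equal(sum(xt$counts), sum(!is.na(fix$level)))
  expect_equal(unname(xt$group_n["purple"]), 55L)
  # purple share of the full cohort rounds to 11%
  expect_equal(round(100 * sum(fix$subgroup == "purple") / nrow(fix)), 11)

  orange <- orange_proliferative_fixture()
  xt2 <- cross_tabulate(orange[, c("sample_id", "subgroup")],
                        orange[, c("sample_id", "level")], "level")
  expect_equal(round(xt2$pct_of_classified["orange", "proliferative"]), 84)
})

test_that("association tests switch family with the covariate type", {
  asg <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                        subgroup = rep(c("purple", "orange"), each = 10))
  perfect <- tibble::tibble(sample_id = asg$sample_id,
                            cls = rep(c("yes", "no"), each = 10))
  xt <- cross_tabulate(asg, perfect, "cls")
  expect_lt(xt$p, 0.001)

  withr::with_seed(3, {
    cont <- tibble::tibble(sample_id = asg$sample_id,
                           age = rnorm(20, mean = rep(c(50, 70), each = 10)))
    xt_c <- cross_tabulate(asg, cont, "age")
    expect_equal(xt_c$method, "one-way ANOVA")
    expect_lt(xt_c$p, 0.01)
  })
  missing_all <- tibble::tibble(sample_id = asg$sample_id,
                                z = rep(NA_character_, 20))
  expect_error(cross_tabulate(asg, missing_all, "z"), "entirely missing")
})
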