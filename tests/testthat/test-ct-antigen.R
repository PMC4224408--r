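# Small antigen cohort: IR membership drawn from a logistic model on the
# named active antigens, everything standardized.
make_antigen_cohort <- function(n, n_antigens, effects, prevalence = 0.2,
                                seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * n_antigens), n, n_antigens,
                dimnames = list(sprintf("S%04d", seq_len(n)),
                                sprintf("AG%02d", seq_len(n_antigens))))
    eff <- rep(0, n_antigens)
    names(eff) <- colnames(z)
    eff[names(effects)] <- effects
    b0 <- uniroot(function(b) {
      integrate(function(q) plogis(b + sqrt(sum(eff^2)) * q) * dnorm(q),
                -Inf, Inf)$value - prevalence
    }, c(-30, 30))$root
    ir <- runif(n) < plogis(b0 + drop(z %*% eff))
    list(expr = expr_from_scaled(t(z)),
         ir = tibble::tibble(sample_id = rownames(z), ir = ir),
         effects = eff[eff != 0])
  })
}

test_that("the antigen screen finds exactly the shifted antigens", {
  exact <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      n <- 500
      ir <- rep(c(TRUE, FALSE), c(60, 440))
      v <- matrix(rnorm(20 * n), 20, n,
                  dimnames = list(sprintf("AG%02d", 1:20),
                                  sprintf("S%04d", 1:n)))
      v[1:3, ir] <- v[1:3, ir] - 1        # depleted in IR
      labels <- tibble::tibble(sample_id = colnames(v), ir = ir)
      res <- ir_antigen_screen(scaled_expr(v), labels, rownames(v))
      hits <- res$antigen[res$bonferroni_p < 0.05]
      planted <- res$antigen %in% sprintf("AG%02d", 1:3)
      setequal(hits, sprintf("AG%02d", 1:3)) &&
        all(res$mean_ir[planted] < res$mean_nonir[planted])
    })
  }, logical(1))
  expect_gte(sum(exact), 4L)   # exact recovery in nearly all replicates

  withr::with_seed(50, {
    v <- matrix(rnorm(20 * 100), 20, 100,
                dimnames = list(sprintf("AG%02d", 1:20),
                                sprintf("S%04d", 1:100)))
    labels <- tibble::tibble(sample_id = colnames(v),
                             ir = rep(c(TRUE, FALSE), c(20, 80)))
    # single antigen: Bonferroni is the raw p
    one <- ir_antigen_screen(scaled_expr(v), labels, "AG05")
    expect_equal(one$bonferroni_p, one$t_p)
    skipped <- ir_antigen_screen(scaled_expr(v), labels, c("AG01", "GHOST"))
    expect_equal(attr(skipped, "skipped"), "GHOST")
  })
})

test_that("stepwise BIC keeps a lone strong predictor and drops pure noise", {
  cohort <- make_antigen_cohort(500, 10, c(AG03 = 1.5), seed = 51)
  fit <- stepwise_bic_logistic(cohort$expr, cohort$ir,
                               rownames(expr_values(cohort$expr)))
  expect_equal(names(fit$coefficients), "AG03")
  expect_gt(fit$coefficients["AG03"], 0)
  # the accepted-move trace is strictly decreasing in BIC
  expect_true(all(diff(fit$step_trace$bic) < 0))

  null_cohort <- make_antigen_cohort(300, 8, c(AG01 = 0), seed = 52)
  null_fit <- stepwise_bic_logistic(null_cohort$expr, null_cohort$ir,
                                    sprintf("AG%02d", 1:8))
  expect_length(null_fit$coefficients, 0)
  expect_equal(null_fit$step_trace$action, "start")
})

test_that("tidy and glance expose the regression table and fit summary", {
  cohort <- make_antigen_cohort(400, 6, c(AG01 = -1, AG02 = 1), seed = 53)
  fit <- stepwise_bic_logistic(cohort$expr, cohort$ir, sprintf("AG%02d", 1:6))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in%
                    names(td)))
  expect_equal(nrow(td), length(fit$coefficients) + 1L)
  gl <- glance(fit)
  expect_equal(gl$bic, fit$bic)
  expect_equal(gl$n, 400L)
})

test_that("threshold tuning finds the sensitivity/specificity crossing", {
  sep <- tune_threshold(c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$threshold, 0.8)   # lowest candidate achieving the crossing
  expect_error(tune_threshold(runif(5), rep(TRUE, 5)), "both classes")

  withr::with_seed(54, {
    d <- 1.5
    truth <- rep(c(TRUE, FALSE), each = 2500)
    score <- rnorm(5000, mean = ifelse(truth, d / 2, -d / 2))
    th <- tune_threshold(score, truth)
    expect_lt(abs(th$sensitivity - pnorm(d / 2)), 0.02)
    expect_lt(abs(th$specificity - pnorm(d / 2)), 0.02)
    # permuting labels pushes the operating point to chance symmetry
    perm <- tune_threshold(score, sample(truth))
    expect_lt(abs(perm$sensitivity - (1 - perm$specificity)), 0.05)
  })
})

test_that("IR calls and their survival contrast behave at the extremes", {
  cohort <- make_antigen_cohort(300, 6, c(AG01 = -1.5, AG02 = 1.5), seed = 55)
  fit <- stepwise_bic_logistic(cohort$expr, cohort$ir, sprintf("AG%02d", 1:6))
  withr::with_seed(56, {
    ir <- cohort$ir$ir
    t_true <- rexp(300, rate = log(2) / 44 * ifelse(ir, 0.5, 1))
    clin <- tibble::tibble(sample_id = cohort$ir$sample_id,
                           os_months = pmin(t_true, 120),
                           os_event = as.integer(t_true <= 120))
  })
  out <- predict_ir_and_hr(fit, 0.5, cohort$expr, clin)
  # predicted non-IR patients should do worse (HR > 1)
  expect_gt(out$hr$hazard_ratio, 1)
  expect_true(is.na(out$hr$flag))

  # raising the threshold never adds IR calls
  calls_lo <- predict_ir_and_hr(fit, 0.2, cohort$expr, clin)$calls$ir_call
  calls_hi <- predict_ir_and_hr(fit, 0.8, cohort$expr, clin)$calls$ir_call
  expect_true(all(calls_hi <= calls_lo))

  # an impossible threshold yields a flagged degenerate contrast
  degen <- predict_ir_and_hr(fit, 2, cohort$expr, clin)
  expect_false(any(degen$calls$ir_call))
  expect_match(degen$hr$flag, "degenerate")

  # a coefficient-free model gives one constant probability
  null_cohort <- make_antigen_cohort(300, 5, c(AG01 = 0), seed = 57)
  null_fit <- stepwise_bic_logistic(null_cohort$expr, null_cohort$ir,
                                    sprintf("AG%02d", 1:5))
  probs <- predict(null_fit, null_cohort$expr)
  expect_equal(length(unique(round(probs, 12))), 1L)
})

test_that("antigens partition into non-IR, IR and immune-stimulatory classes", {
  withr::with_seed(58, {
    n <- 500
    ir <- rep(c(TRUE, FALSE), c(100, 400))
    good <- ir & rep(c(TRUE, FALSE), length.out = n)   # half of IR long-lived
    v <- rbind(
      NONIR1 = rnorm(n) + ifelse(ir, -1, 0),     # expressed outside IR
      IRONLY = rnorm(n) + ifelse(ir, 1, 0),      # uniform IR elevation
      STIM1 = rnorm(n) + ifelse(ir & good, 1.6, 0),  # IR good-prognosis only
      FILLER = rnorm(n))
    colnames(v) <- sprintf("S%04d", 1:n)
    os <- ifelse(good, 80, 20) + runif(n, -5, 5)
    clin <- tibble::tibble(sample_id = colnames(v), os_months = os,
                           os_event = 1L)
    res <- antigen_prognostic_partition(
      scaled_expr(v), tibble::tibble(sample_id = colnames(v), ir = ir),
      clin, rownames(v), os_cutoff_months = 33.5)
    expect_equal(res$class[res$antigen == "NONIR1"], "non-IR")
    expect_equal(res$class[res$antigen == "IRONLY"], "IR")
    expect_equal(res$class[res$antigen == "STIM1"], "immune-stimulatory")
    expect_false("FILLER" %in% res$antigen)
    expect_error(antigen_prognostic_partition(
      scaled_expr(v), tibble::tibble(sample_id = colnames(v), ir = ir),
      clin, rownames(v), os_cutoff_months = -1), "positive")
  })
})

test_that("active antigen coefficients are recovered at large n", {
  truth <- c(AG01 = -1.2, AG02 = -0.6, AG03 = 0.6)
  ok <- vapply(1:3, function(s) {
    cohort <- make_antigen_cohort(2000, 12, truth, seed = 100 + s)
    fit <- stepwise_bic_logistic(cohort$expr, cohort$ir,
                                 sprintf("AG%02d", 1:12))
    all(names(truth) %in% names(fit$coefficients)) &&
      all(abs(fit$coefficients[names(truth)] - truth) / abs(truth) < 0.2)
  }, logical(1))
  expect_gte(sum(ok), 2L)
})
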