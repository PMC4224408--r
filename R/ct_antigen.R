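#' Screen CT antigens for association with immunoreactive status
#'
#' Welch two-sample t-test per antigen between IR and non-IR samples, with
#' Bonferroni correction over the number of antigens tested.
#'
#' @param m scaled expression table.
#' @param ir IR labels (see [marker_volcano()] for accepted forms).
#' @param antigens a [gene_panel()] (its `ct_antigen` rows are used) or a
#'   character vector of antigen symbols.
#' @return Tibble with `antigen`, `mean_ir`, `mean_nonir`, `t_p`,
#'   `bonferroni_p`; absent antigens are listed in the `skipped` attribute.
#' @export
ir_antigen_screen <- function(m, ir, antigens) {
  genes <- antigen_symbols(antigens)
  v <- expr_values(m)
  is_ir <- resolve_ir(ir, colnames(v))
  if (sum(is_ir) < 2L || sum(!is_ir) < 2L) {
    stop("both IR classes need at least 2 samples")
  }
  present <- intersect(genes, rownames(v))
  skipped <- setdiff(genes, present)
  res <- purrr::map_dfr(present, function(g) {
    x <- v[g, is_ir]; y <- v[g, !is_ir]
    tibble::tibble(antigen = g, mean_ir = mean(x), mean_nonir = mean(y),
                   t_p = stats::t.test(x, y)$p.value)
  })
  res$bonferroni_p <- pmin(1, res$t_p * length(present))
  attr(res, "skipped") <- skipped
  res
}

antigen_symbols <- function(antigens) {
  if (inherits(antigens, "gene_panel") || is.data.frame(antigens)) {
    g <- antigens$gene[antigens$category == "ct_antigen"]
    if (length(g) == 0L) g <- antigens$gene
    unique(g)
  } else {
    unique(as.character(antigens))
  }
}

#' Bidirectional BIC-stepwise logistic model of IR status
#'
#' Starting from the intercept-only model, repeatedly applies the single
#' antigen addition or removal that most lowers the Bayesian information
#' criterion, stopping when no move lowers it. Ties between moves are
#' broken by antigen name order, so the procedure is deterministic. The
#' response is IR membership; predictors are standardized antigen
#' expression, so coefficients are log-odds per 1-sd expression.
#'
#' @inheritParams ir_antigen_screen
#' @return An object of class `ir_logistic_fit`: list with `model` (the
#'   final `glm`), `intercept`, `coefficients` (named, retained antigens
#'   only), `bic`, `step_trace` (tibble `action`, `antigen`, `bic`),
#'   `separation` flag and `n`.
#' @export
stepwise_bic_logistic <- function(m, ir, antigens) {
  genes <- antigen_symbols(antigens)
  v <- expr_values(m)
  present <- sort(intersect(genes, rownames(v)))
  if (length(present) == 0L) stop("no antigens present in expression table")
  is_ir <- resolve_ir(ir, colnames(v))
  if (min(sum(is_ir), sum(!is_ir)) < 5L) {
    stop("each IR class needs at least 5 samples")
  }
  dat <- data.frame(.ir = as.integer(is_ir),
                    t(v[present, , drop = FALSE]), check.names = FALSE)
  separation <- FALSE
  fit_bic <- function(vars) {
    f <- stats::reformulate(if (length(vars)) sprintf("`%s`", vars) else "1",
                            response = ".ir")
    fit <- withCallingHandlers(
      stats::glm(f, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(fit = fit, bic = stats::BIC(fit))
  }
  current <- fit_bic(character(0))
  vars <- character(0)
  trace <- tibble::tibble(action = "start", antigen = NA_character_,
                          bic = current$bic)
  repeat {
    adds <- sort(setdiff(present, vars))
    drops <- sort(vars)
    moves <- rbind(
      if (length(adds)) data.frame(action = "add", antigen = adds),
      if (length(drops)) data.frame(action = "drop", antigen = drops)
    )
    if (is.null(moves) || nrow(moves) == 0L) break
    bics <- vapply(seq_len(nrow(moves)), function(i) {
      vs <- if (moves$action[i] == "add") c(vars, moves$antigen[i]) else
        setdiff(vars, moves$antigen[i])
      fit_bic(vs)$bic
    }, numeric(1))
    best <- which.min(bics)            # moves are name-sorted: first min wins
    if (bics[best] >= current$bic - 1e-8) break
    vars <- if (moves$action[best] == "add") {
      c(vars, moves$antigen[best])
    } else {
      setdiff(vars, moves$antigen[best])
    }
    current <- fit_bic(vars)
    trace <- dplyr::bind_rows(trace,
                              tibble::tibble(action = moves$action[best],
                                             antigen = moves$antigen[best],
                                             bic = current$bic))
  }
  if (separation) {
    warning("possible complete separation: fitted probabilities reached 0/1")
  }
  cf <- stats::coef(current$fit)
  structure(list(model = current$fit,
                 intercept = unname(cf["(Intercept)"]),
                 coefficients = cf[setdiff(names(cf), "(Intercept)")],
                 bic = current$bic, step_trace = trace,
                 separation = separation, n = nrow(dat),
                 antigens_considered = present),
            class = "ir_logistic_fit")
}

#' @export
print.ir_logistic_fit <- function(x, ...) {
  cat("IR antigen logistic model:", length(x$coefficients),
      "antigens retained of", length(x$antigens_considered),
      sprintf("(BIC %.1f, n = %d)\n", x$bic, x$n))
  if (length(x$coefficients)) print(round(x$coefficients, 3))
  if (x$separation) cat("note: separation flagged\n")
  invisible(x)
}

#' Predict IR probabilities from a fitted antigen model
#'
#' @param object an `ir_logistic_fit`.
#' @param m_val scaled expression table with the retained antigens.
#' @param ... unused.
#' @return Named vector of predicted IR probabilities per sample.
#' @export
predict.ir_logistic_fit <- function(object, m_val, ...) {
  needed <- names(object$coefficients)
  v <- expr_values(m_val)
  missing <- setdiff(needed, rownames(v))
  if (length(missing) > 0L) {
    stop("antigens missing from validation table: ",
         paste(missing, collapse = ", "))
  }
  lin <- object$intercept +
    if (length(needed)) drop(object$coefficients %*%
                               v[needed, , drop = FALSE]) else 0
  stats::setNames(stats::plogis(rep(lin, length.out = ncol(v))), colnames(v))
}

#' Tune the call threshold at the sensitivity/specificity intersection
#'
#' Sweeps candidate thresholds at the observed predicted values (calling IR
#' when probability >= threshold) and returns the threshold minimising
#' |sensitivity - specificity|, breaking ties toward the lower threshold.
#' Intended to be applied to probabilities pooled across all validation
#' studies.
#'
#' @param prob numeric vector of predicted IR probabilities.
#' @param truth logical (or 0/1) vector of true IR status.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`,
#'   `prevalence`.
#' @export
tune_threshold <- function(prob, truth) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L) {
    stop("threshold tuning needs both classes present")
  }
  cands <- sort(unique(prob))
  sens <- vapply(cands, function(t) mean(prob[truth] >= t), numeric(1))
  spec <- vapply(cands, function(t) mean(prob[!truth] < t), numeric(1))
  best <- which.min(abs(sens - spec))     # sorted ascending: first = lowest
  tibble::tibble(threshold = cands[best], sensitivity = sens[best],
                 specificity = spec[best], prevalence = mean(truth))
}

#' IR calls on a validation cohort and their survival contrast
#'
#' Applies the fitted antigen model and threshold to validation expression,
#' calls each sample IR when its predicted probability reaches the
#' threshold, and fits a two-group Cox model contrasting predicted non-IR
#' against predicted IR on overall survival (so a hazard ratio above 1
#' means predicted non-IR patients die faster).
#'
#' @param fit an `ir_logistic_fit`.
#' @param threshold probability threshold (e.g. from [tune_threshold()]).
#' @param m_val scaled validation expression table.
#' @param clin_val validation clinical tibble with `os_months`, `os_event`.
#' @return List with `calls` (tibble `sample_id`, `probability`,
#'   `ir_call`) and `hr` (tibble `hazard_ratio`, `ci_low`, `ci_high`, `p`,
#'   `flag` — flagged `degenerate` when only one class is called).
#' @export
predict_ir_and_hr <- function(fit, threshold, m_val, clin_val) {
  prob <- stats::predict(fit, m_val)
  calls <- tibble::tibble(sample_id = names(prob), probability = unname(prob),
                          ir_call = unname(prob) >= threshold)
  idx <- match(clin_val$sample_id, calls$sample_id)
  if (anyNA(idx)) stop("clinical samples missing from validation expression")
  call_vec <- calls$ir_call[idx]
  if (length(unique(call_vec)) < 2L) {
    hr <- tibble::tibble(hazard_ratio = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_,
                         flag = "degenerate: single predicted class")
  } else {
    x <- factor(ifelse(call_vec, "IR", "nonIR"), levels = c("IR", "nonIR"))
    cox <- survival::coxph(
      survival::Surv(clin_val$os_months, clin_val$os_event) ~ x)
    s <- summary(cox)
    hr <- tibble::tibble(hazard_ratio = unname(s$conf.int[1L, "exp(coef)"]),
                         ci_low = unname(s$conf.int[1L, "lower .95"]),
                         ci_high = unname(s$conf.int[1L, "upper .95"]),
                         p = unname(s$sctest["pvalue"]),
                         flag = NA_character_)
  }
  list(calls = calls, hr = hr)
}

#' Partition antigens into non-IR, IR and immune-stimulatory classes
#'
#' Within the IR subgroup, patients are labelled good or poor prognosis by
#' overall survival dichotomised at `os_cutoff_months` (patients censored
#' before the cutoff carry no information about it and are excluded unless
#' `censored_good = TRUE`). Antigens are then classified over the union of
#' the IR-association screen hits and the good/poor differential hits:
#' antigens higher in non-IR samples are class `non-IR`; antigens higher in
#' IR samples are `immune-stimulatory` when they also separate good from
#' poor prognosis within IR (Bonferroni t-test at `alpha`), otherwise `IR`.
#'
#' @param m scaled expression table.
#' @param ir IR labels.
#' @param clinical clinical tibble with `os_months`, `os_event`.
#' @param antigens antigen panel or symbol vector.
#' @param os_cutoff_months survival dichotomisation point (default 33.5,
#'   an overall-population median).
#' @param censored_good treat patients censored before the cutoff as good
#'   prognosis instead of excluding them.
#' @param alpha Bonferroni level for both screens (default 0.05).
#' @return Tibble with `antigen`, `class`, `ir_screen_p`, `survival_p`
#'   (both Bonferroni-adjusted), `mean_ir`, `mean_nonir`.
#' @export
antigen_prognostic_partition <- function(m, ir, clinical, antigens,
                                         os_cutoff_months = 33.5,
                                         censored_good = FALSE,
                                         alpha = 0.05) {
  if (os_cutoff_months <= 0) stop("os_cutoff_months must be positive")
  v <- expr_values(m)
  is_ir <- resolve_ir(ir, colnames(v))
  if (!any(is_ir)) stop("IR subgroup is empty")
  screen <- ir_antigen_screen(m, ir, antigens)

  clin <- clinical[match(colnames(v), clinical$sample_id), ]
  good <- clin$os_months >= os_cutoff_months
  informative <- good | clin$os_event == 1       # death before cutoff: poor
  if (censored_good) informative <- rep(TRUE, length(good))
  ir_good <- which(is_ir & informative & good)
  ir_poor <- which(is_ir & informative & !good)
  if (length(ir_good) < 2L || length(ir_poor) < 2L) {
    stop("OS cutoff leaves an empty (or singleton) good/poor class")
  }
  surv_p <- vapply(screen$antigen, function(g) {
    stats::t.test(v[g, ir_good], v[g, ir_poor])$p.value
  }, numeric(1))
  surv_p_adj <- pmin(1, surv_p * nrow(screen))

  res <- dplyr::mutate(
    screen,
    survival_p = surv_p_adj,
    higher_in_ir = .data$mean_ir > .data$mean_nonir,
    ir_hit = .data$bonferroni_p < alpha,
    surv_hit = surv_p_adj < alpha
  )
  res <- dplyr::filter(res, .data$ir_hit | .data$surv_hit)
  res$class <- dplyr::case_when(
    !res$higher_in_ir ~ "non-IR",
    res$surv_hit ~ "immune-stimulatory",
    TRUE ~ "IR"
  )
  dplyr::select(res, antigen = "antigen", class = "class",
                ir_screen_p = "bonferroni_p", survival_p = "survival_p",
                mean_ir = "mean_ir", mean_nonir = "mean_nonir")
}
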