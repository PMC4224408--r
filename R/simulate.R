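#' Simulation configuration for synthetic multi-study cohorts
#'
#' Defines the generative model that the downstream analysis stages assume:
#' a bimodal expression background (an unexpressed "noise" peak plus an
#' expressed "signal" peak), an equicorrelated immune-gene block elevated in
#' an immunoreactive (IR) subgroup covering about 11% of samples, exponential
#' overall/progression-free survival with a reduced hazard in the IR
#' subgroup, several studies with additive mean offsets, planted mediator
#' chains (a latent driver X inducing marginal correlation between A and B),
#' and cancer-testis antigens whose standardized expression shifts the
#' log-odds of IR membership.
#'
#' @param study_sizes integer vector of per-study sample counts.
#' @param n_background_genes number of unstructured background genes.
#' @param panel immune + CT antigen [gene_panel()].
#' @param ir_fraction marginal probability of IR membership.
#' @param block_rho equicorrelation of the immune block.
#' @param ir_shift mean immune-block elevation in IR samples, in residual-sd
#'   units.
#' @param baseline_median_os,baseline_median_pfs median survival in months
#'   for non-IR samples.
#' @param ir_hazard_ratio multiplicative hazard in the IR subgroup (<1 means
#'   protective).
#' @param censor_admin administrative censoring time, months.
#' @param mediator_chains list of character triples `c(A, X, B)`.
#' @param mediator_loading loading of A and B on the latent driver X.
#' @param antigen_effects named numeric vector: per-1-sd log-odds of IR
#'   membership for active antigens. The default plants six active antigens,
#'   four protective-class-depleting and two enriching, with one twice the
#'   magnitude of the others.
#' @param noise_sd residual expression noise standard deviation.
#' @param seed integer seed; every draw in [simulate_cohort()] is derived
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(study_sizes = c(discovery = 100, validationA = 50,
                                       validationB = 50, validationC = 30),
                       n_background_genes = 1000,
                       panel = default_gene_panel(),
                       ir_fraction = 0.11,
                       block_rho = 0.6,
                       ir_shift = 1.5,
                       baseline_median_os = 44,
                       baseline_median_pfs = 18,
                       ir_hazard_ratio = 0.5,
                       censor_admin = 120,
                       mediator_chains = list(c("HLA-DQA2", "GZMA", "GZMK")),
                       mediator_loading = 0.8,
                       antigen_effects = c(CTNNA2 = -1.2, CEP290 = -0.6,
                                           TMEFF1 = -0.6, TEX15 = -0.6,
                                           ZNF164 = 0.6, MAGEA3 = 0.6),
                       noise_sd = 1,
                       seed = 1L) {
  if (is.null(names(study_sizes))) {
    names(study_sizes) <- paste0("study", seq_along(study_sizes))
  }
  cfg <- list(study_sizes = study_sizes,
              n_background_genes = n_background_genes, panel = panel,
              ir_fraction = ir_fraction, block_rho = block_rho,
              ir_shift = ir_shift, baseline_median_os = baseline_median_os,
              baseline_median_pfs = baseline_median_pfs,
              ir_hazard_ratio = ir_hazard_ratio, censor_admin = censor_admin,
              mediator_chains = mediator_chains,
              mediator_loading = mediator_loading,
              antigen_effects = antigen_effects,
              noise_sd = noise_sd, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!all(study_sizes >= 10)) stop("every study needs at least 10 samples")
    if (ir_fraction <= 0 || ir_fraction >= 1) stop("ir_fraction must be in (0,1)")
    if (ir_hazard_ratio <= 0) stop("ir_hazard_ratio must be positive")
    if (block_rho < 0 || block_rho >= 1) stop("block_rho must be in [0,1)")
    if (abs(mediator_loading) >= 1) stop("|mediator_loading| must be < 1")
    if (ir_fraction * sum(study_sizes) < 2) {
      stop("infeasible configuration: expected fewer than 2 IR samples")
    }
  })
  invisible(cfg)
}

# intercept b0 with E[plogis(b0 + s Z)] = target for Z ~ N(0,1),
# s = ||antigen effect vector||
solve_ir_intercept <- function(effects, target) {
  s <- sqrt(sum(effects^2))
  if (s < 1e-12) return(stats::qlogis(target))
  marginal <- function(b0) {
    stats::integrate(function(z) stats::plogis(b0 + s * z) * stats::dnorm(z),
                     -Inf, Inf)$value - target
  }
  stats::uniroot(marginal, c(-40, 40), tol = 1e-10)$root
}

#' Simulate a synthetic multi-study ovarian cancer cohort
#'
#' Draws expression, clinical and ground-truth tables under the generative
#' model described in [sim_config()]. Antigens are drawn first and IR
#' membership is then sampled from the antigen logistic model, so the
#' antigen classifier stage has a recoverable truth; the logistic intercept
#' is solved numerically so that the marginal IR rate equals `ir_fraction`.
#' Non-IR samples are split into three strata echoing the poor-prognosis
#' subgroups: a heterogeneous stratum (random half of the immune block at
#' half the IR shift), a uniformly intermediate stratum, and a low stratum.
#' Survival is exponential with administrative censoring so proportional
#' hazards holds exactly and screen calibration is testable.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `expression` (unscaled [expr_table()]),
#'   `clinical` (tibble, one row per sample), and `truth` (IR labels,
#'   subgroup labels, mediator triples, active antigen coefficients).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n_per <- cfg$study_sizes
  n <- sum(n_per)
  study <- rep(names(n_per), n_per)
  sample_id <- sprintf("%s_S%03d", study, unlist(lapply(n_per, seq_len)))
  study_offset <- stats::setNames(stats::rnorm(length(n_per), 0, 0.5),
                                  names(n_per))
  study_offset[1L] <- 0
  off <- study_offset[study]

  immune <- panel_subset(cfg$panel, setdiff(panel_categories(), "ct_antigen"))
  antigens <- panel_subset(cfg$panel, "ct_antigen")
  n_imm <- nrow(immune)
  n_ant <- nrow(antigens)

  # antigens drive IR membership through a logistic model
  z_ant <- matrix(stats::rnorm(n * n_ant), n, n_ant,
                  dimnames = list(sample_id, antigens$gene))
  eff <- cfg$antigen_effects[names(cfg$antigen_effects) %in% antigens$gene]
  lin <- solve_ir_intercept(eff, cfg$ir_fraction) +
    if (length(eff) > 0L) drop(z_ant[, names(eff), drop = FALSE] %*% eff) else 0
  ir <- stats::runif(n) < stats::plogis(lin)

  # subgroup labels: 1 purple (IR), then heterogeneous / medium / low strata
  subgroup <- integer(n)
  subgroup[ir] <- 1L
  subgroup[!ir] <- sample(2:4, sum(!ir), replace = TRUE,
                          prob = c(0.56, 0.35, 0.09))

  # immune block: equicorrelated via a per-sample latent factor
  base_imm <- stats::rnorm(n_imm, 6, 0.5)
  f <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n_imm * n), n_imm, n)
  block <- sqrt(cfg$block_rho) * matrix(f, n_imm, n, byrow = TRUE) +
    sqrt(1 - cfg$block_rho) * eps
  shift <- matrix(0, n_imm, n)
  shift[, subgroup == 1L] <- cfg$ir_shift
  shift[, subgroup == 3L] <- cfg$ir_shift / 2
  het <- which(subgroup == 2L)
  for (s in het) {
    on <- sample.int(n_imm, ceiling(n_imm / 2))
    shift[on, s] <- cfg$ir_shift / 2
  }
  v_imm <- base_imm + rep(off, each = n_imm) +
    cfg$noise_sd * (block + shift)
  rownames(v_imm) <- immune$gene

  # background genes: bimodal mean distribution (noise peak vs signal peak)
  n_bg <- cfg$n_background_genes
  peak <- stats::runif(n_bg) < 0.45
  mu_bg <- ifelse(peak, stats::rnorm(n_bg, 4, 0.5), stats::rnorm(n_bg, 8, 1))
  v_bg <- mu_bg + rep(off, each = n_bg) +
    cfg$noise_sd * matrix(stats::rnorm(n_bg * n), n_bg, n)
  rownames(v_bg) <- sprintf("BG%04d", seq_len(n_bg))

  v_ant <- stats::rnorm(n_ant, 5, 1) + rep(off, each = n_ant) +
    cfg$noise_sd * t(z_ant)
  rownames(v_ant) <- antigens$gene

  v <- rbind(v_imm, v_ant, v_bg)
  colnames(v) <- sample_id

  # mediator chains: X latent driver, A and B conditionally independent
  # given X; chain rows override any same-named gene
  l <- cfg$mediator_loading
  for (ch in cfg$mediator_chains) {
    x <- stats::rnorm(n)
    trip <- rbind(l * x + sqrt(1 - l^2) * stats::rnorm(n),
                  x,
                  l * x + sqrt(1 - l^2) * stats::rnorm(n))
    trip <- 6 + rep(off, each = 3L) + cfg$noise_sd * trip
    rownames(trip) <- ch
    v <- v[setdiff(rownames(v), ch), , drop = FALSE]
    v <- rbind(v, trip)
  }

  # exponential survival, administrative censoring
  hr <- ifelse(ir, cfg$ir_hazard_ratio, 1)
  t_os <- stats::rexp(n, rate = log(2) / cfg$baseline_median_os * hr)
  t_pfs <- stats::rexp(n, rate = log(2) / cfg$baseline_median_pfs * hr)
  clinical <- tibble::tibble(
    sample_id = sample_id,
    study = study,
    os_months = pmin(t_os, cfg$censor_admin),
    os_event = as.integer(t_os <= cfg$censor_admin),
    pfs_months = pmin(t_pfs, cfg$censor_admin),
    pfs_event = as.integer(t_pfs <= cfg$censor_admin),
    age = round(stats::rnorm(n, 60, 10)),
    stage = sample(c("III", "IV", "I", "II"), n, TRUE,
                   prob = c(0.7, 0.2, 0.05, 0.05)),
    grade = sample(c("2", "3"), n, TRUE, prob = c(0.3, 0.7)),
    debulking = sample(c("optimal", "suboptimal"), n, TRUE,
                       prob = c(0.35, 0.65)),
    platinum = sample(c("sensitive", "resistant"), n, TRUE,
                      prob = c(0.65, 0.35)),
    external_class = ifelse(
      stats::runif(n) < ifelse(ir, 0.7, 0.13), "Immunoreactive", "Other")
  )

  truth <- list(
    ir_labels = tibble::tibble(sample_id = sample_id, ir = ir),
    subgroups = tibble::tibble(sample_id = sample_id, subgroup = subgroup),
    mediators = cfg$mediator_chains,
    active_antigens = eff
  )
  list(expression = expr_table(v), clinical = clinical, truth = truth)
}

#' Simulate a null cohort with all effects removed
#'
#' Identical machinery to [simulate_cohort()] with the IR expression shift,
#' the IR survival benefit, all antigen effects and all mediator loadings
#' set to zero. Ground-truth labels are still emitted (IR membership is then
#' a pure `ir_fraction` coin flip), so calibration tests can stratify on
#' them.
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort()].
#' @export
simulate_null_cohort <- function(cfg = sim_config()) {
  cfg$ir_shift <- 0
  cfg$ir_hazard_ratio <- 1
  cfg$antigen_effects <- cfg$antigen_effects * 0
  cfg$mediator_loading <- 0
  simulate_cohort(cfg)
}

#' Simulate a single latent-mediator chain
#'
#' Generates three gene rows A, X, B where X is standard normal, and A and B
#' each load on X with the given loading and independent residuals scaled to
#' unit variance, so that cor(A, B) = loading^2 marginally while A and B are
#' conditionally independent given X.
#'
#' @param n number of samples (>= 10).
#' @param loading loading of A and B on X, |loading| < 1.
#' @param seed integer seed.
#' @param genes names for the three rows, in order (A, X, B).
#' @return An unscaled [expr_table()] with three gene rows.
#' @export
simulate_mediator_chain <- function(n, loading, seed = 1L,
                                    genes = c("A", "X", "B")) {
  if (n < 10) stop("n must be at least 10")
  if (abs(loading) >= 1) stop("|loading| must be < 1")
  stopifnot(length(genes) == 3L)
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    v <- rbind(loading * x + sqrt(1 - loading^2) * stats::rnorm(n),
               x,
               loading * x + sqrt(1 - loading^2) * stats::rnorm(n))
    rownames(v) <- genes
    colnames(v) <- sprintf("S%04d", seq_len(n))
    expr_table(v)
  })
}
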