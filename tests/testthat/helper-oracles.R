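# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# Cox partial-likelihood score test at beta = 0 (distinct event times).
oracle_cox_score <- function(time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  u <- 0; v <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    xb <- mean(x[risk])
    u <- u + x[i] - xb
    v <- v + mean((x[risk] - xb)^2)
  }
  stat <- u^2 / v
  list(u = u, v = v, stat = stat,
       p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Product-limit estimator: survival curve at each distinct event time.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    n_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = times, surv = surv)
}

oracle_km_median <- function(time, event) {
  km <- oracle_km(time, event)
  below <- which(km$surv <= 0.5)
  if (length(below) == 0L) NA_real_ else km$time[min(below)]
}

# k-group log-rank chi-square (unstratified), generalized-inverse form.
oracle_logrank <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  obs <- exp_ <- numeric(k)
  vmat <- matrix(0, k, k)
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    d <- sum(time == t0 & event == 1)
    ni <- tapply(at_risk, group, sum); ni[is.na(ni)] <- 0
    di <- tapply(time == t0 & event == 1, group, sum); di[is.na(di)] <- 0
    obs <- obs + di
    exp_ <- exp_ + d * ni / n
    if (n > 1) {
      for (i in seq_len(k)) for (j in seq_len(k)) {
        vmat[i, j] <- vmat[i, j] +
          d * (n - d) / (n - 1) * (ni[i] / n) * ((i == j) - ni[j] / n)
      }
    }
  }
  o_e <- (obs - exp_)[-k]
  stat <- drop(t(o_e) %*% solve(vmat[-k, -k, drop = FALSE]) %*% o_e)
  list(chisq = stat,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Partial correlation matrix from the pseudo-inverse of the correlation.
oracle_pcor_matrix <- function(x) {
  r <- stats::cor(x)
  sv <- svd(r)
  pos <- sv$d > max(dim(r)) * .Machine$double.eps * max(sv$d)
  omega <- sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
  d <- sqrt(diag(omega))
  pc <- -omega / outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(r)
  pc
}

# Partial correlation of (a, b) given Z via explicit lm residuals + t-test.
oracle_residual_pcor <- function(a, b, z = NULL) {
  if (is.null(z) || NCOL(z) == 0L) {
    ra <- a - mean(a); rb <- b - mean(b); k <- 0L
  } else {
    z <- as.matrix(z)
    ra <- stats::residuals(stats::lm(a ~ z))
    rb <- stats::residuals(stats::lm(b ~ z))
    k <- ncol(z)
  }
  r <- sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
  df <- length(a) - k - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  list(pcor = r, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
}

# Within/between sum-of-squares ratio by explicit double loop.
oracle_wb_ss <- function(x, labels) {
  grand <- colMeans(x)
  within <- 0; between <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    for (i in seq_len(nrow(xg))) within <- within + sum((xg[i, ] - cg)^2)
    between <- between + nrow(xg) * sum((cg - grand)^2)
  }
  within / between
}

# Adjusted Rand index from the contingency table.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
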