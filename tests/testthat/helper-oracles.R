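# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive quantities from first principles and never
# call the package functions they are used to check.

# k-th order statistic of all pairwise absolute differences, by enumeration
oracle_qn_kernel <- function(x) {
  n <- length(x)
  h <- n %/% 2L + 1L
  k <- h * (h - 1L) / 2
  d <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) d <- c(d, abs(x[i] - x[j]))
  }
  sort(d)[k]
}

# hand product-limit estimator at event times
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  s <- 1
  out <- numeric(0)
  times <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out <- c(out, s)
    times <- c(times, t)
  }
  list(time = times, surv = out)
}

# two-group log-rank via hypergeometric accumulation over event times
oracle_logrank2 <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1L
  oe <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    oe <- oe + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- oe^2 / v
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# 1-covariate Cox log partial likelihood (Breslow; exact when no ties)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, x) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, x),
                  c(-10, 10), tol = 1e-9)$minimum
}

# random log2 ExpressionMatrix fixture
toy_matrix <- function(n_genes = 10, n_samples = 6, seed = 1,
                       roles = "unknown", genes = NULL) {
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(n_genes))
  v <- matrix(rnorm(length(genes) * n_samples, 7, 1), length(genes),
              n_samples,
              dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  expression_matrix(v, scale = "log2", sample_roles = roles)
}

# tumour/normal matrix with planted shifts
tn_matrix <- function(n_genes = 50, n_per_class = 10, planted = NULL,
                      sd = 0.5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  mu <- runif(n_genes, 5, 9)
  fc <- setNames(rep(0, n_genes), genes)
  if (!is.null(planted)) fc[names(planted)] <- planted
  n <- n_per_class
  v <- matrix(rnorm(n_genes * 2 * n, sd = sd), n_genes, 2 * n) + mu +
    outer(fc, c(rep(0, n), rep(1, n)))
  dimnames(v) <- list(genes, c(sprintf("N%02d", 1:n), sprintf("T%02d", 1:n)))
  expression_matrix(v, scale = "log2",
                    sample_roles = c(rep("normal", n), rep("tumour", n)))
}
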