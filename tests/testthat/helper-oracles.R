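# Independent oracles used to check the package implementations.
# Each is written from the definition, not from the code it checks.

# Harrell's C by exhaustive enumeration over all ordered pairs.
oracle_harrell_c <- function(risk, time, event) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # which member of the pair fails first, observably?
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next  # both events or both censored: unusable
        first <- if (event[i] == 1) i else j
        second <- if (first == i) j else i
      } else {
        first <- if (time[i] < time[j]) i else j
        second <- if (first == i) j else i
        if (event[first] != 1) next
      }
      den <- den + 1
      if (risk[first] > risk[second]) num <- num + 1
      else if (risk[first] == risk[second]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (same margins) no more probable than
# the observed one.
oracle_fisher_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Logistic-lasso solver by proximal gradient (ISTA) on the glmnet objective
#   (1/n) * sum[-y eta + log(1 + exp(eta))] + lambda * ||beta||_1
# with an unpenalized intercept.
oracle_logistic_lasso <- function(x, y, lambda, maxit = 200000, tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  beta <- rep(0, p); b0 <- 0
  step <- 4 / max(eigen(crossprod(x) / n, only.values = TRUE)$values + 1)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  obj_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- b0 + drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, mu - y)) / n
    g0 <- mean(mu - y)
    beta <- soft(beta - step * g, step * lambda)
    b0 <- b0 - step * g0
    if (it %% 200 == 0) {
      obj <- mean(-y * eta + log1p(exp(eta))) + lambda * sum(abs(beta))
      if (abs(obj_old - obj) < tol) break
      obj_old <- obj
    }
  }
  list(intercept = b0, beta = beta)
}
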