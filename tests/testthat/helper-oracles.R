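# Independent brute-force oracles, deliberately kept separate from the
# package's own code paths.

# dominant eigenvalue/eigenvector via base dense eigensolver
oracle_eigen <- function(m) {
  e <- eigen(m)
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  list(lambda = Re(e$values[i]), weights = v / sum(v))
}

# dominant eigenvalue of a 3x3 matrix by characteristic-polynomial roots
oracle_lambda_3x3 <- function(m) {
  stopifnot(nrow(m) == 3, ncol(m) == 3)
  # det(m - x I) = -x^3 + tr(m) x^2 - c1 x + det(m), c1 = sum of 2x2 principal minors
  tr <- sum(diag(m))
  c1 <- det(m[-1, -1]) + det(m[-2, -2]) + det(m[-3, -3])
  roots <- polyroot(c(det(m), -c1, tr, -1))
  max(Re(roots[abs(Im(roots)) < 1e-8]))
}

# brute-force disproportionality statistics from first principles
oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_ror_ci <- function(a, b, c, d, z = qnorm(0.975)) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lr <- log(oracle_ror(a, b, c, d))
  c(exp(lr - z * se), exp(lr + z * se))
}
oracle_chi2 <- function(a, b, c, d, yates = FALSE) {
  obs <- matrix(c(a, c, b, d), 2, 2)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  dev <- abs(obs - expd)
  if (yates) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / expd)
}

# exact expectation of an integer score drawn as round(Normal(mu, sigma))
# clipped to [1, 10] (the score simulator's sampling scheme)
oracle_discrete_score_mean <- function(mu, sigma) {
  if (sigma == 0) return(pmin(10, pmax(1, round(mu))))
  k <- 2:9
  p_mid <- pnorm((k + 0.5 - mu) / sigma) - pnorm((k - 0.5 - mu) / sigma)
  1 * pnorm((1.5 - mu) / sigma) + sum(k * p_mid) +
    10 * (1 - pnorm((9.5 - mu) / sigma))
}

# random reciprocal judgment matrix with entries clipped to the Saaty range
random_pcm <- function(n, sd = 0.6) {
  m <- diag(n)
  up <- which(upper.tri(m))
  m[up] <- pmin(9, pmax(1 / 9, exp(rnorm(length(up), 0, sd))))
  m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
  pcm(m, permissive = TRUE)
}
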