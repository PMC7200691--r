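# Independent oracles, deliberately written with different algorithms than
# the package code paths they check.

# OLS by explicit normal equations; returns coef, se, p for each column of X
oracle_ols <- function(y, X) {
  X <- cbind(1, X)
  XtX <- t(X) %*% X
  bh <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bh
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tt <- bh / se
  list(coef = drop(bh), se = se, p = 2 * pt(-abs(tt), df), df = df)
}

# logistic regression by hand-rolled IRLS
oracle_irls <- function(y, X, tol = 1e-12, maxit = 100) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    XtWX <- t(X) %*% (W * X)
    bnew <- solve(XtWX, t(X) %*% (W * z))
    if (max(abs(bnew - b)) < tol) { b <- bnew; break }
    b <- bnew
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  se <- sqrt(diag(solve(t(X) %*% ((mu * (1 - mu)) * X))))
  list(coef = drop(b), se = se)
}

# Benjamini-Hochberg step-up written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# exact HWE p-value by direct enumeration of genotype tables with the same
# allele counts, probabilities from the multinomial/hypergeometric identity
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  hs <- seq(0, min(nA, 2 * n - nA))
  hs <- hs[(nA - hs) %% 2 == 0 & (2 * n - nA - hs) %% 2 == 0 &
             (nA - hs) >= 0 & (2 * n - nA - hs) >= 0]
  pr <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    bb <- (2 * n - nA - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[hs == nAa]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# REML for y = g + e with g ~ N(0, sg2 K), K = ZZ'/p (standardized Z),
# profiled over h2 = sg2/(sg2+se2) via the eigendecomposition of K
oracle_reml_pve <- function(y, Z) {
  K <- tcrossprod(Z) / ncol(Z)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y - mean(y)))
  n <- length(y)
  nll <- function(h2) {
    d <- h2 * lam + (1 - h2)
    s2 <- mean(yt^2 / d)
    0.5 * (sum(log(d)) + n * log(s2))
  }
  opt <- optimize(nll, c(1e-4, 1 - 1e-4))
  opt$minimum
}

# weighted least squares slope/intercept by explicit normal equations
oracle_wls <- function(y, x, w) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  unname(drop(b))
}
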