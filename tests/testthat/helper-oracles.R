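# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately dumb and slow: quadrature, direct
# numerical minimization, regression residuals -- never the package's own
# computational path.

# bivariate normal lower-tail probability by one-dimensional quadrature
bvn_oracle <- function(h, k, rho) {
  if (h == Inf) return(pnorm(k))
  if (k == Inf) return(pnorm(h))
  if (h == -Inf || k == -Inf) return(0)
  stats::integrate(function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
                   -Inf, h, rel.tol = 1e-12)$value
}

# population correlation matrix of a one-factor model
onefactor_cor <- function(lambda) {
  C <- tcrossprod(lambda)
  diag(C) <- 1
  C
}

# random positive-definite correlation matrix (data based, so always PD)
random_pd_cor <- function(J, n = 200) {
  X <- matrix(rnorm(n * J), n, J)
  # mix in a little common structure so correlations are not all tiny
  X <- X + rnorm(n) %*% t(runif(J, 0.2, 0.8))
  cor(X)
}

# discretized bivariate-normal sample as a response_matrix
gen_discrete_biv <- function(n, rho, tau1 = 0, tau2 = 0) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  x <- cbind(findInterval(z1, tau1), findInterval(z2, tau2))
  response_matrix(x, categories = cbind(c(0L, 0L),
                                        c(length(tau1), length(tau2))))
}

# direct numerical minimization of the one-factor ULS loss, multi-start
brute_uls <- function(C, n_starts = 6) {
  J <- ncol(C)
  loss <- function(lam) {
    R <- C - tcrossprod(lam)
    sum(R[upper.tri(R)]^2)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) rep(0.5, J) else runif(J, -0.9, 0.9)
    fit <- optim(start, loss, method = "L-BFGS-B",
                 lower = rep(-1, J), upper = rep(1, J),
                 control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (sum(best$par) < 0) best$par <- -best$par
  best
}

# per-item MSA from explicitly computed partial correlations: for each
# pair (j, k), partial out all remaining variables by least squares on
# synthetic data whose sample correlation matrix equals C.
msa_oracle <- function(C) {
  J <- ncol(C)
  # factorize C so that crossprod(L) = C, then treat L's columns as data
  L <- chol(C)
  Q <- matrix(0, J, J)
  for (j in seq_len(J - 1)) {
    for (k in (j + 1):J) {
      rest <- setdiff(seq_len(J), c(j, k))
      if (length(rest) == 0) {
        q <- -C[j, k]  # 2-variable convention: anti-image = -r
      } else {
        rj <- L[, j] - L[, rest, drop = FALSE] %*%
          solve(crossprod(L[, rest, drop = FALSE]),
                crossprod(L[, rest, drop = FALSE], L[, j]))
        rk <- L[, k] - L[, rest, drop = FALSE] %*%
          solve(crossprod(L[, rest, drop = FALSE]),
                crossprod(L[, rest, drop = FALSE], L[, k]))
        q <- sum(rj * rk) / sqrt(sum(rj^2) * sum(rk^2))
      }
      Q[j, k] <- Q[k, j] <- q
    }
  }
  R2 <- C^2; diag(R2) <- 0
  rowSums(R2) / (rowSums(R2) + rowSums(Q^2))
}

# ten-item screening fixture: 8 benign items, one extreme item
# (target P .95, h2 .6), one pure-noise item (lambda 0); 5 categories.
fixture_pop <- function() {
  h2 <- c(runif(8, 0.30, 0.49), 0.6, 0)
  tP <- c(runif(8, 0.3, 0.7), 0.95, 0.5)
  list(lambda = sqrt(h2), h2 = h2, target_P = tP,
       thresholds = lapply(tP, function(p) thresholds_for_target(5, p)),
       n_categories = 5L)
}

# negative log-likelihood of a polychoric table, written independently in
# R on top of the package's CDF kernel only through the public bvn_cdf
poly_negll_oracle <- function(tab, tau_r, tau_c, rho) {
  R <- nrow(tab); C <- ncol(tab)
  ar <- c(-Inf, tau_r, Inf); ac <- c(-Inf, tau_c, Inf)
  G <- outer(seq_len(R + 1), seq_len(C + 1),
             Vectorize(function(i, j) bvn_oracle(ar[i], ac[j], rho)))
  P <- G[-1, -1] + G[-(R + 1), -(C + 1)] - G[-1, -(C + 1)] - G[-(R + 1), -1]
  -sum(tab * log(pmax(P, 1e-12)))
}
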