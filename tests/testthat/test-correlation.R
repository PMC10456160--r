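test_that("threshold estimation inverts cumulative proportions", {
  expect_equal(as.numeric(estimate_thresholds(c(50, 50))), 0)
  # 160/40 of N = 200: tau = qnorm(0.8), 0.8416 in the inverse-normal table
  expect_equal(as.numeric(estimate_thresholds(c(160, 40))), 0.8416,
               tolerance = 1e-4)
  expect_equal(as.numeric(estimate_thresholds(rep(25, 4))),
               qnorm(c(0.25, 0.5, 0.75)))
  # zero-count categories are dropped, thresholds stay strictly increasing
  tau <- estimate_thresholds(c(30, 0, 70))
  expect_equal(as.numeric(tau), qnorm(0.3))
  expect_equal(attr(tau, "kept"), c(1L, 3L))
  expect_error(estimate_thresholds(c(0, 100, 0)), "degenerate")
})

test_that("Pearson matrix handles collinear, reversed and degenerate items", {
  x <- cbind(a = c(0L, 1L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L, 1L))
  C <- pearson_matrix(response_matrix(x, c(0, 1)))
  expect_equal(unclass(C)[1, 2], 1.0)
  expect_false(attr(C, "is_pd"))

  y <- cbind(a = c(0L, 1L, 0L, 1L, 1L), b = 1L - c(0L, 1L, 0L, 1L, 1L))
  expect_equal(unclass(pearson_matrix(response_matrix(y, c(0, 1))))[1, 2], -1.0)

  z <- cbind(a = c(0L, 1L, 0L), b = c(1L, 1L, 1L))
  expect_error(pearson_matrix(response_matrix(z, c(0, 1))), "'b'")
})

test_that("Pearson correlations of discretized normal data are attenuated", {
  set.seed(101)
  n <- 10000; rho <- 0.5
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cuts <- qnorm(seq(0.2, 0.8, by = 0.2))  # 5 codes
  x <- cbind(findInterval(z1, cuts), findInterval(z2, cuts))
  C <- pearson_matrix(response_matrix(x, c(0, 4)))
  expect_lt(unclass(C)[1, 2], rho)
  expect_gt(unclass(C)[1, 2], 0.35)
})

test_that("bivariate normal CDF matches quadrature to high accuracy", {
  grid <- expand.grid(h = c(-2.5, -1, 0, 0.7, 2.2),
                      k = c(-2, -0.4, 0, 1.3),
                      rho = c(-0.99, -0.8, -0.4, 0, 0.3, 0.9, 0.95, 0.999))
  got <- mapply(function(h, k, r) bvn_cdf(h, k, r), grid$h, grid$k, grid$rho)
  want <- mapply(bvn_oracle, grid$h, grid$k, grid$rho)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("polychoric pair recovers zero, boundary and known correlations", {
  # independence: rows proportional to columns
  tab0 <- outer(c(60, 40), c(30, 70)) * 100
  r0 <- polychoric_pair(tab0, qnorm(0.6), qnorm(0.3))
  expect_lt(abs(as.numeric(r0)), 0.02)

  # perfect association hits the correlation bound
  rb <- polychoric_pair(matrix(c(50, 0, 0, 50), 2), 0, 0)
  expect_gte(as.numeric(rb), 0.99)

  # Monte-Carlo recovery at N = 10000, both margins split at 0
  set.seed(7)
  rm <- gen_discrete_biv(10000, 0.6)
  tab <- table(rm$data[, 1], rm$data[, 2])
  r <- polychoric_pair(tab, 0, 0)
  expect_lt(abs(as.numeric(r) - 0.6), 0.03)
})

test_that("pair estimate maximizes the same likelihood as a rho grid search", {
  set.seed(42)
  grid <- seq(-0.99, 0.99, by = 0.001)
  for (i in 1:10) {
    R <- sample(2:4, 1); C <- sample(2:4, 1)
    tab <- matrix(rpois(R * C, 12) + 1, R, C)
    tau_r <- sort(rnorm(R - 1)); tau_c <- sort(rnorm(C - 1))
    est <- polychoric_pair(tab, tau_r, tau_c)
    ll_est <- attr(est, "logLik")
    ll_grid <- max(-vapply(grid, function(r)
      gpool:::poly_negll_cpp(tab, tau_r, tau_c, r), numeric(1)))
    expect_lt(ll_grid - ll_est, 0.001)
  }
})

test_that("polychoric matrix composes pairs and flags definiteness", {
  set.seed(11)
  rm <- gen_discrete_biv(500, 0.4)
  Cm <- polychoric_matrix(rm)
  tab <- table(rm$data[, 1], rm$data[, 2])
  cnt1 <- table(factor(rm$data[, 1], 0:1))
  cnt2 <- table(factor(rm$data[, 2], 0:1))
  pair <- polychoric_pair(tab, estimate_thresholds(cnt1),
                          estimate_thresholds(cnt2))
  expect_equal(unclass(Cm)[1, 2], as.numeric(pair))
  expect_equal(attr(Cm, "estimator"), "polychoric")

  # one-factor binary data, all loadings .6: off-diagonals near .36
  set.seed(12)
  lam <- rep(0.6, 5)
  pop <- list(lambda = lam, h2 = lam^2, target_P = rep(0.5, 5),
              thresholds = replicate(5, 0, simplify = FALSE),
              n_categories = 2L)
  big <- generate_replicate(pop, 10000)
  Cb <- polychoric_matrix(big)
  off <- unclass(Cb)[upper.tri(Cb)]
  expect_lt(max(abs(off - 0.36)), 0.03)

  # independent items: comfortably positive definite
  set.seed(13)
  ind <- response_matrix(matrix(rbinom(200 * 5, 1, 0.5), 200, 5), c(0, 1))
  expect_true(attr(polychoric_matrix(ind), "is_pd"))
})

test_that("eigen diagnosis separates definite from indefinite matrices", {
  d <- pd_diagnose(diag(3))
  expect_equal(d$min_eigenvalue, 1)
  expect_true(d$is_pd)

  # equicorrelation r = -0.6, J = 3: eigenvalues 1 - r (twice) and 1 + 2r
  E <- matrix(-0.6, 3, 3); diag(E) <- 1
  d2 <- pd_diagnose(E)
  expect_equal(d2$min_eigenvalue, 1 + 2 * (-0.6))
  expect_false(d2$is_pd)

  M <- matrix(0.99, 3, 3); diag(M) <- 1; M[1, 2] <- M[2, 1] <- -0.5
  expect_false(pd_diagnose(M)$is_pd)
  expect_equal(pd_diagnose(M)$min_eigenvalue,
               min(eigen(M, symmetric = TRUE)$values))
})

test_that("correlation engines are invariant to respondent order", {
  set.seed(21)
  pop <- list(lambda = rep(0.6, 4), h2 = rep(0.36, 4),
              target_P = c(0.3, 0.5, 0.6, 0.7),
              thresholds = lapply(c(0.3, 0.5, 0.6, 0.7), function(p)
                thresholds_for_target(3, p)),
              n_categories = 3L)
  rm <- generate_replicate(pop, 300)
  perm <- rm
  idx <- sample(rm$n_respondents)
  perm$data <- rm$data[idx, ]
  expect_equal(unclass(pearson_matrix(perm)), unclass(pearson_matrix(rm)))
  expect_equal(unclass(polychoric_matrix(perm)), unclass(polychoric_matrix(rm)))
})

test_that("polychoric exceeds Pearson on average for discretized normals", {
  set.seed(31)
  diffs <- replicate(200, {
    rm <- gen_discrete_biv(200, 0.5, qnorm(0.4), qnorm(0.65))
    abs(unclass(polychoric_matrix(rm))[1, 2]) -
      abs(unclass(pearson_matrix(rm))[1, 2])
  })
  expect_gt(mean(diffs), 0)
})

test_that("correlation matrices write to annotated TSV", {
  set.seed(41)
  rm <- gen_discrete_biv(300, 0.5)
  C <- polychoric_matrix(rm)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cor_matrix(C, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# estimator=polychoric is_pd=TRUE")
  back <- as.matrix(read.table(path, skip = 1, header = TRUE, row.names = 1,
                               sep = "\t", check.names = FALSE))
  vals <- matrix(as.numeric(C), nrow(C))
  expect_equal(unname(back), vals, tolerance = 1e-9)
})
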