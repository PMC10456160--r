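#' Eigenvalue diagnosis of a correlation matrix
#'
#' Declares a symmetric correlation matrix positive definite when its
#' smallest eigenvalue exceeds `pd_tolerance`. Indefinite matrices are a
#' terminal outcome in the screening cascade: they are flagged, never
#' smoothed or repaired.
#'
#' @param C square numeric matrix.
#' @param pd_tolerance smallest admissible eigenvalue (default `1e-8`).
#' @return list with `min_eigenvalue` and `is_pd`.
#' @export
pd_diagnose <- function(C, pd_tolerance = 1e-8) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  min_ev <- min(ev)
  list(min_eigenvalue = min_ev, is_pd = is.finite(min_ev) && min_ev > pd_tolerance)
}

# internal constructor: tag a correlation matrix with its estimator and
# eigen diagnostics. Symmetry is enforced to machine precision and the
# diagonal set exactly to 1.
new_cor_matrix <- function(values, estimator, pd_tolerance = 1e-8) {
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("correlation matrix is not symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  d <- pd_diagnose(values, pd_tolerance)
  structure(values, class = c("gpool_cor", class(values)),
            estimator = estimator,
            min_eigenvalue = d$min_eigenvalue, is_pd = d$is_pd,
            pd_tolerance = pd_tolerance)
}

#' @export
print.gpool_cor <- function(x, digits = 3, ...) {
  cat(sprintf("%s correlation matrix (%d x %d), min eigenvalue %.3g, %s\n",
              attr(x, "estimator"), nrow(x), ncol(x),
              attr(x, "min_eigenvalue"),
              if (attr(x, "is_pd")) "positive definite" else
                "NOT positive definite"))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Pearson inter-item correlation matrix
#'
#' Product-moment correlations of the raw integer codes, the input of the
#' linear factor model. Items with zero sample variance make the matrix
#' undefined and raise an error naming the item.
#'
#' @param rm a [response_matrix()].
#' @param pd_tolerance passed to [pd_diagnose()].
#' @return a `gpool_cor` matrix with `estimator = "pearson"` and eigen
#'   diagnostics in its attributes.
#' @export
pearson_matrix <- function(rm, pd_tolerance = 1e-8) {
  stopifnot(inherits(rm, "response_matrix"))
  v <- apply(rm$data, 2L, stats::var)
  if (any(v == 0)) {
    j <- which(v == 0)[1L]
    stop(sprintf("item '%s' has zero variance; Pearson matrix undefined",
                 rm$item_labels[j]))
  }
  new_cor_matrix(stats::cor(rm$data), "pearson", pd_tolerance)
}

#' Normal thresholds from category frequencies
#'
#' Estimates the cut points of a standard-normal latent response variable
#' from the marginal category counts: `tau_c` is the normal quantile of
#' the cumulative proportion up to category `c`. Categories with zero
#' counts are dropped before estimation, so the thresholds are strictly
#' increasing; an item with all its mass in one category is degenerate.
#'
#' @param counts per-category frequencies (in category order).
#' @return numeric vector of `C - 1` thresholds, where `C` is the number
#'   of non-empty categories. The indices of the retained categories are
#'   attached as attribute `kept`.
#' @export
#' @examples
#' estimate_thresholds(c(160, 40))  # qnorm(0.8)
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || sum(counts) <= 0)
    stop("at least one nonzero count is required")
  kept <- which(counts > 0)
  if (length(kept) < 2L) stop("degenerate item: all mass in one category")
  p <- counts[kept] / sum(counts)
  tau <- stats::qnorm(cumsum(p)[-length(p)])
  attr(tau, "kept") <- kept
  tau
}

#' Two-step polychoric correlation for one item pair
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' given fixed thresholds: `rho` maximizes the multinomial log-likelihood
#' of the observed contingency table under bivariate-normal rectangle
#' probabilities. The search is a bounded scalar (Brent-type)
#' optimization on `[-rho_max, rho_max]`. Tables containing a zero cell
#' get 0.5 added to every cell before the likelihood is evaluated; cell
#' probabilities are floored at 1e-12 inside the log-likelihood.
#'
#' @param tab two-way contingency table (rows = first item's categories).
#' @param tau_r,tau_c threshold vectors of the row and column items; their
#'   lengths must be one less than the corresponding table dimension.
#' @param rho_max bound of the admissible correlation (default 0.999).
#' @return the estimated correlation (scalar), with the maximized
#'   log-likelihood attached as attribute `logLik`.
#' @export
polychoric_pair <- function(tab, tau_r, tau_c, rho_max = 0.999) {
  tab <- as.matrix(tab)
  if (nrow(tab) != length(tau_r) + 1L || ncol(tab) != length(tau_c) + 1L)
    stop("table dimensions do not match threshold counts + 1")
  if (any(tab == 0)) tab <- tab + 0.5
  negll <- function(rho) poly_negll_cpp(tab, tau_r, tau_c, rho)
  opt <- stats::optimize(negll, interval = c(-rho_max, rho_max),
                         tol = 1e-7)
  if (!is.finite(opt$objective))
    stop("polychoric optimizer failed to converge")
  # optimize() never returns the exact interval ends; snap to the bound
  # when the likelihood keeps increasing there (perfect-association tables)
  rho <- opt$minimum
  for (b in c(-rho_max, rho_max)) {
    if (abs(rho - b) < 1e-4 && negll(b) <= opt$objective) {
      rho <- b
      opt$objective <- negll(b)
    }
  }
  structure(rho, logLik = -opt$objective)
}

#' Polychoric inter-item correlation matrix
#'
#' Two-step estimation: thresholds per item from the marginal category
#' counts, then one bounded ML search per item pair with thresholds held
#' fixed. Indefinite matrices are returned as such (`is_pd = FALSE` in
#' the attributes) and never repaired; for binary items the estimate is
#' the tetrachoric correlation.
#'
#' @inheritParams pearson_matrix
#' @param rho_max pairwise correlation bound, see [polychoric_pair()].
#' @return a `gpool_cor` matrix with `estimator = "polychoric"`.
#' @export
polychoric_matrix <- function(rm, rho_max = 0.999, pd_tolerance = 1e-8) {
  stopifnot(inherits(rm, "response_matrix"))
  J <- ncol(rm$data)
  n <- nrow(rm$data)
  # per-item thresholds on non-empty categories; remember which codes remain
  taus <- vector("list", J)
  codes <- vector("list", J)
  for (j in seq_len(J)) {
    lev <- rm$categories[j, 1L]:rm$categories[j, 2L]
    cnt <- tabulate(rm$data[, j] - rm$categories[j, 1L] + 1L,
                    nbins = length(lev))
    tau <- tryCatch(estimate_thresholds(cnt), error = function(e)
      stop(sprintf("item '%s': %s", rm$item_labels[j], conditionMessage(e)),
           call. = FALSE))
    taus[[j]] <- as.numeric(tau)
    codes[[j]] <- lev[attr(tau, "kept")]
  }
  R <- diag(1, J)
  for (j in seq_len(J - 1L)) {
    fj <- factor(rm$data[, j], levels = codes[[j]])
    for (k in (j + 1L):J) {
      fk <- factor(rm$data[, k], levels = codes[[k]])
      tab <- table(fj, fk)
      r <- tryCatch(
        polychoric_pair(tab, taus[[j]], taus[[k]], rho_max = rho_max),
        error = function(e)
          stop(sprintf("pair (%d, %d): %s", j, k, conditionMessage(e)),
               call. = FALSE))
      R[j, k] <- R[k, j] <- as.numeric(r)
    }
  }
  dimnames(R) <- list(rm$item_labels, rm$item_labels)
  new_cor_matrix(R, "polychoric", pd_tolerance)
}

#' Bivariate standard-normal lower-tail probability
#'
#' `P(X <= h, Y <= k)` for standard normal `(X, Y)` with correlation
#' `rho`, by Gauss-Legendre quadrature accurate to about 1e-14.
#' Vectorized over `h` and `k`.
#'
#' @param h,k upper limits (recycled to a common length).
#' @param rho correlation in `(-1, 1)`.
#' @return numeric vector of probabilities.
#' @export
bvn_cdf <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho), abs(rho) < 1)
  nn <- max(length(h), length(k))
  bvn_cdf_cpp(rep_len(as.numeric(h), nn), rep_len(as.numeric(k), nn), rho)
}

#' Write a correlation matrix as TSV
#'
#' One comment line records the estimator and the eigen diagnostics, then
#' the labelled matrix follows in tab-separated form.
#'
#' @param C a `gpool_cor` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cor_matrix <- function(C, path) {
  stopifnot(inherits(C, "gpool_cor"))
  header <- sprintf("# estimator=%s is_pd=%s min_eigenvalue=%.12g",
                    attr(C, "estimator"), attr(C, "is_pd"),
                    attr(C, "min_eigenvalue"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(unclass(C), digits = 10), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
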