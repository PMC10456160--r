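#' One-factor unweighted least squares extraction
#'
#' MINRES-style extraction of a single factor: minimizes the sum of
#' squared off-diagonal residuals of `C - lambda lambda'` by iterating
#' the leading eigenpair of the reduced matrix (diagonal replaced by the
#' current communalities, started at the squared multiple correlations).
#' The loading signs are fixed so that their sum is non-negative.
#'
#' A Heywood case is recorded whenever an iterate's loading reaches 1 in
#' absolute value (communality at or above 1) before clipping; the
#' returned loadings are clipped to `[-1, 1]`.
#'
#' @param C symmetric correlation matrix with unit diagonal.
#' @param tol convergence tolerance on the maximum communality change
#'   (default 1e-6).
#' @param max_iter iteration cap (default 200); when reached, the best
#'   iterate is returned with `converged = FALSE`.
#' @return object of class `factor_solution`: list with `loadings`,
#'   `communalities`, `converged`, `n_iter`, `heywood`, `residual_rms`.
#' @export
uls_one_factor <- function(C, tol = 1e-6, max_iter = 200) {
  V <- unclass(C)
  J <- ncol(V)
  stopifnot(nrow(V) == J, J >= 2)
  if (max(abs(V - t(V))) > 1e-8) stop("correlation matrix must be symmetric")

  comm <- tryCatch(pmin(pmax(smc_all(V), 0), 0.998),
                   error = function(e) {
                     r2 <- apply(V^2 - diag(J), 2L, max)
                     pmin(r2, 0.998)
                   })
  heywood <- FALSE
  converged <- FALSE
  lambda <- rep(0, J)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Vr <- V
    diag(Vr) <- comm
    e <- eigen(Vr, symmetric = TRUE)
    lam <- e$vectors[, 1L] * sqrt(max(e$values[1L], 0))
    if (any(abs(lam) >= 1) || any(lam^2 >= 1)) heywood <- TRUE
    lam <- pmin(pmax(lam, -1), 1)
    new_comm <- lam^2
    delta <- max(abs(new_comm - comm))
    comm <- new_comm
    lambda <- lam
    if (delta < tol) { converged <- TRUE; break }
  }
  if (sum(lambda) < 0) lambda <- -lambda
  resid <- V - tcrossprod(lambda)
  off <- resid[upper.tri(resid)]
  structure(
    list(loadings = lambda, communalities = lambda^2,
         converged = converged, n_iter = it, heywood = heywood,
         residual_rms = sqrt(mean(off^2))),
    class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 3, ...) {
  cat(sprintf(
    "One-factor ULS solution (%s in %d iterations%s), residual rms %.4g\n",
    if (x$converged) "converged" else "NOT converged", x$n_iter,
    if (x$heywood) ", Heywood case" else "", x$residual_rms))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Loading bias against the population
#'
#' Absolute difference between estimated and population loadings, either
#' for one focal item or averaged over all items. Sign-invariant: the
#' estimated vector is aligned with the population vector before the
#' difference is taken.
#'
#' @param est a `factor_solution` or numeric loading vector.
#' @param pop_lambda population loading vector.
#' @param item_index focal item; `NULL` averages `|bias|` over all items.
#' @return non-negative bias value.
#' @export
loading_bias <- function(est, pop_lambda, item_index = NULL) {
  lam <- if (inherits(est, "factor_solution")) est$loadings else as.numeric(est)
  stopifnot(length(lam) == length(pop_lambda))
  if (sum(lam * pop_lambda) < 0) lam <- -lam
  d <- abs(lam - pop_lambda)
  if (is.null(item_index)) mean(d) else d[item_index]
}

#' Sampling instability of a focal loading
#'
#' Variance of the focal item's ULS loading across an inner bootstrap:
#' rows are resampled with replacement, the model's correlation matrix is
#' re-estimated and the one-factor solution refitted on each resample.
#' Indefinite or degenerate resamples are dropped; when fewer than half
#' of the requested resamples are usable the item is deemed unstable and
#' `Inf` is returned.
#'
#' @param rm a [response_matrix()].
#' @param focal_item item index whose loading is tracked.
#' @param model `"linear"` or `"graded"` correlation engine.
#' @param inner_B number of bootstrap resamples (default 50).
#' @param seed optional integer seed for the resampling.
#' @return the bootstrap loading variance, with the number of usable
#'   resamples attached as attribute `n_used`.
#' @export
instability_metric <- function(rm, focal_item, model = c("linear", "graded"),
                               inner_B = 50, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(rm, "response_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- rm$n_respondents
  lam <- rep(NA_real_, inner_B)
  for (b in seq_len(inner_B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- rm_subset_rows(rm, idx)
    C <- tryCatch(
      if (model == "linear") pearson_matrix(sub) else polychoric_matrix(sub),
      error = function(e) NULL)
    if (is.null(C) || !isTRUE(attr(C, "is_pd"))) next
    fit <- uls_one_factor(C)
    lam[b] <- fit$loadings[focal_item]
  }
  used <- sum(!is.na(lam))
  if (used < inner_B / 2)
    return(structure(Inf, n_used = used))
  structure(stats::var(lam[!is.na(lam)]), n_used = used)
}
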