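#' Item extremeness in proportion metric
#'
#' The item mean linearly rescaled by the declared category range, so the
#' index is normed between 0 and 1 regardless of the response format. For
#' 0/1 items it is the classical difficulty index (proportion correct or
#' endorsed).
#'
#' @param item_scores integer vector of responses to one item.
#' @param min_code,max_code declared category range, `max_code > min_code`.
#' @return extremeness `P` in `[0, 1]`.
#' @export
#' @examples
#' extremeness(c(1, 3, 5, 1, 3, 5), 1, 5)  # 0.5
extremeness <- function(item_scores, min_code, max_code) {
  if (length(item_scores) == 0L) stop("empty score vector")
  if (max_code <= min_code) stop("max_code must exceed min_code")
  (mean(item_scores) - min_code) / (max_code - min_code)
}

# internal: SMC for every item; errors on indefinite input
smc_all <- function(C) {
  if (!isTRUE(attr(C, "is_pd")) && !pd_diagnose(C)$is_pd)
    stop("SMC undefined on non-PD matrix")
  1 - 1 / diag(solve(unclass(C)))
}

#' Prior communality: squared multiple correlation
#'
#' `h2_j = 1 - 1/(C^-1)_jj`, the squared multiple correlation of item `j`
#' regressed on all remaining items. It is a lower bound of the item's
#' true communality, available before any factor solution is specified,
#' and it can never reach 1 on a positive-definite matrix (hence the
#' screening cascade's Heywood check, which uses it, fires with
#' structural rate zero).
#'
#' @param C positive-definite correlation matrix (a `gpool_cor` or plain
#'   matrix).
#' @param j optional item index; when missing all items are returned.
#' @return squared multiple correlation(s) in `[0, 1)`.
#' @export
prior_communality <- function(C, j = NULL) {
  h2 <- smc_all(C)
  if (is.null(j)) h2 else h2[j]
}

#' Per-item measure of sampling adequacy (MSA)
#'
#' The Kaiser-Meyer-Olkin style per-item index contrasting raw against
#' anti-image (partial) correlations:
#' `MSA_j = sum(r_jk^2) / (sum(r_jk^2) + sum(q_jk^2))` over `k != j`,
#' where `q_jk = -(C^-1)_jk / sqrt((C^-1)_jj (C^-1)_kk)` is the partial
#' correlation of items j and k given all others. Values below 0.5 mark
#' "noisy" items that behave almost at random with respect to the rest
#' of the pool.
#'
#' @inheritParams prior_communality
#' @return MSA value(s) in `[0, 1]`; an item uncorrelated with every
#'   other item gets 0 by convention.
#' @export
msa_item <- function(C, j = NULL) {
  if (!isTRUE(attr(C, "is_pd")) && !pd_diagnose(C)$is_pd)
    stop("MSA undefined on non-PD matrix")
  V <- unclass(C)
  Ci <- solve(V)
  s <- 1 / sqrt(diag(Ci))
  Q <- -Ci * outer(s, s)          # anti-image partial correlations
  diag(Q) <- 0
  R2 <- V^2; diag(R2) <- 0
  num <- rowSums(R2)
  den <- num + rowSums(Q^2)
  out <- ifelse(den > 0, num / den, 0)
  names(out) <- rownames(V)
  if (is.null(j)) out else out[j]
}

#' Prior item efficiency (PIE)
#'
#' `PIE = h2 * P * (1 - P)`: the marginal approximation of the expected
#' item information, with the squared multiple correlation standing in
#' for the squared multidimensional discrimination. Efficiency vanishes
#' at the extremes (`P` of 0 or 1) and grows with consistency.
#'
#' @param h2 prior communality in `[0, 1)`.
#' @param P extremeness in `[0, 1]`.
#' @return PIE value(s), non-negative.
#' @export
#' @examples
#' pie_index(0.5625, 0.5)  # 0.140625
pie_index <- function(h2, P) {
  stopifnot(all(h2 >= 0), all(P >= 0 & P <= 1))
  h2 * P * (1 - P)
}

#' Relative prior item efficiency (R-PIE)
#'
#' PIE normed by the maximum attainable under the consistency ceiling
#' `h_upper`: `R-PIE = PIE / (h_upper^2 * 0.25)`. Equals 1 for an item of
#' medium extremeness sitting exactly at the ceiling; values above 1 are
#' possible when `h2 > h_upper^2` and are reported as is.
#'
#' @inheritParams pie_index
#' @param h_upper consistency ceiling (default 0.75, the appropriateness
#'   region's upper bound for `h`).
#' @return R-PIE value(s).
#' @export
r_pie <- function(h2, P, h_upper = 0.75) {
  if (h_upper <= 0) stop("h_upper must be positive")
  pie_index(h2, P) / (h_upper^2 * 0.25)
}

#' Item information profile over the latent trait
#'
#' Pointwise information `I(theta) = sum_a2 * P(theta) (1 - P(theta))`
#' for an item with squared multidimensional discrimination `sum_a2` and
#' response curve `P(theta)`, plus its standard-normal-weighted average
#' over the grid. The averaged value is the quantity PIE approximates
#' through the marginal extremeness.
#'
#' @param sum_a2 squared multidimensional discrimination (scalar, >= 0).
#' @param theta_grid latent trait grid.
#' @param item_curve function of theta returning response probabilities,
#'   or a numeric vector of probabilities on the grid.
#' @return list with `theta_grid`, `info`, `sum_a2` and
#'   `expected_info` (normal-weighted grid average).
#' @export
info_profile <- function(sum_a2, theta_grid = seq(-4, 4, length.out = 161),
                         item_curve) {
  p <- if (is.function(item_curve)) item_curve(theta_grid)
       else rep_len(as.numeric(item_curve), length(theta_grid))
  stopifnot(sum_a2 >= 0, all(p >= 0 & p <= 1))
  info <- sum_a2 * p * (1 - p)
  w <- stats::dnorm(theta_grid)
  list(theta_grid = theta_grid, info = info, sum_a2 = sum_a2,
       expected_info = sum(w * info) / sum(w))
}

#' Per-item screening coordinates
#'
#' Computes the full coordinate table used by the pool screening: the
#' extremeness `P`, prior communality `h2` and consistency `h`, the
#' per-item MSA, and the PIE / R-PIE efficiency indices. The linear
#' model reads them off the Pearson matrix, the graded model off the
#' polychoric matrix.
#'
#' @param rm a [response_matrix()].
#' @param model `"linear"` (Pearson) or `"graded"` (polychoric).
#' @param C optional precomputed `gpool_cor` matrix matching `model`.
#' @param h_upper consistency ceiling for R-PIE.
#' @return data frame with one row per item: `label`, `P`, `h2`, `h`,
#'   `msa`, `pie`, `r_pie`.
#' @export
item_coordinates <- function(rm, model = c("linear", "graded"), C = NULL,
                             h_upper = 0.75) {
  model <- match.arg(model)
  stopifnot(inherits(rm, "response_matrix"))
  if (is.null(C))
    C <- if (model == "linear") pearson_matrix(rm) else polychoric_matrix(rm)
  if (!isTRUE(attr(C, "is_pd")))
    stop("correlation matrix is not positive definite; screening indices undefined")
  J <- ncol(rm$data)
  P <- vapply(seq_len(J), function(j)
    extremeness(rm$data[, j], rm$categories[j, 1L], rm$categories[j, 2L]),
    numeric(1))
  h2 <- unname(prior_communality(C))
  data.frame(label = rm$item_labels, P = P, h2 = h2, h = sqrt(h2),
             msa = unname(msa_item(C)), pie = pie_index(h2, P),
             r_pie = r_pie(h2, P, h_upper), stringsAsFactors = FALSE)
}
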