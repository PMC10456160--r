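#' Appropriateness region configuration
#'
#' The rectangle of item coordinates considered safe for item factor
#' analysis, together with the MSA threshold of the noisy-item screen and
#' the consistency ceiling used by R-PIE. The defaults are the
#' simulation-calibrated common region for both factor models:
#' extremeness between .10 and .90 and consistency between .20 and .75,
#' with the conventional .50 MSA cutoff.
#'
#' @param ex_lo,ex_hi extremeness bounds (`0 <= ex_lo < ex_hi <= 1`).
#' @param h_lo,h_hi consistency bounds (`0 <= h_lo < h_hi <= 1`).
#' @param msa_threshold per-item MSA below this flags a noisy item.
#' @param h_upper consistency ceiling of the R-PIE norm.
#' @return object of class `region_config`.
#' @export
region_config <- function(ex_lo = 0.10, ex_hi = 0.90, h_lo = 0.20,
                          h_hi = 0.75, msa_threshold = 0.50,
                          h_upper = 0.75) {
  stopifnot(ex_lo >= 0, ex_lo < ex_hi, ex_hi <= 1,
            h_lo >= 0, h_lo < h_hi, h_hi <= 1, h_upper > 0)
  structure(list(ex_lo = ex_lo, ex_hi = ex_hi, h_lo = h_lo, h_hi = h_hi,
                 msa_threshold = msa_threshold, h_upper = h_upper),
            class = "region_config")
}

#' @export
print.region_config <- function(x, ...) {
  cat(sprintf(
    "Appropriateness region: P in [%.2f, %.2f], h in [%.2f, %.2f]; MSA >= %.2f; h_upper = %.2f\n",
    x$ex_lo, x$ex_hi, x$h_lo, x$h_hi, x$msa_threshold, x$h_upper))
  invisible(x)
}

#' Bootstrap confidence intervals for item coordinates
#'
#' Percentile intervals for each item's extremeness `P` and consistency
#' `h`, obtained by resampling respondents (rows) with replacement and
#' recomputing both coordinates on every resample through the chosen
#' model's correlation matrix. Resamples whose correlation matrix is
#' indefinite or degenerate (a real possibility for the graded model on
#' extreme binary items) are dropped and counted; more than half dropped
#' aborts with an error.
#'
#' @param rm a [response_matrix()].
#' @param model `"linear"` (Pearson) or `"graded"` (polychoric).
#' @param B number of bootstrap resamples (default 500, minimum 100).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed; fixing it makes the whole report
#'   reproducible.
#' @return object of class `gpool_boot`: list with `ci_P` and `ci_h`
#'   (`J x 2` matrices of lower/upper limits), `level`, `B`,
#'   `n_dropped`, `model`.
#' @export
bootstrap_coordinates <- function(rm, model = c("linear", "graded"), B = 500,
                                  level = 0.95, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(rm, "response_matrix"), B >= 100, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rm$n_respondents
  J <- ncol(rm$data)
  bp <- matrix(NA_real_, B, J)
  bh <- matrix(NA_real_, B, J)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- rm_subset_rows(rm, idx)
    C <- tryCatch(
      if (model == "linear") pearson_matrix(sub) else polychoric_matrix(sub),
      error = function(e) NULL)
    if (is.null(C) || !isTRUE(attr(C, "is_pd"))) next
    bp[b, ] <- vapply(seq_len(J), function(j)
      extremeness(sub$data[, j], sub$categories[j, 1L], sub$categories[j, 2L]),
      numeric(1))
    bh[b, ] <- sqrt(pmax(smc_all(C), 0))
  }
  ok <- !is.na(bp[, 1L])
  n_dropped <- sum(!ok)
  if (n_dropped > B / 2)
    stop(sprintf("bootstrap unstable: %d of %d resamples unusable",
                 n_dropped, B))
  if (n_dropped > 0)
    message(sprintf("bootstrap: dropped %d of %d resamples (degenerate or non-PD)",
                    n_dropped, B))
  a <- (1 - level) / 2
  ci <- function(M) t(apply(M[ok, , drop = FALSE], 2L, stats::quantile,
                            probs = c(a, 1 - a), names = FALSE))
  ci_P <- ci(bp); ci_h <- ci(bh)
  dimnames(ci_P) <- dimnames(ci_h) <- list(rm$item_labels, c("lo", "hi"))
  structure(list(ci_P = ci_P, ci_h = ci_h, level = level, B = B,
                 n_dropped = n_dropped, model = model),
            class = "gpool_boot")
}

#' Flag items against the appropriateness region
#'
#' The robust flagging rule: an axis flags an item only when **both**
#' confidence limits fall outside the region on the same side of the
#' same boundary; an interval that straddles a boundary does not flag.
#' The two axes are judged independently. The MSA screen uses the point
#' estimate against the region's threshold. `point_in_region` reports
#' where the point estimate itself sits, for diagnostics.
#'
#' @param coords coordinate table from [item_coordinates()].
#' @param boot intervals from [bootstrap_coordinates()] (or `NULL` to
#'   collapse the intervals onto the point estimates, which reduces the
#'   rule to point-in-region classification).
#' @param region a [region_config()].
#' @return data frame of class `gpool_flags`: the coordinates, CI limits,
#'   `point_in_region`, `flag_extremeness` / `flag_consistency`
#'   (`"none"`, `"low"`, `"high"`), `flag_msa`, `decision`
#'   (`"keep"`/`"flag"`), and `r_pie_rank`.
#' @export
flag_items <- function(coords, boot = NULL, region = region_config()) {
  stopifnot(is.data.frame(coords), inherits(region, "region_config"))
  if (is.null(boot)) {
    ci_P <- cbind(coords$P, coords$P)
    ci_h <- cbind(coords$h, coords$h)
  } else {
    ci_P <- boot$ci_P
    ci_h <- boot$ci_h
  }
  axis_flag <- function(lo, hi, b_lo, b_hi)
    ifelse(hi < b_lo, "low", ifelse(lo > b_hi, "high", "none"))
  f_ex <- axis_flag(ci_P[, 1L], ci_P[, 2L], region$ex_lo, region$ex_hi)
  f_h <- axis_flag(ci_h[, 1L], ci_h[, 2L], region$h_lo, region$h_hi)
  f_msa <- coords$msa < region$msa_threshold
  decision <- ifelse(f_ex != "none" | f_h != "none" | f_msa, "flag", "keep")
  in_region <- coords$P >= region$ex_lo & coords$P <= region$ex_hi &
    coords$h >= region$h_lo & coords$h <= region$h_hi
  rk <- integer(nrow(coords))
  rk[order(-coords$r_pie, seq_len(nrow(coords)))] <- seq_len(nrow(coords))
  out <- data.frame(
    label = coords$label, P = coords$P, P_lo = ci_P[, 1L], P_hi = ci_P[, 2L],
    h = coords$h, h_lo = ci_h[, 1L], h_hi = ci_h[, 2L], h2 = coords$h2,
    msa = coords$msa, pie = coords$pie, r_pie = coords$r_pie,
    point_in_region = in_region, flag_extremeness = f_ex,
    flag_consistency = f_h, flag_msa = f_msa, decision = decision,
    r_pie_rank = rk, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gpool_flags", "data.frame")
  out
}

#' Two-step item selection
#'
#' Step 1 removes every flagged item (outside-region on either axis, or
#' below the MSA threshold). Step 2 sorts the survivors by R-PIE in
#' decreasing order (ties keep the input order) and, when `keep_k` is
#' given, truncates to the `keep_k` most efficient items.
#'
#' @param report a `gpool_flags` table from [flag_items()].
#' @param keep_k number of items to keep, or `NULL` for all survivors.
#' @return character vector of kept item labels, in R-PIE order.
#' @export
select_items <- function(report, keep_k = NULL) {
  stopifnot(inherits(report, "gpool_flags"))
  keep <- report[report$decision == "keep", , drop = FALSE]
  if (nrow(keep) == 0L) stop("empty pool: every item was flagged")
  keep <- keep[order(-keep$r_pie, seq_len(nrow(keep))), , drop = FALSE]
  if (!is.null(keep_k)) keep <- keep[seq_len(min(keep_k, nrow(keep))), ,
                                     drop = FALSE]
  keep$label
}

#' Full pool screening pipeline
#'
#' Computes coordinates, bootstrap intervals, region flags and the
#' selection in one call.
#'
#' @inheritParams bootstrap_coordinates
#' @param region a [region_config()].
#' @param keep_k optional truncation passed to [select_items()].
#' @return object of class `gpool_screen`: list with `coordinates`,
#'   `bootstrap`, `report`, `kept`, `region`, `model`, `seed`.
#' @export
gpool_screen <- function(rm, model = c("linear", "graded"),
                         region = region_config(), B = 500, level = 0.95,
                         seed = NULL, keep_k = NULL) {
  model <- match.arg(model)
  coords <- item_coordinates(rm, model, h_upper = region$h_upper)
  boot <- bootstrap_coordinates(rm, model, B = B, level = level, seed = seed)
  report <- flag_items(coords, boot, region)
  kept <- tryCatch(select_items(report, keep_k), error = function(e) character())
  structure(list(coordinates = coords, bootstrap = boot, report = report,
                 kept = kept, region = region, model = model, seed = seed),
            class = "gpool_screen")
}

#' @export
print.gpool_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Pool screening (%s model, B = %d, %.0f%% CI)\n",
              x$model, x$bootstrap$B, 100 * x$bootstrap$level))
  print(x$region)
  df <- x$report
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat("Kept (R-PIE order):",
      if (length(x$kept)) paste(x$kept, collapse = ", ") else "<none>", "\n")
  invisible(x)
}

#' Split-sample replication check
#'
#' Splits the respondents at random into two halves, screens each half
#' independently, and reports the per-item agreement of the keep/flag
#' decisions. Agreement near 1 indicates the selection would replicate
#' in a fresh sample.
#'
#' @inheritParams gpool_screen
#' @param fraction proportion of rows in the first half (default 0.5).
#' @return list with `report_A`, `report_B` (both `gpool_flags`) and
#'   `agreement` (fraction of items with identical decision).
#' @export
split_sample_check <- function(rm, fraction = 0.5, seed = NULL,
                               model = c("linear", "graded"),
                               region = region_config(), B = 500,
                               level = 0.95) {
  model <- match.arg(model)
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- rm$n_respondents
  idx <- sample.int(n, floor(n * fraction))
  half <- function(rows) {
    sub <- rm_subset_rows(rm, rows)
    flag_items(item_coordinates(sub, model, h_upper = region$h_upper),
               bootstrap_coordinates(sub, model, B = B, level = level),
               region)
  }
  rep_A <- half(idx)
  rep_B <- half(setdiff(seq_len(n), idx))
  list(report_A = rep_A, report_B = rep_B,
       agreement = mean(rep_A$decision == rep_B$decision))
}
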