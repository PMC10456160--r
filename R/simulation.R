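#' Simulation condition for the region-calibration study
#'
#' One cell of the Monte-Carlo design: five ordinal items measuring one
#' factor, four of them "medium" (extremeness levels 4-7 paired in order
#' with communality bands .30-.34, .35-.39, .40-.44, .45-.49) and a fifth
#' focal item whose extremeness and communality levels sweep a 10 x 10
#' grid. Level `k` of either attribute denotes the interval
#' `[.10 (k-1), .10 (k-1) + .09]`.
#'
#' @param n_categories number of response categories, 2 to 5.
#' @param focal_extremeness_level,focal_communality_level levels 1-10 of
#'   the fifth item.
#' @param n sample size per replicate (default 200).
#' @return object of class `sim_condition`.
#' @export
sim_condition <- function(n_categories, focal_extremeness_level,
                          focal_communality_level, n = 200) {
  stopifnot(n_categories %in% 2:5,
            focal_extremeness_level %in% 1:10,
            focal_communality_level %in% 1:10, n >= 10)
  structure(list(n_categories = as.integer(n_categories),
                 focal_extremeness_level = as.integer(focal_extremeness_level),
                 focal_communality_level = as.integer(focal_communality_level),
                 n = as.integer(n)),
            class = "sim_condition")
}

# level k -> interval [.10(k-1), .10(k-1)+.09]
level_interval <- function(k) c(0.10 * (k - 1), 0.10 * (k - 1) + 0.09)

#' Normal thresholds hitting a target extremeness
#'
#' Builds category thresholds for a standard-normal latent response so
#' that the expected item mean in proportion metric equals `target_P`
#' exactly: category probabilities follow `Binomial(C - 1, target_P)` and
#' the thresholds are the normal quantiles of their cumulative sums. For
#' binary items this reduces to a single threshold at
#' `qnorm(1 - target_P)`, i.e. the top-category probability is the
#' target itself.
#'
#' @param n_categories number of response categories (>= 2).
#' @param target_P target extremeness in proportion metric; values of
#'   exactly 0 or 1 are clamped to .005 / .995 with a message.
#' @return numeric vector of `n_categories - 1` strictly increasing
#'   thresholds.
#' @export
thresholds_for_target <- function(n_categories, target_P) {
  stopifnot(n_categories >= 2, target_P >= 0, target_P <= 1)
  if (target_P == 0 || target_P == 1) {
    target_P <- min(max(target_P, 0.005), 0.995)
    message(sprintf("target_P clamped to %.3f", target_P))
  }
  p <- stats::dbinom(0:(n_categories - 1), n_categories - 1, target_P)
  stats::qnorm(cumsum(p)[-n_categories])
}

#' Draw one replicate's population parameters
#'
#' Samples the population of a [sim_condition()]: each medium item's
#' extremeness target is uniform in its level interval (levels 4-7) and
#' its communality uniform in its band; the focal fifth item draws both
#' from the condition's focal intervals. Loadings are the square roots
#' of the communalities and thresholds come from
#' [thresholds_for_target()]. Uses the current RNG state.
#'
#' @param cond a [sim_condition()].
#' @return list with `lambda`, `h2`, `target_P` (length-5 vectors),
#'   `thresholds` (list of per-item cut points), `n_categories`.
#' @export
draw_population <- function(cond) {
  stopifnot(inherits(cond, "sim_condition"))
  comm_bands <- rbind(c(0.30, 0.34), c(0.35, 0.39),
                      c(0.40, 0.44), c(0.45, 0.49))
  ex_int <- rbind(t(vapply(4:7, level_interval, numeric(2))),
                  level_interval(cond$focal_extremeness_level))
  h2_int <- rbind(comm_bands, level_interval(cond$focal_communality_level))
  target_P <- stats::runif(5, ex_int[, 1L], ex_int[, 2L])
  h2 <- stats::runif(5, h2_int[, 1L], h2_int[, 2L])
  thresholds <- lapply(target_P, function(p)
    thresholds_for_target(cond$n_categories, p))
  list(lambda = sqrt(h2), h2 = h2, target_P = target_P,
       thresholds = thresholds, n_categories = cond$n_categories)
}

#' Generate one sample of discretized one-factor responses
#'
#' Draws `n` latent response vectors `x_j = lambda_j z + e_j` with a
#' standard-normal common factor and unique variances `1 - lambda_j^2`,
#' then discretizes each item at its thresholds into integer codes
#' `0 .. C-1`. The declared category range of the result is the full
#' `0 .. C-1` scale even when extreme categories go unobserved.
#'
#' @param pop population spec from [draw_population()].
#' @param n number of respondents.
#' @return a [response_matrix()].
#' @export
generate_replicate <- function(pop, n = 200) {
  J <- length(pop$lambda)
  z <- stats::rnorm(n)
  lat <- z %*% t(pop$lambda) +
    matrix(stats::rnorm(n * J), n, J) %*% diag(sqrt(1 - pop$lambda^2), J)
  codes <- vapply(seq_len(J), function(j)
    findInterval(lat[, j], pop$thresholds[[j]]), integer(n))
  response_matrix(codes,
                  categories = c(0L, pop$n_categories - 1L))
}

#' Classify one replicate through the screening cascade
#'
#' Applies the strict six-step cascade to a generated sample, stopping at
#' the first failure: (1) indefinite or degenerate correlation matrix
#' (`"npd"`); (2) Heywood case on the focal item's squared multiple
#' correlation (`"heywood"`, structurally impossible on a
#' positive-definite matrix); (3) focal MSA below the threshold
#' (`"noisy"`); (4) focal ULS loading bias above `bias_threshold`
#' (`"biased"`); (5) inner-bootstrap loading variance above
#' `sev_threshold` (`"unstable"`); otherwise `"ok"`. The graded model
#' analyses the polychoric matrix, the linear model the Pearson matrix;
#' the focal item is the fifth throughout.
#'
#' The reported focal consistency `h` is the sample value except for
#' `"npd"` replicates, where the sample value does not exist and the
#' population value is reported instead.
#'
#' @param rmat a [response_matrix()] from [generate_replicate()].
#' @param pop the matching population spec.
#' @param model `"graded"` (polychoric) or `"linear"` (Pearson).
#' @param msa_threshold,bias_threshold,sev_threshold cascade cutoffs
#'   (defaults .50, .80, .85).
#' @param inner_B inner bootstrap size of the instability step.
#' @param max_stage `"full"` runs all six steps; `"msa"` stops the
#'   cascade after the noisy-item step (replicates surviving to that
#'   point are classified `"ok"`), which leaves the npd / heywood /
#'   noisy counts identical to a full run at a fraction of the cost.
#' @param focal focal item index (default 5).
#' @return list with `classification`, `focal_P`, `focal_h`,
#'   `uls_heywood` (the extraction-level Heywood flag, reported
#'   separately from the cascade's SMC-based check), `bias_focal`,
#'   `bias_mean`, `sev`.
#' @export
classify_replicate <- function(rmat, pop, model = c("graded", "linear"),
                               msa_threshold = 0.50, bias_threshold = 0.80,
                               sev_threshold = 0.85, inner_B = 50,
                               max_stage = c("full", "msa"), focal = 5L) {
  model <- match.arg(model)
  max_stage <- match.arg(max_stage)
  out <- list(classification = NA_character_,
              focal_P = extremeness(rmat$data[, focal],
                                    rmat$categories[focal, 1L],
                                    rmat$categories[focal, 2L]),
              focal_h = NA_real_, uls_heywood = NA, bias_focal = NA_real_,
              bias_mean = NA_real_, sev = NA_real_)

  # step 1: correlation matrix must exist and be positive definite
  C <- tryCatch(
    if (model == "linear") pearson_matrix(rmat) else polychoric_matrix(rmat),
    error = function(e) NULL)
  if (is.null(C) || !isTRUE(attr(C, "is_pd"))) {
    out$classification <- "npd"
    out$focal_h <- sqrt(pop$h2[focal])   # sample value not computable
    return(out)
  }

  # step 2: Heywood check on the SMC communality
  h2 <- unname(smc_all(C))
  out$focal_h <- sqrt(max(h2[focal], 0))
  if (h2[focal] >= 1) { out$classification <- "heywood"; return(out) }

  # step 3: noisy-item check
  if (unname(msa_item(C, focal)) < msa_threshold) {
    out$classification <- "noisy"
    return(out)
  }
  if (max_stage == "msa") { out$classification <- "ok"; return(out) }

  # step 4: loading bias
  fit <- uls_one_factor(C)
  out$uls_heywood <- fit$heywood
  out$bias_focal <- loading_bias(fit, pop$lambda, focal)
  out$bias_mean <- loading_bias(fit, pop$lambda)
  if (out$bias_focal > bias_threshold) {
    out$classification <- "biased"
    return(out)
  }

  # step 5: instability
  out$sev <- as.numeric(instability_metric(rmat, focal, model,
                                           inner_B = inner_B))
  if (out$sev > sev_threshold) { out$classification <- "unstable"; return(out) }

  out$classification <- "ok"
  out
}

# deterministic per-replicate substream seed; injective within one run
# for up to 1024 cells and 500 replicates per cell, with a stride of 4
# leaving room for per-model offsets.
substream_seed <- function(seed, cell, rep, offset = 0L) {
  base <- as.double(seed %% 1021L)
  s <- base * 2^21 + (cell - 1) * 2^11 + 4 * (rep - 1) + offset
  as.integer(s %% 2147483647)
}

#' Run the region-calibration Monte-Carlo study
#'
#' Loops the full design -- response categories x 10 focal extremeness
#' levels x 10 focal communality levels x replicates -- generating one
#' sample per replicate and classifying it under the requested models
#' (the same sample is analysed by both, as in the calibration design).
#' Each replicate runs on its own deterministic RNG substream derived
#' from `(seed, cell, replicate)`, so results are identical for any
#' `n_jobs`.
#'
#' @param reps replicates per cell (at most 500).
#' @param categories response-category counts to simulate (subset of 2:5).
#' @param models character vector among `"graded"`, `"linear"`.
#' @param n sample size per replicate (default 200).
#' @param seed integer study seed.
#' @param n_jobs parallel workers over design cells (forked; default 1).
#' @param max_stage,inner_B,msa_threshold,bias_threshold,sev_threshold
#'   passed to [classify_replicate()].
#' @param region [region_config()] used for the region-occupancy summary.
#' @return object of class `gpool_study`: list with `outcomes` (one row
#'   per replicate x model: design cell, classification, focal
#'   coordinates), `class_table` (percentage of each problem class per
#'   model x categories), `region_occupancy` (percentage of
#'   non-problematic replicates per 3 x 3 region cell), and the call
#'   settings.
#' @export
run_study <- function(reps = 200, categories = 2:5,
                      models = c("graded", "linear"), n = 200, seed = 1,
                      n_jobs = 1, max_stage = c("full", "msa"),
                      inner_B = 50, msa_threshold = 0.50,
                      bias_threshold = 0.80, sev_threshold = 0.85,
                      region = region_config()) {
  max_stage <- match.arg(max_stage)
  stopifnot(all(categories %in% 2:5), reps >= 1, reps <= 500,
            all(models %in% c("graded", "linear")))
  cells <- expand.grid(comm = 1:10, ex = 1:10, cat = categories,
                       KEEP.OUT.ATTRS = FALSE)
  cell_ids <- seq_len(nrow(cells))

  one_cell <- function(ci) {
    cond <- sim_condition(cells$cat[ci], cells$ex[ci], cells$comm[ci], n)
    res <- vector("list", reps * length(models))
    k <- 0L
    for (r in seq_len(reps)) {
      set.seed(substream_seed(seed, ci, r, 0L))
      pop <- draw_population(cond)
      rmat <- generate_replicate(pop, n)
      for (mi in seq_along(models)) {
        set.seed(substream_seed(seed, ci, r, mi))
        cl <- classify_replicate(rmat, pop, models[mi],
                                 msa_threshold = msa_threshold,
                                 bias_threshold = bias_threshold,
                                 sev_threshold = sev_threshold,
                                 inner_B = inner_B, max_stage = max_stage)
        k <- k + 1L
        res[[k]] <- data.frame(
          categories = cond$n_categories, ex_level = cond$focal_extremeness_level,
          comm_level = cond$focal_communality_level, rep = r,
          model = models[mi], classification = cl$classification,
          focal_P = cl$focal_P, focal_h = cl$focal_h,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  }

  chunks <- if (n_jobs > 1) {
    parallel::mclapply(cell_ids, one_cell, mc.cores = n_jobs,
                       mc.preschedule = TRUE)
  } else {
    lapply(cell_ids, one_cell)
  }
  outcomes <- do.call(rbind, chunks)

  classes <- c("npd", "heywood", "noisy", "biased", "unstable", "ok")
  class_table <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(categories, function(ct) {
      sub <- outcomes[outcomes$model == m & outcomes$categories == ct, ]
      pct <- 100 * vapply(classes, function(cl)
        mean(sub$classification == cl), numeric(1))
      data.frame(model = m, categories = ct, class = classes,
                 pct = unname(pct), n = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))
  rownames(class_table) <- NULL

  # 3 x 3 region partition of the focal coordinates; share of "ok" in each
  px <- cut(outcomes$focal_P, c(-Inf, region$ex_lo, region$ex_hi, Inf),
            labels = c("P_low", "P_mid", "P_high"))
  hy <- cut(outcomes$focal_h, c(-Inf, region$h_lo, region$h_hi, Inf),
            labels = c("h_low", "h_mid", "h_high"))
  occ <- aggregate(list(pct_ok = outcomes$classification == "ok"),
                   by = list(model = outcomes$model, h_band = hy, P_band = px),
                   FUN = function(z) 100 * mean(z))
  nocc <- aggregate(list(n = rep(1L, nrow(outcomes))),
                    by = list(model = outcomes$model, h_band = hy, P_band = px),
                    FUN = sum)
  occ <- merge(occ, nocc)

  structure(list(outcomes = outcomes, class_table = class_table,
                 region_occupancy = occ, reps = reps, n = n, seed = seed,
                 models = models, categories = categories,
                 max_stage = max_stage),
            class = "gpool_study")
}

#' Wide problem-class table of a simulation study
#'
#' Rearranges the class percentages into the familiar layout: one row
#' per problem class, one column per model x category count.
#'
#' @param study a `gpool_study` from [run_study()].
#' @return data frame with a `class` column and `<model>_<categories>`
#'   percentage columns.
#' @export
study_table <- function(study) {
  stopifnot(inherits(study, "gpool_study"))
  ct <- study$class_table
  out <- data.frame(class = unique(ct$class), stringsAsFactors = FALSE)
  for (m in study$models) {
    for (cc in study$categories) {
      v <- ct$pct[ct$model == m & ct$categories == cc]
      out[[paste0(m, "_", cc)]] <- round(v, 2)
    }
  }
  out
}

#' @export
print.gpool_study <- function(x, ...) {
  cat(sprintf(
    "Region-calibration study: %d reps/cell, N = %d, categories %s, %s cascade\n",
    x$reps, x$n, paste(x$categories, collapse = ","),
    if (x$max_stage == "full") "full" else "truncated (through MSA)"))
  print(study_table(x), row.names = FALSE)
  invisible(x)
}

#' Extract a pooled percentage from a study
#'
#' Percentage of replicates with a given classification for one model
#' and category count, pooled over the focal 10 x 10 grid.
#'
#' @param study a `gpool_study`.
#' @param model,categories cell selector.
#' @param class classification to count.
#' @return percentage (0-100).
#' @export
study_pct <- function(study, model, categories, class) {
  ct <- study$class_table
  ct$pct[ct$model == model & ct$categories == categories & ct$class == class]
}
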