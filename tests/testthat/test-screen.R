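# build a minimal coordinate table / CI pair by hand
fake_coords <- function(P, h, msa = rep(0.8, length(P))) {
  data.frame(label = paste0("item", seq_along(P)), P = P, h2 = h^2, h = h,
             msa = msa, pie = pie_index(h^2, P), r_pie = r_pie(h^2, P),
             stringsAsFactors = FALSE)
}
fake_boot <- function(ci_P, ci_h) list(ci_P = ci_P, ci_h = ci_h,
                                       level = 0.95, B = 500, n_dropped = 0)

test_that("flagging requires both CI limits beyond the same boundary", {
  co <- fake_coords(P = c(0.95, 0.9, 0.5), h = c(0.5, 0.5, 0.08),
                    msa = c(0.8, 0.8, 0.61))
  boot <- fake_boot(
    ci_P = rbind(c(0.92, 0.97), c(0.88, 0.93), c(0.45, 0.55)),
    ci_h = rbind(c(0.4, 0.6), c(0.4, 0.6), c(0.05, 0.12)))
  fl <- flag_items(co, boot)
  expect_equal(fl$flag_extremeness, c("high", "none", "none"))
  expect_equal(fl$flag_consistency, c("none", "none", "low"))
  expect_equal(fl$flag_msa, c(FALSE, FALSE, FALSE))
  expect_equal(fl$decision, c("flag", "keep", "flag"))
  expect_equal(fl$point_in_region, c(FALSE, TRUE, FALSE))
  # decision holds iff some axis or the MSA flag fired
  any_flag <- fl$flag_extremeness != "none" | fl$flag_consistency != "none" |
    fl$flag_msa
  expect_equal(fl$decision == "flag", any_flag)
})

test_that("MSA flag uses the point estimate against the threshold", {
  co <- fake_coords(P = c(0.5, 0.5), h = c(0.5, 0.5), msa = c(0.49, 0.51))
  fl <- flag_items(co, NULL)
  expect_equal(fl$flag_msa, c(TRUE, FALSE))
  expect_equal(fl$decision, c("flag", "keep"))
})

test_that("widening a CI symmetrically never creates a new flag", {
  set.seed(15)
  for (i in 1:50) {
    P <- runif(1); h <- runif(1)
    wP <- runif(1, 0, 0.2); wh <- runif(1, 0, 0.2)
    co <- fake_coords(P, h)
    narrow <- flag_items(co, fake_boot(cbind(P - wP, P + wP),
                                       cbind(h - wh, h + wh)))
    wide <- flag_items(co, fake_boot(cbind(P - wP - 0.1, P + wP + 0.1),
                                     cbind(h - wh - 0.1, h + wh + 0.1)))
    if (narrow$flag_extremeness == "none")
      expect_equal(wide$flag_extremeness, "none")
    if (narrow$flag_consistency == "none")
      expect_equal(wide$flag_consistency, "none")
  }
})

test_that("degenerate resampling collapses flags to point classification", {
  co <- fake_coords(P = c(0.95, 0.5, 0.05), h = c(0.5, 0.1, 0.5))
  fl <- flag_items(co, NULL)
  expect_equal(fl$flag_extremeness, c("high", "none", "low"))
  expect_equal(fl$flag_consistency, c("none", "low", "none"))
  expect_equal(!fl$point_in_region, fl$decision == "flag")
})

test_that("selection drops flagged items and ranks survivors by R-PIE", {
  co <- fake_coords(P = c(0.5, 0.6, 0.45), h = c(0.71, 0.5, 0.63))
  fl <- flag_items(co, NULL)
  expect_equal(fl$decision, rep("keep", 3))
  expect_equal(select_items(fl), c("item1", "item3", "item2"))
  expect_equal(fl$r_pie_rank, c(1L, 3L, 2L))
  expect_equal(select_items(fl, keep_k = 2), c("item1", "item3"))

  # MSA-only flag still excludes before ranking
  co2 <- fake_coords(P = c(0.5, 0.5, 0.5), h = c(0.7, 0.6, 0.5),
                     msa = c(0.45, 0.8, 0.8))
  kept <- select_items(flag_items(co2, NULL))
  expect_false("item1" %in% kept)
  expect_equal(kept, c("item2", "item3"))

  # kept R-PIE dominates any dropped unflagged item (here: none dropped)
  co3 <- fake_coords(P = rep(0.5, 4), h = c(0.6, 0.3, 0.5, 0.4))
  kept3 <- select_items(flag_items(co3, NULL), keep_k = 2)
  r <- co3$r_pie[match(kept3, co3$label)]
  expect_true(min(r) >= max(co3$r_pie[!co3$label %in% kept3]))

  all_bad <- fake_coords(P = c(0.99, 0.01), h = c(0.5, 0.5))
  expect_error(select_items(flag_items(all_bad, NULL)), "empty pool")
})

test_that("bootstrap intervals are seed-reproducible and sane", {
  set.seed(16)
  pop <- fixture_pop()
  rm <- generate_replicate(pop, 300)
  b1 <- bootstrap_coordinates(rm, "linear", B = 120, seed = 5)
  b2 <- bootstrap_coordinates(rm, "linear", B = 120, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_P[, 1] <= b1$ci_P[, 2]))
  expect_true(all(b1$ci_h[, 1] <= b1$ci_h[, 2]))
  expect_error(bootstrap_coordinates(rm, "linear", B = 50), "B >= 100")
})

test_that("interval widths shrink with sample size on average", {
  set.seed(17)
  pop <- list(lambda = sqrt(c(0.4, 0.45, 0.42, 0.38, 0.35)),
              h2 = c(0.4, 0.45, 0.42, 0.38, 0.35),
              target_P = c(0.35, 0.45, 0.5, 0.55, 0.65),
              thresholds = lapply(c(0.35, 0.45, 0.5, 0.55, 0.65), function(p)
                thresholds_for_target(5, p)),
              n_categories = 5L)
  small <- generate_replicate(pop, 200)
  big <- generate_replicate(pop, 2000)
  bs <- bootstrap_coordinates(small, "linear", B = 150, seed = 1)
  bb <- bootstrap_coordinates(big, "linear", B = 150, seed = 1)
  expect_lt(mean(bb$ci_P[, 2] - bb$ci_P[, 1]),
            mean(bs$ci_P[, 2] - bs$ci_P[, 1]))
  expect_lt(mean(bb$ci_h[, 2] - bb$ci_h[, 1]),
            mean(bs$ci_h[, 2] - bs$ci_h[, 1]))
})

test_that("unusable resamples abort the bootstrap with an error", {
  # two items with a single positive response each: the majority of
  # resamples contain at least one constant column
  set.seed(18)
  x <- cbind(rbinom(40, 1, 0.5), c(rep(0L, 39), 1L), c(1L, rep(0L, 39)))
  rm <- response_matrix(x, c(0, 1))
  expect_error(suppressMessages(
    bootstrap_coordinates(rm, "linear", B = 100, seed = 2)),
    "bootstrap unstable")
})

test_that("full screening pipeline is reproducible end to end", {
  set.seed(19)
  pop <- fixture_pop()
  rm <- generate_replicate(pop, 400)
  s1 <- suppressMessages(gpool_screen(rm, "linear", B = 120, seed = 3))
  s2 <- suppressMessages(gpool_screen(rm, "linear", B = 120, seed = 3))
  expect_identical(s1$report, s2$report)
  expect_s3_class(s1$report, "gpool_flags")
  expect_equal(nrow(s1$report), 10)
  expect_true(all(s1$kept %in% s1$report$label[s1$report$decision == "keep"]))
})

test_that("split-sample decisions replicate on stable pools", {
  set.seed(20)
  pop <- list(lambda = sqrt(c(0.4, 0.45, 0.42, 0.38, 0.35)),
              h2 = c(0.4, 0.45, 0.42, 0.38, 0.35),
              target_P = c(0.35, 0.45, 0.5, 0.55, 0.65),
              thresholds = lapply(c(0.35, 0.45, 0.5, 0.55, 0.65), function(p)
                thresholds_for_target(5, p)),
              n_categories = 5L)
  rm <- generate_replicate(pop, 2000)
  sp <- split_sample_check(rm, seed = 4, model = "linear", B = 120)
  expect_equal(sp$agreement, 1.0)
  sp2 <- split_sample_check(rm, seed = 4, model = "linear", B = 120)
  expect_identical(sp$report_A, sp2$report_A)
  expect_gte(sp$agreement, 0)
  expect_lte(sp$agreement, 1)
})
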