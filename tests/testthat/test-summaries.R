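# Brute-force enumeration oracles on printed toy fixtures.

toy_surface <- function() {
  # 3 pixels x 1 year, 5 draws, printed values
  grid <- grid_definition(0, 1, cellsize = 1, n_cols = 3, n_rows = 1,
                          years = 2005)
  draws <- matrix(c(0.95, 0.85, 0.50,
                    0.92, 0.91, 0.40,
                    0.88, 0.93, 0.45,
                    0.96, 0.89, 0.55,
                    0.91, 0.87, 0.60), 5, 3, byrow = TRUE)
  list(mean = matrix(colMeans(draws), 3, 1), draws = draws, grid = grid,
       years = 2005)
}

test_that("threshold-area proportions match exhaustive enumeration", {
  sp <- toy_surface()
  tr <- area_below_threshold(sp, threshold = 0.9)
  # brute force: count pixels < 0.9 in the mean surface and in every draw
  expect_equal(tr$proportion, mean(colMeans(sp$draws) < 0.9))
  per_draw <- apply(sp$draws, 1, function(x) mean(x < 0.9))  # 5 values
  expect_equal(tr$lower, unname(quantile(per_draw, 0.025)))
  expect_equal(tr$upper, unname(quantile(per_draw, 0.975)))
  expect_true(tr$lower <= tr$proportion && tr$proportion <= tr$upper)
  # monotone in the threshold
  expect_gte(area_below_threshold(sp, 0.9)$proportion,
             area_below_threshold(sp, 0.5)$proportion)
  # all pixels at mortality 1.0: proportion 0 with CI [0, 0]
  ones <- list(mean = matrix(1, 3, 1),
               draws = matrix(1, 5, 3), grid = sp$grid, years = 2005)
  tr1 <- area_below_threshold(ones, 0.9)
  expect_equal(unlist(tr1[, c("proportion", "lower", "upper")]),
               c(proportion = 0, lower = 0, upper = 0))
  expect_error(area_below_threshold(sp, mask = rep(FALSE, 3)), "empty mask")
})

test_that("country trends partition and match brute force", {
  sp <- toy_surface()
  whole <- area_below_threshold(sp, 0.9)
  # single country covering the region reproduces the regional trend
  one <- country_trends(sp, list(all = rep(TRUE, 3)), 0.9)
  expect_equal(one$proportion, whole$proportion)
  # two disjoint countries partitioning the region: pixel-weighted mean of
  # country proportions equals the regional proportion
  masks <- list(west = c(TRUE, TRUE, FALSE), east = c(FALSE, FALSE, TRUE))
  two <- country_trends(sp, masks, 0.9)
  expect_equal(two$proportion[1], mean(sp$mean[1:2, 1] < 0.9))  # brute force
  expect_equal(two$proportion[2], mean(sp$mean[3, 1] < 0.9))
  expect_equal((2 * two$proportion[1] + 1 * two$proportion[2]) / 3,
               whole$proportion)
  expect_warning(country_trends(sp, list(none = rep(FALSE, 3))),
                 "zero unmasked")
})

test_that("interannual change matches a brute-force pairwise scan", {
  # constant in time: both maps zero
  const <- matrix(0.7, 4, 5)
  chg <- interannual_change(const)
  expect_equal(chg$max_increase, rep(0, 4))
  expect_equal(chg$max_decrease, rep(0, 4))
  # monotone series 0.9 -> 0.3 in equal steps of 0.05
  series <- seq(0.9, 0.3, by = -0.05)
  chg2 <- interannual_change(matrix(series, 1))
  expect_equal(chg2$max_decrease, 0.05)
  expect_equal(chg2$max_increase, -0.05)  # no increase ever occurs
  # printed single-pixel fixture vs brute-force scan over all pairs
  px <- c(0.95, 0.80, 0.85, 0.60, 0.65, 0.30)
  chg3 <- interannual_change(matrix(px, 1))
  diffs <- diff(px)
  expect_equal(chg3$max_increase, max(diffs))
  expect_equal(chg3$max_decrease, max(-diffs))
  expect_error(interannual_change(matrix(1, 3, 1)), "2 years")
})

test_that("weighted importance matches hand-computed sums and rankings", {
  imp <- matrix(c(0.5, 0.3, 0.1, 0.1,
                  0.1, 0.4, 0.4, 0.1,
                  0.25, 0.25, 0.25, 0.25), 4, 3,
                dimnames = list(c("f1", "f2", "f3", "f4"),
                                c("xgb", "rf", "bgam")))
  w <- c(xgb = 0.5, rf = 0.3, bgam = 0.2)
  out <- weighted_importance(imp, w)
  # hand-computed weighted sums
  hand <- c(f1 = 0.5 * 0.5 + 0.1 * 0.3 + 0.25 * 0.2,
            f2 = 0.3 * 0.5 + 0.4 * 0.3 + 0.25 * 0.2,
            f3 = 0.1 * 0.5 + 0.4 * 0.3 + 0.25 * 0.2,
            f4 = 0.1 * 0.5 + 0.1 * 0.3 + 0.25 * 0.2)
  expect_equal(setNames(out$total, out$feature), sort(hand, decreasing = TRUE))
  # degenerate weights (1, 0, 0): ranking equals model 1's own ranking
  out1 <- weighted_importance(imp, c(xgb = 1, rf = 0, bgam = 0))
  expect_equal(out1$feature, names(sort(imp[, "xgb"], decreasing = TRUE)))
  # equal weights and identical importance vectors: all totals equal
  same <- matrix(0.25, 4, 3, dimnames = dimnames(imp))
  oute <- weighted_importance(same, c(xgb = 1, rf = 1, bgam = 1) / 3)
  expect_equal(var(oute$total), 0)
  # mismatched feature sets are rejected, naming the difference
  expect_error(weighted_importance(list(xgb = c(f1 = 1),
                                        rf = c(f2 = 1)), w[1:2]),
               "mismatched feature sets")
  expect_error(weighted_importance(imp, c(xgb = 0.5, rf = 0.5)),
               "mismatched model sets")
  # top_n truncation
  expect_equal(nrow(weighted_importance(imp, w, top_n = 2)), 2)
})
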