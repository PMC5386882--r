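test_that("a degenerate cohort yields one bin with all quantiles at the value", {
  coh <- degenerate_cohort(280, 500)
  qt <- conditional_quantile_table(coh, seed = 1)
  expect_equal(nrow(qt), 1)
  expect_equal(qt$bin_left, 280)
  expect_equal(qt$n, 500L)
  expect_equal(as.numeric(qt[1, c("q05", "q25", "q50", "q75", "q95")]),
               rep(280, 5))
})

test_that("bin retention is strict: exactly 100 dropped, 101 kept", {
  coh <- degenerate_cohort(c(240, 260, 280), c(100, 101, 500))
  qt <- conditional_quantile_table(coh, seed = 2)
  expect_false(238 %in% qt$bin_left)   # floor(240/7)*7
  expect_true(259 %in% qt$bin_left)
  expect_true(280 %in% qt$bin_left)
})

test_that("bin edges are multiples of the bin width with 280 as a left edge", {
  coh <- simulate_pair_cohort(spec_m0(), 20000, seed = 3)
  qt <- conditional_quantile_table(coh, seed = 4)
  expect_true(all(qt$bin_left %% 7 == 0))
  expect_true(280 %in% qt$bin_left)
  expect_true(all(diff(qt$bin_left) >= 7))
})

test_that("per-bin percentiles equal an independent sort-and-interpolate oracle", {
  set.seed(5)
  vals <- round(runif(300, 200, 299))
  coh <- tibble::tibble(ga1 = vals, ga2 = vals)  # identical pair values
  qt <- conditional_quantile_table(coh, min_count = 10, seed = 6)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (r in seq_len(nrow(qt))) {
    members <- sort(vals[floor(vals / 7) * 7 == qt$bin_left[r]])
    # type-7 linear interpolation between order statistics, from scratch
    h <- (length(members) - 1) * probs + 1
    oracle <- members[floor(h)] +
      (h - floor(h)) * (members[pmin(ceiling(h), length(members))] -
                          members[floor(h)])
    expect_equal(as.numeric(qt[r, c("q05", "q25", "q50", "q75", "q95")]),
                 oracle, tolerance = 1e-12)
  }
  expect_true(all(qt$q05 <= qt$q25 & qt$q25 <= qt$q50 &
                    qt$q50 <= qt$q75 & qt$q75 <= qt$q95))
})

test_that("cost is zero on identical tables and matches the hand-worked bin", {
  fxq <- conditional_quantile_table(degenerate_cohort(c(270, 280), c(400, 400)),
                                    seed = 7)
  expect_equal(weighted_ss_cost(fxq, fxq), 0)
  sim <- fxq
  sim$q50[1] <- sim$q50[1] + 2   # one quantile off by 2 days, N = 400
  expect_equal(weighted_ss_cost(sim, fxq), sqrt(400) * 4)  # = 80
})

test_that("cost is additive over bins and quadratic in deviations", {
  ref <- conditional_quantile_table(
    degenerate_cohort(c(266, 273, 280), c(300, 400, 500)), seed = 8)
  sim <- ref
  sim$q25 <- sim$q25 + c(1, 2, 0)
  total <- weighted_ss_cost(sim, ref)
  parts <- vapply(1:3, function(i) weighted_ss_cost(sim[i, ], ref[i, ]),
                  numeric(1))
  expect_equal(total, sum(parts))
  sim2 <- ref
  sim2$q25 <- sim2$q25 + 2 * c(1, 2, 0)
  expect_equal(weighted_ss_cost(sim2, ref), 4 * total)
})

test_that("a reference bin missing from the simulation is penalized and logged", {
  ref <- conditional_quantile_table(
    degenerate_cohort(c(273, 280), c(400, 900)), seed = 9)
  sim <- ref[2, ]
  expect_warning(cost <- weighted_ss_cost(sim, ref), class = "gw_missing_bins")
  expect_equal(cost, sqrt(400) * 5 * 25^2)
})

test_that("evaluate_model reports replicate spread and discriminates models", {
  fx <- make_reference_population(spec = spec_m3(), n_pairs = 12000, seed = 10)
  ev1 <- evaluate_model(spec_m0(), fx$table, replicates = 1, seed = 11)
  expect_true(is.na(ev1$sd_cost))
  ev0 <- evaluate_model(spec_m0(), fx$table, replicates = 3, seed = 12)
  evt <- evaluate_model(spec_m3(), fx$table, replicates = 3, seed = 13)
  expect_gt(ev0$mean_cost, evt$mean_cost)   # truth beats the no-genetics model
  expect_equal(nrow(tidy(ev0)), 3)
  expect_equal(glance(evt)$spec, "M3")
})

test_that("cost is stable across root seeds at matched sampling", {
  fx <- make_reference_population(spec = spec_m0(), n_pairs = 10000, seed = 14)
  a <- evaluate_model(spec_m0(), fx$table, replicates = 4, seed = 15)
  b <- evaluate_model(spec_m0(), fx$table, replicates = 4, seed = 16)
  pooled <- sqrt(a$sd_cost^2 + b$sd_cost^2)
  expect_lt(abs(a$mean_cost - b$mean_cost), 3 * pooled + 1e-9)
})

test_that("slope contrast: zero for parallel series, error below 3 bins", {
  qt <- conditional_quantile_table(
    degenerate_cohort(c(266, 273, 280, 287), c(200, 300, 400, 300)), seed = 17)
  shift <- qt
  for (cn in c("q05", "q25", "q50", "q75", "q95")) {
    shift[[cn]] <- 260 + shift$bin_left / 7   # all series share one slope
  }
  expect_equal(quantile_slope_contrast(shift), 0, tolerance = 1e-12)
  expect_error(quantile_slope_contrast(qt[1:2, ]), "3 retained bins")
})

test_that("quantile tables round-trip through TSV", {
  qt <- conditional_quantile_table(
    degenerate_cohort(c(266, 273, 280), c(200, 300, 400)), seed = 18)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quantile_table(qt, path)
  back <- read_quantile_table(path)
  expect_equal(as.data.frame(back), as.data.frame(qt), tolerance = 1e-12)
  expect_equal(attr(back, "bin_width"), 7)
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(x = 1), bad)
  expect_error(read_quantile_table(bad), "malformed")
})
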