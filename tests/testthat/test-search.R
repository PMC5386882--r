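# Small shared reference for search tests: cheap but non-trivial.
ref_small <- local({
  fx <- make_reference_population(spec = spec_m1(), n_pairs = 6000, seed = 50)
  fx$table
})

test_that("candidate draws follow the stated prior distributions", {
  set.seed(51)
  draws <- purrr::map(1:20000, ~ draw_candidate(spec_m1()))
  g <- vapply(draws, function(d) d$classes$gamma[1], numeric(1))
  p <- vapply(draws, function(d) d$classes$maf[1], numeric(1))
  n <- vapply(draws, function(d) d$classes$count[1], numeric(1))
  expect_true(all(g >= -5 & g <= 5))
  expect_true(all(p > 0 & p < 0.5))
  expect_true(all(n >= 1))
  # n ~ 1 + Poisson(1)
  k <- 1:6
  expected <- dpois(k - 1, 1) * length(n)
  observed <- tabulate(pmin(n, 6), 6)
  expected[6] <- (1 - ppois(4, 1)) * length(n)
  chi <- suppressWarnings(chisq.test(observed, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.001)
  # Unif(-5, 5) interval mass: P(gamma in (2.4, 2.8)) = 0.04
  expect_lt(abs(mean(g > 2.4 & g < 2.8) - 0.04), 0.006)
  expect_error(draw_candidate(spec_m0()), "no free parameters")
})

test_that("fixed parameters are never touched by the search", {
  set.seed(52)
  for (i in 1:50) {
    cand <- draw_candidate(spec_m3())
    vy <- cand$classes[cand$classes$kind == "varying", ]
    expect_equal(vy$gamma, c(100, 80, 60, -100))
    expect_equal(vy$maf, c(0.005, 0.01, 0.015, 0.3))
    expect_equal(vy$mu, c(230, 237, 244, 258))
    cand2 <- draw_candidate(spec_m2())
    expect_equal(cand2$classes$count[2], 1L)
  }
})

test_that("random search ranks candidates and is seed-deterministic", {
  s1 <- random_search(spec_m1(), ref_small, budget = 30, n_pairs = 3000,
                      seed = 53)
  expect_equal(nrow(s1$candidates), 30)
  expect_true(!is.unsorted(s1$candidates$mean_cost))
  s2 <- random_search(spec_m1(), ref_small, budget = 30, n_pairs = 3000,
                      seed = 53)
  expect_equal(tidy(s1), tidy(s2))
  single <- random_search(spec_m1(), ref_small, budget = 1, n_pairs = 3000,
                          seed = 54)
  expect_equal(nrow(single$candidates), 1)
})

test_that("metamodel interval tracks the low-cost region of a constructed landscape", {
  set.seed(55)
  sgpn <- runif(2000, -3, 3)
  fake <- structure(list(candidates = tibble::tibble(
    sum_gpn = sgpn,
    mean_cost = (sgpn - 0.5)^2 + rnorm(2000, 0, 0.01),
    stage = "stage1"
  ), spec = spec_m1(), config = list()), class = "gw_search")
  iv <- metamodel_restrict(fake)
  expect_lt(iv[1], 0.5)
  expect_gt(iv[2], 0.5)
  expect_lt(diff(iv), 1)   # narrow relative to the (-3, 3) prior span
  # keep_fraction 1 spans the full range plus margins
  iv_all <- metamodel_restrict(fake, keep_fraction = 1)
  expect_lt(iv_all[1], min(sgpn))
  expect_gt(iv_all[2], max(sgpn))
  # all-equal costs: interval covers all summaries
  fake$candidates$mean_cost <- 1
  iv_eq <- metamodel_restrict(fake)
  expect_lte(iv_eq[1], min(sgpn))
  expect_gte(iv_eq[2], max(sgpn))
  # degenerate point interval widens to the documented minimum
  fake$candidates$sum_gpn <- 0.3
  iv_pt <- metamodel_restrict(fake)
  expect_gte(diff(iv_pt), 0.05)
  expect_error(metamodel_restrict(
    structure(list(candidates = fake$candidates[1:50, ]), class = "gw_search")),
    "100")
})

test_that("fit_model handles the no-free-parameter and no-metamodel cases", {
  ev <- fit_model(spec_m0(), ref_small, n_pairs = 3000, replicates_final = 2,
                  seed = 56)
  expect_equal(nrow(ev$candidates), 1)
  expect_equal(ev$candidates$stage, "evaluate")
  expect_null(ev$interval)

  m4 <- spec_m4()
  fit4 <- fit_model(m4, ref_small, budget1 = 15, budget2 = 15,
                    n_pairs = 3000, replicates_final = 2, top_k = 3,
                    seed = 57)
  expect_null(fit4$interval)             # no meta-modeling stage
  expect_true(all(fit4$candidates$stage == "stage1"))
  expect_equal(nrow(fit4$candidates), 30)
  # only the four effect sizes vary; pinned parameters intact
  cand_specs <- fit4$candidates$spec
  for (cs in cand_specs[1:5]) {
    expect_equal(cs$classes$maf, m4$classes$maf)
    expect_equal(cs$classes$count, m4$classes$count)
    expect_equal(cs$classes$gamma[1], m4$classes$gamma[1])
  }
  expect_equal(sum(!is.na(fit4$candidates$final_cost)), 3)
})

test_that("two-stage fit only adds candidates and confines stage 2 to the interval", {
  fit <- fit_model(spec_m1(), ref_small, budget1 = 120, budget2 = 40,
                   n_pairs = 3000, replicates_final = 2, top_k = 3,
                   seed = 58)
  cand <- fit$candidates
  expect_true(any(cand$stage == "stage2"))
  s2 <- cand[cand$stage == "stage2", ]
  expect_true(all(s2$sum_gpn >= fit$interval[1] &
                    s2$sum_gpn <= fit$interval[2]))
  best_overall <- min(dplyr::coalesce(cand$final_cost, cand$mean_cost))
  best_stage1 <- min(cand$mean_cost[cand$stage == "stage1"])
  expect_lte(min(cand$mean_cost), best_stage1)  # stage 2 can only improve the pool
  expect_true(is.finite(best_overall))
  # re-scoring the returned best reproduces its cost within 3 combined SDs
  best <- best_candidate(fit)
  re <- evaluate_model(best, ref_small, n_pairs = 3000, replicates = 4,
                       engine = "iterative", seed = 59)
  se_diff <- re$sd_cost * sqrt(1 / 4 + 1 / 2)  # means over 4 and 2 replicates
  expect_lt(abs(re$mean_cost - cand$final_cost[1]), 5 * se_diff)
})

test_that("search results serialize to ranked TSV + JSON", {
  fit <- random_search(spec_m1(), ref_small, budget = 5, n_pairs = 3000,
                       seed = 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_search_result(fit, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 5)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$n_candidates, 5)
})
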