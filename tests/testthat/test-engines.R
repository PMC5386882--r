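test_that("analytic draws follow the closed-form distribution (DKW band)", {
  b <- baseline_hazard(rate = 0.001, shape = 0.05)
  n <- 100000
  days <- sample_survival_analytic(b, multiplier = 1, n = n, seed = 31)
  expect_true(all(days > 150 & days <= 300))
  eps <- sqrt(log(2 / 0.01) / (2 * n))   # DKW 99% band
  for (d in seq(160, 290, by = 10)) {
    expect_lt(abs(mean(days <= d) - (1 - gompertz_surv(d - 150, 0.001, 0.05))),
              eps + 1e-9)
  }
  # inverse-transform median: S(t) = 0.5 at t ~ 71.43, ceiling day 222
  expect_equal(unname(quantile(days, 0.5, type = 1)), 222, tolerance = 1)
})

test_that("extreme multipliers give immediate events; domain errors raised", {
  b <- default_baseline()
  expect_true(all(sample_survival_analytic(b, 1e15, n = 200, seed = 1) == 151))
  huge <- baseline_hazard(rate = 10, shape = 0)
  g <- matrix(integer(0), nrow = 50, ncol = 0)
  expect_true(all(sample_survival_iterative(huge, g, spec_m0()$classes,
                                            seed = 2) == 151))
  expect_error(sample_survival_analytic(b, multiplier = 0), "> 0")
})

test_that("iterative engine output is integer days within the viable range", {
  sp <- spec_m3()
  coh <- simulate_pair_cohort(sp, 2000, engine = "iterative", seed = 33)
  expect_true(all(coh$ga1 > 150 & coh$ga1 <= 300))
  expect_true(all(coh$ga2 == round(coh$ga2)))
})

test_that("analytic and iterative engines agree for a constant-effect model", {
  sp <- spec_m1(gamma = 1.5, maf = 0.1, count = 2)
  n <- 20000
  ca <- simulate_pair_cohort(sp, n, engine = "analytic", seed = 34)
  ci <- simulate_pair_cohort(sp, n, engine = "iterative", seed = 35)
  a <- c(ca$ga1, ca$ga2)
  i <- c(ci$ga1, ci$ga2)
  expect_true(all(abs(quantile(a, 1:9 / 10) - quantile(i, 1:9 / 10)) <= 1))
  ks <- suppressWarnings(stats::ks.test(a, i))
  expect_gt(ks$p.value, 0.01)
})

test_that("day-300 cap mass matches closed-form survival at the horizon", {
  b <- default_baseline()
  mult <- 0.2   # inflate the cap mass to a testable size
  n <- 30000
  days <- sample_survival_analytic(b, mult, n = n, seed = 36)
  p_cap <- gompertz_surv(149, b$rate, b$shape, mult)
  se <- sqrt(p_cap * (1 - p_cap) / n)
  expect_lt(abs(mean(days == 300) - p_cap), 4 * se)
})

test_that("pair cohorts: no correlation without genetics, rising with effect size", {
  c0 <- simulate_pair_cohort(spec_m0(), 30000, seed = 37)
  expect_lt(abs(cor(c0$ga1, c0$ga2)), 0.02)
  cors <- vapply(c(0.5, 1, 2), function(g) {
    coh <- simulate_pair_cohort(spec_m1(gamma = g, maf = 0.05, count = 1),
                                20000, seed = 38)
    cor(coh$ga1, coh$ga2)
  }, numeric(1))
  expect_gt(cors[2], cors[1])
  expect_gt(cors[3], cors[2])
  expect_gt(cors[3], 0)
})

test_that("engine policy and determinism contracts hold", {
  expect_error(simulate_pair_cohort(spec_m3(), 10, engine = "analytic"),
               "constant-effect")
  a <- simulate_pair_cohort(spec_m1(), 500, seed = 40, keep_genotypes = TRUE)
  b <- simulate_pair_cohort(spec_m1(), 500, seed = 40, keep_genotypes = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  i1 <- simulate_individuals(spec_m3(), 300, seed = 41)
  i2 <- simulate_individuals(spec_m3(), 300, seed = 41)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
})

test_that("individual cohorts expose genotypes and effect direction", {
  m0 <- simulate_individuals(spec_m0(), 100, seed = 42)
  expect_equal(names(m0), "ga")
  sp <- spec_m1(gamma = 2, maf = 0.3, count = 1)
  ind <- simulate_individuals(sp, 50000, seed = 43)
  expect_true("L1.1" %in% names(ind))
  # risk allele shortens gestation
  expect_gt(mean(ind$ga[ind$L1.1 == 0]), mean(ind$ga[ind$L1.1 == 2]))
})

test_that("cohort TSV round trip preserves data and writes a manifest", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.tsv")
  coh <- simulate_pair_cohort(spec_m1(), 300, seed = 44, keep_genotypes = TRUE)
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(lapply(as.list(back), as.numeric),
               lapply(as.list(tibble::as_tibble(coh)), as.numeric),
               tolerance = 1e-12)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(man$spec$name, "M1")
  expect_equal(man$seed, 44)
  expect_equal(man$engine, "analytic")
})
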