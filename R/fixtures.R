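.gw_env <- new.env(parent = emptyenv())

#' Calibrate the Gompertz baseline to a target term distribution
#'
#' The rate and shape are solved numerically so that the continuous
#' baseline-only model has the given median gestational age and 10th
#' percentile: the shape is the root of the quantile-ratio equation
#' `(exp(a * t_med) - 1) / (exp(a * t_10) - 1) = log(0.5) / log(0.9)`
#' (on the shifted scale `t = ga - origin_day`), and the rate follows
#' from the median. Defaults (280 d / 266 d) describe a typical term
#' distribution.
#'
#' @param median_ga Target median gestational age (days).
#' @param q10_ga Target 10th percentile (days).
#' @param origin_day,cap_day At-risk origin and cap.
#' @return A [baseline_hazard()].
#' @export
calibrate_baseline <- function(median_ga = 280, q10_ga = 266,
                               origin_day = 150, cap_day = 300) {
  stopifnot(origin_day < q10_ga, q10_ga < median_ga, median_ga <= cap_day)
  t_med <- median_ga - origin_day
  t_10 <- q10_ga - origin_day
  ratio <- log(0.5) / log(0.9)
  f <- function(a) (exp(a * t_med) - 1) / (exp(a * t_10) - 1) - ratio
  a <- stats::uniroot(f, c(1e-8, 2), tol = 1e-12)$root
  l <- -log(0.5) * a / (exp(a * t_med) - 1)
  baseline_hazard(rate = l, shape = a, origin_day = origin_day,
                  cap_day = cap_day)
}

#' Default calibrated baseline hazard
#'
#' [calibrate_baseline()] at its defaults (median 280 d, 10th percentile
#' 266 d), cached for the session.
#' @return A [baseline_hazard()].
#' @export
default_baseline <- function() {
  if (is.null(.gw_env$baseline)) .gw_env$baseline <- calibrate_baseline()
  .gw_env$baseline
}

#' Default free constant-effect locus class
#'
#' The constant class attached to the reference-population spec: effect
#' size 2.6, frequency 0.01, two loci — a plausible rare, strong
#' susceptibility factor of the kind the model fits prefer (a handful of
#' rare alleles with large effects rather than common weak ones).
#'
#' @return A one-row locus-class tibble with all three parameters marked
#'   free.
#' @export
default_constant_class <- function() {
  locus_class("constant", gamma = 2.6, maf = 0.01, count = 2L,
              gamma_free = TRUE, maf_free = TRUE, count_free = TRUE)
}

fixture_manifest <- function(spec, base, n_pairs, seed, engine, files = NULL) {
  list(spec = list(name = spec$name,
                   classes = as.data.frame(spec$classes),
                   metamodel = spec$metamodel),
       base = base[c("rate", "shape", "origin_day", "cap_day")],
       calibration_targets = list(median_ga = 280, q10_ga = 266),
       n_pairs = n_pairs, seed = seed, engine = engine,
       files = files)
}

#' Generate the synthetic reference cousin-pair population
#'
#' A stand-in, with known ground truth, for a register-derived sample of
#' maternal-cousin gestational ages: by default 35,541 pairs simulated
#' with the iterative engine under the M3-style model (four fixed
#' Gaussian-window classes plus the [default_constant_class()]). The
#' emitted retained-bin quantile table is the fitting target for
#' [fit_model()] and reproduces the qualitative register pattern in
#' which the lower quantiles climb more steeply than the upper ones.
#'
#' @param spec Generating [model_spec()] (default [spec_m3()]).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed (required: fixtures must be reproducible).
#' @param base Baseline hazard.
#' @param dir Optional directory; when given, the cohort TSV, quantile
#'   TSV and manifest JSON are written there.
#' @return A list (class `gw_fixture`) with `cohort`, `table`, and
#'   `manifest` (generating parameters, seed, engine, file md5 hashes
#'   when written).
#' @export
make_reference_population <- function(spec = spec_m3(), n_pairs = 35541,
                                      seed = 1, base = default_baseline(),
                                      dir = NULL) {
  cohort <- simulate_pair_cohort(spec, n_pairs, base = base,
                                 engine = "iterative", seed = seed)
  qt <- conditional_quantile_table(cohort, seed = child_seed(seed, 1))
  manifest <- fixture_manifest(spec, base, n_pairs, seed, "iterative")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cohort_path <- file.path(dir, "reference_cohort.tsv")
    table_path <- file.path(dir, "reference_quantiles.tsv")
    readr::write_tsv(as_tibble(cohort), cohort_path)
    write_quantile_table(qt, table_path)
    manifest$files <- list(
      cohort = list(path = cohort_path, md5 = unname(tools::md5sum(cohort_path))),
      table = list(path = table_path, md5 = unname(tools::md5sum(table_path))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(cohort = cohort, table = qt, manifest = manifest),
            class = "gw_fixture")
}

#' Generate a polygenic "height-like" control cohort
#'
#' A plain additive Gaussian trait (not a survival trait) shared between
#' siblings: each member's value is the sum of small equal allele effects
#' over `n_loci` shared sibling genotypes plus independent Gaussian
#' noise, scaled so the heritable fraction of the variance is `h2`.
#' Siblings share half the additive variance, so the expected pair
#' correlation is `h2 / 2`. Its conditional quantile pattern is uniform
#' (parallel quantile series) — the contrast case for the gestational-age
#' fixture.
#'
#' @param n_pairs Number of sibling pairs.
#' @param n_loci Number of loci (>= 100); frequencies drawn uniformly in
#'   (0.05, 0.5).
#' @param h2 Heritable fraction of trait variance, in \[0, 1\].
#' @param trait_mean,trait_sd Marginal mean and SD of the trait (defaults
#'   emulate maternal height in cm).
#' @param bin_width Bin width for the emitted quantile table.
#' @param seed Integer seed.
#' @param min_count Bin retention threshold.
#' @return A list (class `gw_fixture`) with `cohort` (columns `trait1`,
#'   `trait2`), `table`, and `manifest`.
#' @export
make_polygenic_control <- function(n_pairs = 35541, n_loci = 1000, h2 = 0.5,
                                   trait_mean = 165, trait_sd = 6,
                                   bin_width = 5, seed = 1, min_count = 100) {
  stopifnot(n_loci >= 100, h2 >= 0, h2 <= 1)
  local_seed(seed)
  mafs <- runif(n_loci, 0.05, 0.5)
  var_g_unit <- sum(2 * mafs * (1 - mafs))   # per unit effect^2
  a <- if (h2 > 0) sqrt(h2 * trait_sd^2 / var_g_unit) else 0
  s1 <- numeric(n_pairs)
  s2 <- numeric(n_pairs)
  for (l in seq_len(n_loci)) {
    gp <- draw_sibling_genotype_pairs(mafs[l], n_pairs)
    s1 <- s1 + a * (gp$g1 - 2 * mafs[l])
    s2 <- s2 + a * (gp$g2 - 2 * mafs[l])
  }
  sd_e <- sqrt((1 - h2) * trait_sd^2)
  cohort <- tibble(trait1 = trait_mean + s1 + stats::rnorm(n_pairs, 0, sd_e),
                   trait2 = trait_mean + s2 + stats::rnorm(n_pairs, 0, sd_e))
  qt <- conditional_quantile_table(cohort, cols = c("trait1", "trait2"),
                                   bin_width = bin_width,
                                   min_count = min_count)
  manifest <- list(kind = "polygenic_control", n_pairs = n_pairs,
                   n_loci = n_loci, h2 = h2, trait_mean = trait_mean,
                   trait_sd = trait_sd, bin_width = bin_width, seed = seed)
  structure(list(cohort = cohort, table = qt, manifest = manifest),
            class = "gw_fixture")
}

#' @export
print.gw_fixture <- function(x, ...) {
  cat(sprintf("<gw_fixture> %d pairs, %d retained bins\n",
              nrow(x$cohort), nrow(x$table)))
  invisible(x)
}
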