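#' Single-locus association tests
#'
#' `linear_test()` returns the two-sided p-value for the slope of a
#' univariate least-squares regression of the phenotype (gestational age
#' in days) on the additively coded genotype. `cox_wald_test()` returns
#' the Wald p-value of the single coefficient of a Cox proportional-
#' hazards fit (`survival::coxph`) of the event time on the genotype,
#' with the Efron approximation for the heavy ties produced by
#' integer-day data.
#'
#' @param genotype Additively coded dosages (0/1/2).
#' @param phenotype,time Gestational ages in days.
#' @param event Event indicator; defaults to all-events (every pregnancy
#'   ends in an observed birth; day-300-capped outcomes are treated as
#'   observed deliveries by induction).
#' @return A single p-value with attributes `estimate` (slope or log
#'   hazard ratio), `std.error`, and for the Cox test `flagged` (TRUE if
#'   the fit emitted convergence warnings). `NA` (with attribute
#'   `reason`) when the test is not assessable (constant genotype,
#'   n < 3, no events, or a failed fit).
#' @export
linear_test <- function(genotype, phenotype) {
  if (length(genotype) < 3 || length(unique(genotype)) < 2) {
    return(structure(NA_real_, reason = "degenerate genotype"))
  }
  fit <- lm(phenotype ~ genotype)
  cf <- summary(fit)$coefficients
  structure(cf["genotype", "Pr(>|t|)"],
            estimate = cf["genotype", "Estimate"],
            std.error = cf["genotype", "Std. Error"])
}

#' @rdname linear_test
#' @export
cox_wald_test <- function(genotype, time, event = rep(1, length(time))) {
  if (length(genotype) < 3 || length(unique(genotype)) < 2 || sum(event) < 1) {
    return(structure(NA_real_, reason = "degenerate input"))
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(survival::Surv(time, event) ~ genotype, ties = "efron"),
      error = function(e) NULL),
    warning = function(w) {
      flagged <<- TRUE
      rlang::cnd_muffle(w)
    })
  if (is.null(fit) || is.na(coef(fit)[1])) {
    return(structure(NA_real_, reason = "fit failed", flagged = TRUE))
  }
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  z <- beta / se
  structure(2 * stats::pnorm(-abs(z)),
            estimate = beta, std.error = se, flagged = flagged)
}

control_locus_names <- function(control_mafs) {
  sprintf("ctrl_maf%s", vapply(control_mafs, format, character(1)))
}

control_genotypes <- function(n, control_mafs) {
  cols <- purrr::map(control_mafs, ~ draw_independent_genotypes(.x, n))
  names(cols) <- control_locus_names(control_mafs)
  as_tibble(cols)
}

test_all_loci <- function(cohort, locus_cols) {
  purrr::map_dfr(locus_cols, function(lc) {
    g <- cohort[[lc]]
    tibble(locus = lc,
           test = c("linear", "cox"),
           p = c(as.numeric(linear_test(g, cohort$ga)),
                 as.numeric(cox_wald_test(g, cohort$ga))))
  })
}

#' Empirical power and type-I error of locus detection
#'
#' For each sample size, simulates `reps` cohorts of unrelated
#' individuals under `spec`, appends null control loci, tests every
#' locus with both the linear and the Cox test, and reports the fraction
#' of p-values below the genome-wide threshold (power for causal loci;
#' type-I error for controls). Control rejection rates are additionally
#' tabulated at each `nominal_levels` entry.
#'
#' @param spec A [model_spec()] (the causal loci are its locus columns).
#' @param sample_sizes Integer vector of cohort sizes (each >= 10).
#' @param reps Replicates per sample size (>= 1).
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @param nominal_levels Nominal levels at which control-locus rejection
#'   is tabulated.
#' @param control_mafs Frequencies of the appended no-effect loci.
#' @param base Baseline hazard.
#' @param seed Optional integer seed.
#' @return A `gw_power`: list with `power` (tibble: locus, kind, n, test,
#'   power, reps, failures), `control` (control rejection rates per
#'   nominal level), `threshold`, `reps`.
#' @export
power_analysis <- function(spec, sample_sizes, reps, threshold = 5e-8,
                           nominal_levels = c(0.05, threshold),
                           control_mafs = c(0.015, 0.3),
                           base = default_baseline(), seed = NULL) {
  stopifnot(reps >= 1, all(sample_sizes >= 10))
  local_seed(seed)
  res <- purrr::map_dfr(sample_sizes, function(n) {
    purrr::map_dfr(seq_len(reps), function(r) {
      cohort <- simulate_individuals(spec, n, base = base)
      cohort <- dplyr::bind_cols(cohort, control_genotypes(n, control_mafs))
      locus_cols <- setdiff(names(cohort), "ga")
      dplyr::mutate(test_all_loci(cohort, locus_cols), n = n, rep = r)
    })
  })
  res <- dplyr::mutate(res, kind = ifelse(grepl("^ctrl", .data$locus),
                                          "control", "causal"))
  power <- res |>
    dplyr::summarise(
      power = mean(.data$p < threshold, na.rm = TRUE),
      reps = dplyr::n(),
      failures = sum(is.na(.data$p)),
      .by = c("locus", "kind", "n", "test"))
  control <- purrr::map_dfr(nominal_levels, function(lv) {
    res |>
      dplyr::filter(.data$kind == "control") |>
      dplyr::summarise(level = lv,
                       rate = mean(.data$p < lv, na.rm = TRUE),
                       reps = sum(!is.na(.data$p)),
                       .by = c("locus", "n", "test"))
  })
  structure(list(power = power, control = control, threshold = threshold,
                 reps = reps, spec_name = spec$name),
            class = "gw_power")
}

#' @export
print.gw_power <- function(x, ...) {
  cat(sprintf("<gw_power> %s: threshold %.1e, %d reps per sample size\n",
              x$spec_name, x$threshold, x$reps))
  print(x$power, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gw_power <- function(x, ...) x$power

#' @exportS3Method generics::glance
glance.gw_power <- function(x, ...) {
  tibble(spec = x$spec_name, threshold = x$threshold, reps = x$reps,
         n_loci = length(unique(x$power$locus)),
         n_sizes = length(unique(x$power$n)))
}

#' Type-I-error table for null control loci
#'
#' Simulates `reps` cohorts of size `n` under `spec`, tests control loci
#' (which are independent of the phenotype) with both tests, and reports
#' the empirical rejection rate at each nominal level with a 99% binomial
#' (Wilson) confidence interval. Cells where the expected minor-allele
#' count `2 * n * maf` is about 3 or fewer are flagged: with so few
#' carriers the tests are known to be unreliable.
#'
#' @inheritParams power_analysis
#' @param n Cohort size per replicate.
#' @return A tibble: locus, maf, test, level, rate, ci_lo, ci_hi, reps,
#'   low_count flag.
#' @export
type1_table <- function(spec, control_mafs = c(0.015, 0.3),
                        nominal_levels = c(0.05, 5e-8), reps, n,
                        base = default_baseline(), seed = NULL) {
  stopifnot(reps >= 1, n >= 10)
  local_seed(seed)
  res <- purrr::map_dfr(seq_len(reps), function(r) {
    cohort <- simulate_individuals(spec, n, base = base)
    ctrl <- control_genotypes(n, control_mafs)
    cohort <- dplyr::bind_cols(cohort["ga"], ctrl)
    test_all_loci(cohort, names(ctrl))
  })
  maf_of <- stats::setNames(control_mafs, control_locus_names(control_mafs))
  purrr::map_dfr(nominal_levels, function(lv) {
    res |>
      dplyr::summarise(level = lv,
                       rate = mean(.data$p < lv, na.rm = TRUE),
                       reps = sum(!is.na(.data$p)),
                       .by = c("locus", "test")) |>
      dplyr::mutate(
        maf = unname(maf_of[.data$locus]),
        ci_lo = wilson_ci(.data$rate, .data$reps, 0.99)[, 1],
        ci_hi = wilson_ci(.data$rate, .data$reps, 0.99)[, 2],
        low_count = 2 * n * .data$maf <= 3)
  }) |>
    dplyr::select("locus", "maf", "test", "level", "rate",
                  "ci_lo", "ci_hi", "reps", "low_count")
}

# Wilson score interval, vectorized; returns a 2-column matrix.
wilson_ci <- function(p_hat, n, conf = 0.99) {
  z <- qnorm(1 - (1 - conf) / 2)
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(pmax(0, centre - half), pmin(1, centre + half))
}

#' Write a power result as TSV plus JSON manifest
#'
#' @param x A `gw_power`.
#' @param path Output TSV path (power table); the control-rate table goes
#'   to `<path>.control.tsv` and a JSON manifest to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_power_result <- function(x, path) {
  readr::write_tsv(x$power, path)
  readr::write_tsv(x$control, paste0(path, ".control.tsv"))
  jsonlite::write_json(
    list(spec = x$spec_name, threshold = x$threshold, reps = x$reps),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
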