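#' Gompertz baseline hazard for gestational age
#'
#' The baseline instantaneous rate of birth is `rate * exp(shape * t)`,
#' with `t = 0` at `origin_day` (gestational day 150, when pregnancies
#' enter the population at risk) and all assigned gestational ages capped
#' at `cap_day` (day 300, emulating post-term induction).
#'
#' @param rate Gompertz rate `lambda` (> 0, per day).
#' @param shape Gompertz shape `alpha` (per day); 0 gives the exponential
#'   limit.
#' @param origin_day Gestational day mapped to `t = 0`.
#' @param cap_day Maximum assignable gestational day.
#' @return An object of class `gw_baseline`.
#' @export
baseline_hazard <- function(rate, shape, origin_day = 150, cap_day = 300) {
  stopifnot(rate > 0, origin_day < cap_day)
  structure(list(rate = rate, shape = shape,
                 origin_day = origin_day, cap_day = cap_day),
            class = "gw_baseline")
}

#' @export
print.gw_baseline <- function(x, ...) {
  cat(sprintf(
    "<gw_baseline> Gompertz rate = %.4g /d, shape = %.4g /d, origin day %g, cap day %g\n",
    x$rate, x$shape, x$origin_day, x$cap_day))
  invisible(x)
}

#' Evaluate the baseline hazard
#'
#' @param t Days since the at-risk origin (>= 0); vectorized.
#' @param base A [baseline_hazard()].
#' @return Hazard per day, `rate * exp(shape * t)`.
#' @export
hazard_baseline <- function(t, base) {
  stopifnot(inherits(base, "gw_baseline"))
  if (any(t < 0)) abort("`t` must be >= 0 (days since the at-risk origin)")
  base$rate * exp(base$shape * t)
}

# Cumulative baseline hazard on the shifted scale; exact exponential limit.
cumhaz_baseline <- function(t, base) {
  if (abs(base$shape) < 1e-12) return(base$rate * t)
  base$rate / base$shape * (exp(base$shape * t) - 1)
}

#' Baseline survival function
#'
#' Closed-form Gompertz survival `S(t) = exp(-m * (rate/shape) *
#' (exp(shape t) - 1))` under a constant hazard multiplier `m`.
#'
#' @inheritParams hazard_baseline
#' @param multiplier Constant hazard multiplier (default 1).
#' @return `P(T > t)`, vectorized over `t`.
#' @export
survival_baseline <- function(t, base, multiplier = 1) {
  exp(-multiplier * cumhaz_baseline(t, base))
}

#' Per-allele effect trajectory of a locus class
#'
#' Constant classes contribute `gamma` to the log hazard at every day;
#' varying classes contribute a Gaussian window
#' `gamma / (sigma * sqrt(2 * pi)) * exp(-((day - mu) / sigma)^2 / 2)`
#' with `day`, `mu` and `sigma` on the gestational-day scale, so the
#' trajectory integrates to `gamma` over all time.
#'
#' @param class A one-row locus-class tibble from [locus_class()].
#' @param day Gestational day(s) at which to evaluate (not days since
#'   origin).
#' @return Per-allele log-hazard contribution, vectorized over `day`.
#' @export
effect_trajectory <- function(class, day) {
  stopifnot(is.data.frame(class), nrow(class) == 1L)
  if (class$kind == "constant") {
    rep(class$gamma, length(day))
  } else {
    class$gamma / (class$sigma * sqrt(2 * pi)) *
      exp(-0.5 * ((day - class$mu) / class$sigma)^2)
  }
}

# Matrix of per-allele effects: rows = classes (in order), one column per day.
effect_matrix <- function(classes, days) {
  m <- vapply(seq_len(nrow(classes)),
              function(i) effect_trajectory(classes[i, ], days),
              numeric(length(days)))
  t(matrix(m, nrow = length(days)))
}

#' Composite individual hazard
#'
#' The full model hazard `rate * exp(shape * t) * exp(sum_i G_i E_i(day))`
#' where `G_i` is the individual's minor-allele dosage at locus `i`,
#' `E_i` the per-allele trajectory of its class, and `day = origin_day + t`
#' feeds the Gaussian windows.
#'
#' @param t Days since the at-risk origin (scalar or vector).
#' @param genotypes Integer dosage vector, one entry per locus, i.e. of
#'   length `sum(classes$count)`, ordered by class then locus.
#' @param classes Locus-class tibble (rows from [locus_class()]).
#' @param base A [baseline_hazard()].
#' @return Hazard per day, vectorized over `t`.
#' @export
total_hazard <- function(t, genotypes, classes, base) {
  classes <- as_tibble(classes)
  n_loci <- sum(classes$count)
  if (length(genotypes) != n_loci) {
    abort(sprintf("`genotypes` has length %d but classes define %d loci",
                  length(genotypes), n_loci))
  }
  g_class <- class_dosage_sums(matrix(genotypes, nrow = 1), classes)
  E <- effect_matrix(classes, base$origin_day + t)   # classes x t
  hazard_baseline(t, base) * exp(as.vector(g_class %*% E))
}

# Sum per-locus dosages within each class: geno is n x total_loci with
# columns grouped by class; returns n x n_classes.
class_dosage_sums <- function(geno, classes) {
  idx <- rep(seq_len(nrow(classes)), classes$count)
  out <- matrix(0, nrow = nrow(geno), ncol = nrow(classes))
  for (k in seq_len(nrow(classes))) {
    cols <- which(idx == k)
    out[, k] <- if (length(cols) == 1L) geno[, cols] else rowSums(geno[, cols, drop = FALSE])
  }
  out
}

#' Fit a parametric baseline to gestational ages
#'
#' Maximum-likelihood fit of an exponential, Weibull or Gompertz model to
#' times on the shifted scale `t = ga - origin_day`, treating every
#' observation as an event (live births, no censoring). Fitting is done
#' with \pkg{flexsurv}.
#'
#' @param ga_days Gestational ages in days, all in `(origin_day, cap_day]`;
#'   need not be integers. At least 10 observations.
#' @param family `"exponential"`, `"weibull"` or `"gompertz"`.
#' @param origin_day,cap_day At-risk origin and cap (days).
#' @return An object of class `gw_parametric_fit` with elements `family`,
#'   `params` (named, natural scale), `loglik`, `aic`, `n`, and the
#'   underlying `flexsurv` fit.
#' @export
fit_parametric_baseline <- function(ga_days,
                                    family = c("gompertz", "weibull", "exponential"),
                                    origin_day = 150, cap_day = 300) {
  family <- match.arg(family)
  if (length(ga_days) < 10) abort("need at least 10 observations")
  if (any(ga_days <= origin_day | ga_days > cap_day)) {
    abort("all gestational ages must lie in (origin_day, cap_day]")
  }
  t <- ga_days - origin_day
  dist <- switch(family, exponential = "exp", weibull = "weibull",
                 gompertz = "gompertz")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(t, rep(1, length(t))) ~ 1, dist = dist),
    error = function(e) abort(sprintf("%s fit failed to converge: %s",
                                      family, conditionMessage(e))))
  params <- fit$res[, "est"]
  structure(list(family = family, params = params,
                 loglik = fit$loglik, aic = stats::AIC(fit),
                 n = length(t), origin_day = origin_day, fit = fit),
            class = "gw_parametric_fit")
}

#' @export
print.gw_parametric_fit <- function(x, ...) {
  cat(sprintf("<gw_parametric_fit> %s, n = %d, loglik = %.2f, AIC = %.2f\n",
              x$family, x$n, x$loglik, x$aic))
  print(round(x$params, 6))
  invisible(x)
}

#' Select the best-fitting baseline family by AIC
#'
#' Fits exponential, Weibull and Gompertz models to the same sample and
#' returns the family with the lowest AIC (ties broken toward fewer
#' parameters).
#'
#' @inheritParams fit_parametric_baseline
#' @return A list with `best` (family name) and `fits` (named list of
#'   [fit_parametric_baseline()] results; a failed family is recorded as
#'   the condition object).
#' @export
select_baseline <- function(ga_days, origin_day = 150, cap_day = 300) {
  fams <- c("exponential", "weibull", "gompertz")  # increasing k on ties
  fits <- purrr::map(fams, function(f) {
    tryCatch(fit_parametric_baseline(ga_days, f, origin_day, cap_day),
             error = identity)
  })
  names(fits) <- fams
  ok <- !vapply(fits, inherits, logical(1), "condition")
  if (!any(ok)) abort("all three parametric fits failed")
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  list(best = names(aics)[which.min(aics)], fits = fits)
}

#' @exportS3Method generics::tidy
tidy.gw_parametric_fit <- function(x, ...) {
  res <- x$fit$res
  tibble(term = rownames(res), estimate = res[, "est"],
         conf.low = res[, "L95%"], conf.high = res[, "U95%"],
         std.error = res[, "se"])
}

#' @exportS3Method generics::glance
glance.gw_parametric_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic, nobs = x$n)
}
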