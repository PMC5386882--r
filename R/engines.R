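#' Analytic survival-time sampling under a constant hazard multiplier
#'
#' Inverse-transform sampling from the Gompertz model with hazard
#' `m * rate * exp(shape * t)`: with `U ~ Unif(0, 1)`,
#' `T = log(1 - shape * log(U) / (m * rate)) / shape` (or
#' `T = -log(U) / (m * rate)` in the exponential limit `shape = 0`).
#' Times are discretized by ceiling to whole days, so the first possible
#' birth day is `origin_day + 1`, and capped at `cap_day`.
#'
#' @param base A [baseline_hazard()].
#' @param multiplier Constant hazard multiplier(s) `m > 0`; one draw per
#'   element (or `n` draws of a scalar).
#' @param n Number of draws (defaults to `length(multiplier)`).
#' @param seed Optional integer seed; `NULL` uses the current stream.
#' @param discretize If `FALSE`, return continuous gestational ages
#'   `origin_day + T` (still capped) instead of whole days.
#' @return Gestational ages in days, in `(origin_day, cap_day]`.
#' @export
sample_survival_analytic <- function(base, multiplier = 1, n = length(multiplier),
                                     seed = NULL, discretize = TRUE) {
  stopifnot(inherits(base, "gw_baseline"), n >= 1)
  if (any(multiplier <= 0)) abort("`multiplier` must be > 0")
  local_seed(seed)
  m <- rep_len(multiplier, n)
  u <- runif(n)
  T <- if (abs(base$shape) < 1e-12) {
    -log(u) / (m * base$rate)
  } else {
    log1p(-base$shape * log(u) / (m * base$rate)) / base$shape
  }
  ga <- base$origin_day + if (discretize) ceiling(T) else T
  pmin(ga, base$cap_day)
}

#' Iterative daily-hazard survival-time sampling
#'
#' Walks gestation day by day from the at-risk origin: on day
#' `origin_day + t` the individual hazard is evaluated at mid-day
#' (`t - 0.5` on the shifted scale, so Gaussian windows see gestational
#' day `origin_day + t - 0.5`) and a birth is assigned with probability
#' `1 - exp(-hazard)`. Individuals still pregnant at `cap_day` are
#' assigned `cap_day` as an observed delivery. This engine supports any
#' mix of constant- and varying-effect classes; for constant-only models
#' it agrees with [sample_survival_analytic()] to within the one-day
#' discretization.
#'
#' @inheritParams sample_survival_analytic
#' @param genotypes Integer dosage matrix, one row per individual and one
#'   column per locus (columns grouped by class, `sum(classes$count)` in
#'   total); a vector is taken as a single individual.
#' @param classes Locus-class tibble (may have zero rows).
#' @return Integer gestational days in `(origin_day, cap_day]`, one per
#'   row of `genotypes`.
#' @export
sample_survival_iterative <- function(base, genotypes, classes, seed = NULL) {
  stopifnot(inherits(base, "gw_baseline"))
  classes <- as_tibble(classes)
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1)
  n_loci <- sum(classes$count)
  if (ncol(genotypes) != n_loci && !(n_loci == 0 && ncol(genotypes) == 0)) {
    abort(sprintf("`genotypes` has %d columns but classes define %d loci",
                  ncol(genotypes), n_loci))
  }
  local_seed(seed)
  n <- nrow(genotypes)
  gsum <- if (nrow(classes)) class_dosage_sums(genotypes, classes) else
    matrix(0, n, 0)
  iterative_days(base, gsum, classes, n)
}

# Core day-by-day simulation given per-class dosage sums (n x n_classes).
iterative_days <- function(base, gsum, classes, n) {
  horizon <- base$cap_day - base$origin_day
  t_mid <- seq_len(horizon) - 0.5
  # log-hazard decomposition: baseline(t) + constant part + varying part(t)
  log_base <- log(base$rate) + base$shape * t_mid
  const <- classes$kind == "constant"
  eta_const <- if (any(const)) {
    as.vector(gsum[, const, drop = FALSE] %*% classes$gamma[const])
  } else rep(0, n)
  vary <- which(!const)
  E_var <- if (length(vary)) {
    effect_matrix(classes[vary, ], base$origin_day + t_mid)  # V x T
  } else NULL
  G_var <- if (length(vary)) gsum[, vary, drop = FALSE] else NULL

  days <- rep(base$cap_day, n)
  alive <- seq_len(n)
  for (t in seq_len(horizon)) {
    eta <- eta_const[alive]
    if (!is.null(E_var)) {
      eta <- eta + as.vector(G_var[alive, , drop = FALSE] %*% E_var[, t])
    }
    p_birth <- -expm1(-exp(log_base[t] + eta))
    born <- runif(length(alive)) < p_birth
    if (any(born)) {
      days[alive[born]] <- base$origin_day + t
      alive <- alive[!born]
      if (!length(alive)) break
    }
  }
  as.integer(days)
}

draw_spec_genotypes <- function(spec, n, paired) {
  cl <- spec$classes
  cols <- list()
  for (k in seq_len(nrow(cl))) {
    for (j in seq_len(cl$count[k])) {
      nm <- sprintf("L%d.%d", k, j)
      if (paired) {
        gp <- draw_sibling_genotype_pairs(cl$maf[k], n)
        cols[[paste0(nm, "_1")]] <- gp$g1
        cols[[paste0(nm, "_2")]] <- gp$g2
      } else {
        cols[[nm]] <- draw_independent_genotypes(cl$maf[k], n)
      }
    }
  }
  cols
}

resolve_engine <- function(engine, spec) {
  engine <- match.arg(engine, c("auto", "analytic", "iterative"))
  if (engine == "auto") {
    engine <- if (has_varying(spec)) "iterative" else "analytic"
  }
  if (engine == "analytic" && has_varying(spec)) {
    abort("the analytic engine requires all locus classes to be constant-effect")
  }
  engine
}

member_days <- function(geno, spec, base, engine) {
  if (engine == "analytic") {
    cl <- spec$classes
    eta <- if (nrow(cl)) {
      as.vector(class_dosage_sums(geno, cl) %*% (cl$gamma * (cl$kind == "constant")))
    } else rep(0, nrow(geno))
    as.integer(sample_survival_analytic(base, exp(eta)))
  } else {
    sample_survival_iterative(base, geno, spec$classes)
  }
}

#' Simulate a cohort of relative pairs
#'
#' Draws shared full-sibling genotypes per locus class and generates each
#' member's gestational age from the composite hazard. This emulates the
#' gestational ages of maternal-cousin pairs, i.e. pregnancies of full
#' sisters whose shared maternal genotypes drive the familial correlation.
#'
#' @param spec A [model_spec()].
#' @param n_pairs Number of pairs.
#' @param base A [baseline_hazard()]; defaults to [default_baseline()].
#' @param engine `"auto"` (analytic when all classes are constant-effect,
#'   iterative otherwise), `"analytic"` or `"iterative"`.
#' @param seed Optional integer seed.
#' @param keep_genotypes Attach per-member genotype columns
#'   (`L<class>.<locus>_1/_2`)?
#' @return A tibble with columns `ga1`, `ga2` (integer days in
#'   `(origin_day, cap_day]`) and optionally genotype columns; attributes
#'   `spec`, `base`, `engine`, `seed`.
#' @export
simulate_pair_cohort <- function(spec, n_pairs, base = default_baseline(),
                                 engine = c("auto", "analytic", "iterative"),
                                 seed = NULL, keep_genotypes = FALSE) {
  stopifnot(inherits(spec, "gw_model_spec"), n_pairs >= 1)
  engine <- resolve_engine(engine, spec)
  local_seed(seed)
  g <- draw_spec_genotypes(spec, n_pairs, paired = TRUE)
  is1 <- grepl("_1$", names(g))
  g1 <- do.call(cbind, c(g[is1], list(matrix(0L, n_pairs, 0))))
  g2 <- do.call(cbind, c(g[!is1], list(matrix(0L, n_pairs, 0))))
  cohort <- tibble(ga1 = member_days(g1, spec, base, engine),
                   ga2 = member_days(g2, spec, base, engine))
  if (keep_genotypes && length(g)) cohort <- dplyr::bind_cols(cohort, as_tibble(g))
  structure(cohort, spec = spec, base = base, engine = engine, seed = seed)
}

#' Simulate unrelated individuals with genotypes
#'
#' @inheritParams simulate_pair_cohort
#' @param n_ind Number of individuals.
#' @return A tibble with column `ga` and one genotype column per locus
#'   (`L<class>.<locus>`, dosage 0/1/2); no genotype columns for a
#'   genetics-free spec.
#' @export
simulate_individuals <- function(spec, n_ind, base = default_baseline(),
                                 engine = c("auto", "analytic", "iterative"),
                                 seed = NULL) {
  stopifnot(inherits(spec, "gw_model_spec"), n_ind >= 1)
  engine <- resolve_engine(engine, spec)
  local_seed(seed)
  g <- draw_spec_genotypes(spec, n_ind, paired = FALSE)
  gm <- do.call(cbind, c(g, list(matrix(0L, n_ind, 0))))
  out <- tibble(ga = member_days(gm, spec, base, engine))
  if (length(g)) out <- dplyr::bind_cols(out, as_tibble(g))
  structure(out, spec = spec, base = base, engine = engine, seed = seed)
}

#' Write / read a pair cohort as TSV with a JSON manifest
#'
#' The manifest records the generating model, baseline parameters, seed
#' and engine so a cohort can be regenerated bit-for-bit.
#'
#' @param cohort A cohort tibble from [simulate_pair_cohort()] or
#'   [simulate_individuals()].
#' @param path Output TSV path; the manifest is written alongside as
#'   `<path>.manifest.json`.
#' @return `path` invisibly (`write`); a tibble (`read`).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path)
  spec <- attr(cohort, "spec")
  base <- attr(cohort, "base")
  manifest <- list(
    n = nrow(cohort),
    spec = if (!is.null(spec)) list(name = spec$name,
                                    classes = as.data.frame(spec$classes),
                                    metamodel = spec$metamodel),
    base = if (!is.null(base)) base[c("rate", "shape", "origin_day", "cap_day")],
    engine = attr(cohort, "engine"),
    seed = attr(cohort, "seed"),
    md5 = unname(tools::md5sum(path))
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
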