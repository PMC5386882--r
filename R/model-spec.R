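#' Define a class of identical susceptibility loci
#'
#' A locus class groups `count` loci that share the same parameters. A
#' `constant` class multiplies the log hazard by `gamma` per allele copy
#' uniformly across gestation; a `varying` class contributes a Gaussian
#' window of sensitivity centred at gestational day `mu` with spread
#' `sigma` (days) and total mass `gamma`.
#'
#' @param kind `"constant"` or `"varying"`.
#' @param gamma Per-allele log-hazard effect size. For constant classes
#'   this is the proportional-hazards log hazard ratio per allele copy;
#'   for varying classes it is the area under the effect trajectory.
#' @param maf Minor allele frequency, in (0, 0.5\] (0 allowed for
#'   degenerate test cases).
#' @param count Integer number of identical loci in the class (>= 1).
#' @param mu Day of peak effect (gestational days); varying classes only.
#' @param sigma Spread of the effect window (days, > 0); varying classes
#'   only.
#' @param gamma_free,maf_free,count_free Whether each parameter is free to
#'   be optimized by [random_search()] / [fit_model()] (otherwise fixed).
#' @return A one-row tibble; bind rows of these to form the class table of
#'   a [model_spec()].
#' @export
locus_class <- function(kind = c("constant", "varying"), gamma, maf, count = 1L,
                        mu = NA_real_, sigma = NA_real_,
                        gamma_free = FALSE, maf_free = FALSE,
                        count_free = FALSE) {
  kind <- match.arg(kind)
  assert_scalar_prob(maf, "maf", max = 0.5)
  if (count < 1 || count != round(count)) {
    abort("`count` must be a positive integer")
  }
  if (kind == "varying") {
    if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
      abort("varying classes need finite `mu` and `sigma` > 0")
    }
  } else {
    mu <- NA_real_
    sigma <- NA_real_
  }
  tibble(kind = kind, gamma = as.numeric(gamma), maf = as.numeric(maf),
         count = as.integer(count), mu = mu, sigma = sigma,
         gamma_free = gamma_free, maf_free = maf_free,
         count_free = count_free)
}

#' Construct a model specification
#'
#' A model specification names a set of locus classes together with the
#' free/fixed status of their parameters and whether the two-stage fit
#' uses meta-modeling on the sum-of-gamma-p-n summary.
#'
#' @param name Model name (e.g. `"M1"`).
#' @param classes A tibble of locus classes, rows from [locus_class()];
#'   `NULL` or zero rows gives a genetics-free model.
#' @param metamodel Should [fit_model()] restrict stage 2 to the
#'   low-cost interval of the `sum(gamma * maf * count)` summary?
#' @return An object of class `gw_model_spec`.
#' @seealso [spec_m0()], [spec_m1()], [spec_m2()], [spec_m3()], [spec_m4()]
#'   for the five canonical model families.
#' @export
model_spec <- function(name, classes = NULL, metamodel = FALSE) {
  if (is.null(classes)) {
    classes <- locus_class("constant", gamma = 0, maf = 0.1)[0, ]
  }
  stopifnot(is.data.frame(classes))
  classes <- as_tibble(classes)
  structure(
    list(name = name, classes = classes, metamodel = isTRUE(metamodel)),
    class = "gw_model_spec"
  )
}

#' @export
print.gw_model_spec <- function(x, ...) {
  cat(sprintf("<gw_model_spec> %s: %d locus class(es), metamodel = %s\n",
              x$name, nrow(x$classes), x$metamodel))
  if (nrow(x$classes)) print(x$classes, ...)
  invisible(x)
}

n_free_params <- function(spec) {
  cl <- spec$classes
  sum(cl$gamma_free) + sum(cl$maf_free) + sum(cl$count_free)
}

has_varying <- function(spec) any(spec$classes$kind == "varying")

#' The five canonical model families
#'
#' Nested families of gestational-age models: `M0` has no genetic
#' factors; `M1` one free constant-effect class; `M2` two constant-effect
#' classes (the second with a single locus); `M3` one free constant-effect
#' class plus four fixed varying-effect classes with windows peaking at
#' gestational days 230, 237, 244 and 258 (spread 10 d, effect masses
#' 100, 80, 60, -100, frequencies 0.005, 0.01, 0.015, 0.3); `M4` replaces
#' the varying classes of `M3` by constant-effect classes with the same
#' frequencies and counts, leaving only their four effect sizes free.
#'
#' Free parameters default to the values of [default_constant_class()]
#' so every spec is simulable as-is; [fit_model()] overrides the free ones.
#'
#' @param gamma,maf,count Values for the first (constant-effect) class.
#' @param gamma2,maf2 Values for the second class of `M2`.
#' @param gammas Effect sizes of the four constant classes of `M4`.
#' @return A [model_spec()].
#' @export
spec_m0 <- function() model_spec("M0")

#' @rdname spec_m0
#' @export
spec_m1 <- function(gamma = 2.6, maf = 0.01, count = 2L) {
  model_spec("M1",
    locus_class("constant", gamma, maf, count,
                gamma_free = TRUE, maf_free = TRUE, count_free = TRUE),
    metamodel = TRUE)
}

#' @rdname spec_m0
#' @export
spec_m2 <- function(gamma = 2.6, maf = 0.01, count = 2L,
                    gamma2 = -0.5, maf2 = 0.3) {
  model_spec("M2", dplyr::bind_rows(
    locus_class("constant", gamma, maf, count,
                gamma_free = TRUE, maf_free = TRUE, count_free = TRUE),
    locus_class("constant", gamma2, maf2, 1L,
                gamma_free = TRUE, maf_free = TRUE)),
    metamodel = TRUE)
}

varying_class_table <- function() {
  dplyr::bind_rows(
    locus_class("varying", 100, 0.005, 1L, mu = 230, sigma = 10),
    locus_class("varying", 80, 0.010, 1L, mu = 237, sigma = 10),
    locus_class("varying", 60, 0.015, 1L, mu = 244, sigma = 10),
    locus_class("varying", -100, 0.300, 1L, mu = 258, sigma = 10)
  )
}

#' @rdname spec_m0
#' @export
spec_m3 <- function(gamma = 2.6, maf = 0.01, count = 2L) {
  model_spec("M3", dplyr::bind_rows(
    locus_class("constant", gamma, maf, count,
                gamma_free = TRUE, maf_free = TRUE, count_free = TRUE),
    varying_class_table()),
    metamodel = TRUE)
}

#' @rdname spec_m0
#' @export
spec_m4 <- function(gamma = 2.6, maf = 0.01, count = 2L,
                    gammas = c(1, 1, 1, -1)) {
  stopifnot(length(gammas) == 4)
  vt <- varying_class_table()
  m4 <- purrr::pmap_dfr(
    list(gammas, vt$maf), function(g, p) {
      locus_class("constant", g, p, 1L, gamma_free = TRUE)
    })
  model_spec("M4", dplyr::bind_rows(
    locus_class("constant", gamma, maf, count), m4),
    metamodel = FALSE)
}

#' Sum of effect size x frequency x locus count over classes
#'
#' The scalar `sum(gamma * maf * count)` over locus classes, used by the
#' meta-modeling stage of [fit_model()] as a one-dimensional summary
#' predictive of fit cost.
#'
#' @param x A [model_spec()] or its class tibble.
#' @param free_only If `TRUE`, sum only over classes that have at least
#'   one free parameter (the convention used when fixed varying classes
#'   contribute a constant shift).
#' @return A single number; 0 for a model with no (matching) classes.
#' @export
sum_gamma_p_n <- function(x, free_only = FALSE) {
  cl <- if (inherits(x, "gw_model_spec")) x$classes else as_tibble(x)
  if (free_only && nrow(cl)) {
    cl <- dplyr::filter(cl, .data$gamma_free | .data$maf_free | .data$count_free)
  }
  if (!nrow(cl)) return(0)
  sum(cl$gamma * cl$maf * cl$count)
}

#' Read or write a model specification as YAML
#'
#' The file mirrors the class-table fields: `name`, `metamodel`, and a
#' list of classes with `kind`, `gamma`, `maf`, `count`, `mu`, `sigma`
#' and the `*_free` flags.
#'
#' @param path File path.
#' @param spec A [model_spec()] (for writing).
#' @return `read_model_spec()` a [model_spec()]; `write_model_spec()`
#'   `path` invisibly.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- purrr::map_dfr(y$classes, function(cl) {
    locus_class(kind = cl$kind, gamma = cl$gamma, maf = cl$maf,
                count = cl$count %||% 1L,
                mu = cl$mu %||% NA_real_, sigma = cl$sigma %||% NA_real_,
                gamma_free = isTRUE(cl$gamma_free),
                maf_free = isTRUE(cl$maf_free),
                count_free = isTRUE(cl$count_free))
  })
  if (length(y$classes) == 0) classes <- NULL
  model_spec(y$name, classes, metamodel = isTRUE(y$metamodel))
}

#' @rdname read_model_spec
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gw_model_spec"))
  cl_list <- purrr::pmap(spec$classes, function(...) {
    row <- list(...)
    row[!vapply(row, function(v) is.na(v) %in% TRUE, logical(1))]
  })
  yaml::write_yaml(list(name = spec$name, metamodel = spec$metamodel,
                        classes = cl_list), path)
  invisible(path)
}
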