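#' Draw a random candidate parameter assignment for a model
#'
#' Free parameters are drawn independently per class: effect size
#' `gamma ~ Unif(-5, 5)`, frequency `maf ~ Unif(0, 0.5)`, locus count
#' `n ~ 1 + Poisson(1)`. Fixed parameters are left untouched.
#'
#' @param spec A [model_spec()] with at least one free parameter.
#' @param seed Optional integer seed.
#' @return A [model_spec()] with free parameters replaced by the draws.
#' @export
draw_candidate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "gw_model_spec"))
  if (n_free_params(spec) == 0) {
    abort("spec has no free parameters; use `evaluate_model()` directly")
  }
  local_seed(seed)
  cl <- spec$classes
  for (k in seq_len(nrow(cl))) {
    if (cl$gamma_free[k]) cl$gamma[k] <- runif(1, -5, 5)
    if (cl$maf_free[k])   cl$maf[k]   <- runif(1, 0, 0.5)
    if (cl$count_free[k]) cl$count[k] <- 1L + rpois(1, 1)
  }
  out <- spec
  out$classes <- cl
  out
}

free_param_row <- function(spec) {
  cl <- spec$classes
  vals <- list()
  for (k in seq_len(nrow(cl))) {
    if (cl$gamma_free[k]) vals[[sprintf("gamma%d", k)]] <- cl$gamma[k]
    if (cl$maf_free[k])   vals[[sprintf("maf%d", k)]]   <- cl$maf[k]
    if (cl$count_free[k]) vals[[sprintf("count%d", k)]] <- as.numeric(cl$count[k])
  }
  as_tibble(vals)
}

score_candidates <- function(cands, ref, n_pairs, replicates, base, engine,
                             stage) {
  scored <- purrr::map(cands, function(cand) {
    ev <- evaluate_model(cand, ref, n_pairs = n_pairs,
                         replicates = replicates, base = base,
                         engine = engine)
    dplyr::bind_cols(
      free_param_row(cand),
      tibble(sum_gpn = sum_gamma_p_n(cand, free_only = TRUE),
             mean_cost = ev$mean_cost, sd_cost = ev$sd_cost,
             stage = stage, spec = list(cand)))
  })
  dplyr::bind_rows(scored)
}

new_search_result <- function(candidates, spec, config, interval = NULL) {
  candidates <- if ("final_cost" %in% names(candidates)) {
    dplyr::arrange(candidates, is.na(.data$final_cost),
                   dplyr::coalesce(.data$final_cost, .data$mean_cost))
  } else {
    dplyr::arrange(candidates, .data$mean_cost)
  }
  candidates$rank <- seq_len(nrow(candidates))
  structure(list(candidates = candidates, spec = spec,
                 interval = interval, config = config),
            class = "gw_search")
}

#' Random search over a model's free parameters
#'
#' Draws `budget` candidates with [draw_candidate()] and scores each
#' against the reference with [evaluate_model()].
#'
#' @param spec A [model_spec()] with free parameters.
#' @param ref Reference `gw_quantile_table`.
#' @param budget Number of candidates (>= 1).
#' @param n_pairs Pairs per scoring cohort (default: reference total).
#' @param replicates Scoring replicates per candidate (1 during search).
#' @param base,engine Passed to the simulator.
#' @param seed Optional integer seed for the whole search.
#' @return A `gw_search`: ranked `candidates` tibble (free parameter
#'   columns, `sum_gpn`, `mean_cost`, `sd_cost`, `stage`, `rank`, and a
#'   `spec` list-column of the candidate model specs).
#' @export
random_search <- function(spec, ref, budget, n_pairs = sum(ref$n),
                          replicates = 1, base = default_baseline(),
                          engine = c("auto", "analytic", "iterative"),
                          seed = NULL) {
  stopifnot(budget >= 1)
  local_seed(seed)
  cands <- purrr::map(seq_len(budget), function(i) draw_candidate(spec))
  res <- score_candidates(cands, ref, n_pairs, replicates, base, engine,
                          stage = "stage1")
  new_search_result(res, spec, list(budget = budget, n_pairs = n_pairs,
                                    replicates = replicates, seed = seed))
}

#' Meta-model restriction interval on the sum-of-gamma-p-n summary
#'
#' The interval of `sum_gpn` spanned by the lowest-cost fraction of
#' stage-1 candidates, widened by `margin` times its length on each side.
#' This one-dimensional summary is strongly predictive of cost, so the
#' second search stage can be confined to it.
#'
#' @param stage1 A `gw_search` with at least 100 candidates.
#' @param keep_fraction Fraction of candidates (by ascending cost) that
#'   defines the interval.
#' @param margin Relative widening on each side.
#' @param min_width Width substituted when the kept candidates span a
#'   degenerate (near-point) interval.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
metamodel_restrict <- function(stage1, keep_fraction = 0.01, margin = 0.1,
                               min_width = 0.05) {
  stopifnot(inherits(stage1, "gw_search"))
  cand <- stage1$candidates
  if (nrow(cand) < 100) abort("need at least 100 stage-1 candidates")
  k <- max(1L, ceiling(keep_fraction * nrow(cand)))
  kept <- dplyr::slice_min(cand, .data$mean_cost, n = k)  # ties kept
  iv <- range(kept$sum_gpn)
  len <- diff(iv)
  if (len < min_width) {
    mid <- mean(iv)
    iv <- mid + c(-0.5, 0.5) * min_width
    len <- min_width
  }
  iv + c(-1, 1) * margin * len
}

#' Two-stage meta-model fit of a model to a reference quantile table
#'
#' Stage 1 is an unconstrained [random_search()]. For meta-modeled specs,
#' the low-cost interval of `sum_gpn` is then determined with
#' [metamodel_restrict()] and stage 2 rejection-samples candidates whose
#' free-class `sum_gpn` falls inside it (keeping the stated marginal
#' draw distributions). Finally the `top_k` candidates over both stages
#' are re-scored with the iterative engine at `replicates_final`
#' replicates and re-ranked. Specs without meta-modeling (e.g. an
#' M4-style model) run a single-stage search with the combined budget; a
#' spec with no free parameters is simply evaluated.
#'
#' @param spec A [model_spec()].
#' @param ref Reference `gw_quantile_table`.
#' @param budget1,budget2 Candidate budgets for the two stages.
#' @param n_pairs Pairs per scoring cohort.
#' @param replicates_search,replicates_final Scoring replicates during
#'   the search and for the final re-ranking.
#' @param top_k Number of best candidates re-scored iteratively.
#' @param keep_fraction,margin Passed to [metamodel_restrict()].
#' @param base Baseline hazard.
#' @param seed Optional integer seed.
#' @return A `gw_search` whose `candidates` carry a `final_cost` column
#'   (`NA` outside the re-scored top set); ranked by `final_cost` where
#'   available, then `mean_cost`. The meta-model interval (if any) is in
#'   `$interval`.
#' @export
fit_model <- function(spec, ref, budget1 = 2000, budget2 = budget1,
                      n_pairs = sum(ref$n), replicates_search = 1,
                      replicates_final = 10, top_k = 20,
                      keep_fraction = 0.01, margin = 0.1,
                      base = default_baseline(), seed = NULL) {
  stopifnot(inherits(spec, "gw_model_spec"))
  local_seed(seed)
  config <- list(budget1 = budget1, budget2 = budget2, n_pairs = n_pairs,
                 replicates_search = replicates_search,
                 replicates_final = replicates_final, top_k = top_k,
                 keep_fraction = keep_fraction, margin = margin, seed = seed)

  if (n_free_params(spec) == 0) {
    ev <- evaluate_model(spec, ref, n_pairs = n_pairs,
                         replicates = replicates_final, base = base,
                         engine = "iterative")
    cand <- dplyr::bind_cols(
      tibble(sum_gpn = sum_gamma_p_n(spec, free_only = TRUE),
             mean_cost = ev$mean_cost, sd_cost = ev$sd_cost,
             stage = "evaluate", spec = list(spec),
             final_cost = ev$mean_cost))
    return(new_search_result(cand, spec, config))
  }

  interval <- NULL
  if (spec$metamodel) {
    s1 <- random_search(spec, ref, budget1, n_pairs, replicates_search,
                        base = base)
    interval <- metamodel_restrict(s1, keep_fraction, margin)
    cands2 <- list()
    tries <- 0L
    max_tries <- budget2 * 200L
    while (length(cands2) < budget2 && tries < max_tries) {
      tries <- tries + 1L
      cand <- draw_candidate(spec)
      s <- sum_gamma_p_n(cand, free_only = TRUE)
      if (s >= interval[1] && s <= interval[2]) {
        cands2[[length(cands2) + 1L]] <- cand
      }
    }
    if (length(cands2) < budget2) {
      warn(sprintf("stage 2 accepted only %d of %d requested candidates",
                   length(cands2), budget2))
    }
    res2 <- if (length(cands2)) {
      score_candidates(cands2, ref, n_pairs, replicates_search, base,
                       "auto", stage = "stage2")
    } else NULL
    all_cand <- dplyr::bind_rows(s1$candidates[setdiff(names(s1$candidates), "rank")],
                                 res2)
  } else {
    s1 <- random_search(spec, ref, budget1 + budget2, n_pairs,
                        replicates_search, base = base)
    all_cand <- s1$candidates[setdiff(names(s1$candidates), "rank")]
  }

  # final re-scoring of the best candidates with the iterative engine
  all_cand <- dplyr::arrange(all_cand, .data$mean_cost)
  k <- min(top_k, nrow(all_cand))
  final <- purrr::map_dbl(seq_len(k), function(i) {
    evaluate_model(all_cand$spec[[i]], ref, n_pairs = n_pairs,
                   replicates = replicates_final, base = base,
                   engine = "iterative")$mean_cost
  })
  all_cand$final_cost <- c(final, rep(NA_real_, nrow(all_cand) - k))
  all_cand <- dplyr::arrange(all_cand, is.na(.data$final_cost),
                             dplyr::coalesce(.data$final_cost, .data$mean_cost))
  new_search_result(all_cand, spec, config, interval)
}

#' @export
print.gw_search <- function(x, ...) {
  cat(sprintf("<gw_search> %s: %d candidate(s)", x$spec$name,
              nrow(x$candidates)))
  if (!is.null(x$interval)) {
    cat(sprintf("; metamodel interval [%.3f, %.3f]",
                x$interval[1], x$interval[2]))
  }
  cat("\n")
  print(head(tidy(x), 5), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gw_search <- function(x, ...) {
  dplyr::select(x$candidates, -"spec")
}

#' @exportS3Method generics::glance
glance.gw_search <- function(x, ...) {
  best <- x$candidates[1, ]
  best_final <- if ("final_cost" %in% names(best)) best$final_cost else NA_real_
  tibble(spec = x$spec$name, n_candidates = nrow(x$candidates),
         best_cost = dplyr::coalesce(best_final, best$mean_cost),
         best_sum_gpn = best$sum_gpn,
         interval_lo = x$interval[1] %||% NA_real_,
         interval_hi = x$interval[2] %||% NA_real_)
}

#' Best candidate of a search result
#'
#' @param x A `gw_search`.
#' @return The top-ranked candidate's [model_spec()].
#' @export
best_candidate <- function(x) {
  stopifnot(inherits(x, "gw_search"))
  x$candidates$spec[[1]]
}

#' Write a search result as a ranked TSV plus JSON summary
#'
#' @param x A `gw_search`.
#' @param path Output TSV path; a JSON summary is written alongside as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  jsonlite::write_json(
    c(as.list(glance(x)), list(config = x$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
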