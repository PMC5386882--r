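quantile_probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
quantile_cols <- c("q05", "q25", "q50", "q75", "q95")

#' Conditional quantile table of a paired phenotype
#'
#' Members of each pair are first labelled "first" and "second" at
#' random (the two are exchangeable). The conditioning member's value is
#' binned into `[edge, edge + bin_width)` windows with edges at multiples
#' of `bin_width` (so for gestational age with 7-day bins, 280 is a left
#' edge), and the 5th, 25th, 50th, 75th and 95th percentiles of the other
#' member's value are computed per bin. Percentiles use linear
#' interpolation between order statistics (`quantile(type = 7)`). Only
#' bins with strictly more than `min_count` pairs are retained.
#'
#' @param cohort A data frame with one row per pair.
#' @param cols Names of the two paired value columns (default
#'   `c("ga1", "ga2")`).
#' @param bin_width Bin width in the phenotype's units (7 days for
#'   gestational age; e.g. 5 cm for height-like traits).
#' @param min_count Retention threshold: a bin is kept only if its count
#'   exceeds this value.
#' @param seed Optional integer seed for the random member assignment.
#' @return A `gw_quantile_table`: a tibble with columns `bin_left`, `n`,
#'   `q05`, `q25`, `q50`, `q75`, `q95`, ordered by `bin_left`. Zero rows
#'   (with attribute `empty = TRUE`) if no bin passes retention.
#' @export
conditional_quantile_table <- function(cohort, cols = c("ga1", "ga2"),
                                       bin_width = 7, min_count = 100,
                                       seed = NULL) {
  stopifnot(is.data.frame(cohort), length(cols) == 2, all(cols %in% names(cohort)))
  if (!nrow(cohort)) abort("`cohort` is empty")
  local_seed(seed)
  a <- cohort[[cols[1]]]
  b <- cohort[[cols[2]]]
  swap <- runif(length(a)) < 0.5
  x_out <- ifelse(swap, b, a)    # member whose quantiles are reported
  x_cond <- ifelse(swap, a, b)   # member that is binned
  qt <- tibble(bin_left = floor(x_cond / bin_width) * bin_width, x = x_out) |>
    dplyr::summarise(
      n = dplyr::n(),
      q = list(quantile(.data$x, quantile_probs, names = FALSE, type = 7)),
      .by = "bin_left") |>
    dplyr::filter(.data$n > min_count) |>
    dplyr::arrange(.data$bin_left) |>
    tidyr::unnest_wider("q", names_sep = "") |>
    rlang::set_names(c("bin_left", "n", quantile_cols))
  structure(qt, class = c("gw_quantile_table", class(qt)),
            bin_width = bin_width, empty = nrow(qt) == 0)
}

#' Square-root-weighted sum-of-squares cost between quantile tables
#'
#' For every retained bin of the reference table, the squared deviations
#' of the five simulated quantiles from the reference quantiles are
#' summed and weighted by the square root of the reference bin count
#' (sample quantiles have standard errors shrinking with `sqrt(n)`):
#' `cost = sum_bins sqrt(n_ref) * sum_q (sim_q - ref_q)^2`.
#' A reference bin with no simulated counterpart contributes its weight
#' times a fixed penalty deviation on every quantile.
#'
#' @param sim,ref Quantile tables from [conditional_quantile_table()];
#'   `ref` supplies both the bin set and the weights.
#' @param penalty_dev Deviation (phenotype units) imputed per quantile
#'   for a reference bin missing from `sim`.
#' @return A single non-negative number (0 when `sim` equals `ref` on the
#'   reference bins).
#' @export
weighted_ss_cost <- function(sim, ref, penalty_dev = 25) {
  stopifnot(is.data.frame(sim), is.data.frame(ref))
  if (!nrow(ref)) abort("reference table has no retained bins")
  m <- match(ref$bin_left, sim$bin_left)
  dev2 <- vapply(seq_len(nrow(ref)), function(i) {
    if (is.na(m[i])) return(5 * penalty_dev^2)
    sum((as.numeric(sim[m[i], quantile_cols]) -
         as.numeric(ref[i, quantile_cols]))^2)
  }, numeric(1))
  if (anyNA(m)) {
    warn(sprintf("%d reference bin(s) missing from the simulated table; penalized",
                 sum(is.na(m))), class = "gw_missing_bins")
  }
  sum(sqrt(ref$n) * dev2)
}

#' Evaluate a model's fit cost against a reference quantile table
#'
#' Simulates `replicates` independent pair cohorts under `spec`, computes
#' each cohort's conditional quantile table with the reference's bin
#' width, and scores it with [weighted_ss_cost()].
#'
#' @param spec A [model_spec()].
#' @param ref Reference `gw_quantile_table` (its bin counts are the cost
#'   weights).
#' @param n_pairs Pairs per simulated cohort; defaults to the reference's
#'   total pair count so simulated bins rarely go missing.
#' @param replicates Number of independent cohorts (`R >= 1`).
#' @param base,engine,seed Passed to [simulate_pair_cohort()].
#' @param min_count Retention threshold for the simulated tables.
#' @return A `gw_cost_eval`: list with `mean_cost`, `sd_cost` (`NA` when
#'   `replicates = 1`), `costs` (per-replicate tibble), `spec_name`,
#'   `n_pairs`, `replicates`.
#' @export
evaluate_model <- function(spec, ref, n_pairs = sum(ref$n), replicates = 1,
                           base = default_baseline(),
                           engine = c("auto", "analytic", "iterative"),
                           min_count = 100, seed = NULL) {
  stopifnot(replicates >= 1)
  local_seed(seed)
  bw <- attr(ref, "bin_width") %||% 7
  costs <- purrr::map_dbl(seq_len(replicates), function(r) {
    cohort <- simulate_pair_cohort(spec, n_pairs, base = base, engine = engine)
    sim <- conditional_quantile_table(cohort, bin_width = bw,
                                      min_count = min_count)
    withCallingHandlers(
      weighted_ss_cost(sim, ref),
      gw_missing_bins = function(w) rlang::cnd_muffle(w))
  })
  structure(list(mean_cost = mean(costs),
                 sd_cost = if (replicates > 1) sd(costs) else NA_real_,
                 costs = tibble(replicate = seq_len(replicates), cost = costs),
                 spec_name = spec$name, n_pairs = n_pairs,
                 replicates = replicates),
            class = "gw_cost_eval")
}

#' @export
print.gw_cost_eval <- function(x, ...) {
  cat(sprintf("<gw_cost_eval> %s: mean cost %.1f (SD %s) over %d replicate(s) of %d pairs\n",
              x$spec_name, x$mean_cost,
              if (is.na(x$sd_cost)) "-" else sprintf("%.1f", x$sd_cost),
              x$replicates, x$n_pairs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gw_cost_eval <- function(x, ...) x$costs

#' @exportS3Method generics::glance
glance.gw_cost_eval <- function(x, ...) {
  tibble(spec = x$spec_name, mean_cost = x$mean_cost, sd_cost = x$sd_cost,
         replicates = x$replicates, n_pairs = x$n_pairs)
}

#' Nonuniformity of the conditional quantile pattern
#'
#' Slope of each quantile series against bin index, fitted by least
#' squares weighted by the square root of the bin count (sample quantiles
#' in a sparse, barely-retained tail bin are far noisier than in the
#' central bins, and the same `sqrt(n)` weighting underlies the fit
#' cost); returns `slope(q05) - slope(q95)` in phenotype units per bin.
#' Positive values mean the lower quantiles climb faster than the upper
#' ones — the signature of time-variant shared effects — while parallel
#' quantile series (e.g. a polygenic additive trait) give values near 0.
#'
#' @param qt A `gw_quantile_table` with at least 3 bins.
#' @return A single number (units per bin).
#' @export
quantile_slope_contrast <- function(qt) {
  stopifnot(is.data.frame(qt))
  if (nrow(qt) < 3) abort("need at least 3 retained bins")
  idx <- qt$bin_left / (attr(qt, "bin_width") %||%
                          (min(diff(sort(unique(qt$bin_left))))))
  w <- sqrt(qt$n)
  wmean <- function(v) sum(w * v) / sum(w)
  slope <- function(y) sum(w * (idx - wmean(idx)) * (y - wmean(y))) /
    sum(w * (idx - wmean(idx))^2)
  slope(qt$q05) - slope(qt$q95)
}

#' Threshold for calling a quantile pattern uniform
#'
#' Absolute [quantile_slope_contrast()] values below this (phenotype
#' units per bin) are treated as a uniform, parallel-quantile pattern, as
#' expected for a highly polygenic additive trait.
#' @export
uniformity_threshold <- 0.25

#' Write / read a quantile table as TSV
#'
#' @param qt A `gw_quantile_table`.
#' @param path File path.
#' @return `path` invisibly (`write`); a `gw_quantile_table` (`read`).
#' @export
write_quantile_table <- function(qt, path) {
  readr::write_tsv(as_tibble(qt), path)
  invisible(path)
}

#' @rdname write_quantile_table
#' @param bin_width Bin width to record on the read table (inferred from
#'   edge spacing when `NULL`).
#' @export
read_quantile_table <- function(path, bin_width = NULL) {
  qt <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("bin_left", "n", quantile_cols)
  if (!all(need %in% names(qt))) {
    abort(sprintf("malformed quantile table: expected columns %s",
                  paste(need, collapse = ", ")))
  }
  bw <- bin_width %||% if (nrow(qt) > 1) min(diff(sort(qt$bin_left))) else 7
  structure(qt[need], class = c("gw_quantile_table", class(qt)),
            bin_width = bw, empty = nrow(qt) == 0)
}
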