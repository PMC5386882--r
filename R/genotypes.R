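#' Joint genotype distribution of a full-sibling pair under Hardy-Weinberg
#'
#' Closed-form 3x3 joint probabilities of the minor-allele dosages (0/1/2)
#' of two full siblings at a diallelic locus, assuming Hardy-Weinberg
#' equilibrium in the parental population and Mendelian segregation.
#' With minor allele frequency `p` and `q = 1 - p`, the diagonal entries
#' are q^2(q + p^2/4), pq(1 + pq) and p^2(p + q^2/4); see the returned
#' matrix for the full set.
#'
#' @param p Minor allele frequency, a single number in \[0, 0.5\]. `p = 0`
#'   is accepted as the degenerate monomorphic case.
#' @return A 3x3 numeric matrix with dimnames `0:2` x `0:2`; entry
#'   `[i, j]` is `P(sib1 = i - 1, sib2 = j - 1)`. Symmetric, sums to 1,
#'   and both marginals equal the Hardy-Weinberg genotype frequencies
#'   `(q^2, 2pq, p^2)`.
#' @examples
#' sibling_joint_table(0.25)
#' # additive-coded sibling genotype correlation is exactly 1/2:
#' P <- sibling_joint_table(0.3)
#' g <- 0:2
#' m <- sum(g * rowSums(P))
#' (sum(outer(g, g) * P) - m^2) / (sum(g^2 * rowSums(P)) - m^2)
#' @export
sibling_joint_table <- function(p) {
  assert_scalar_prob(p, "p", max = 0.5)
  q <- 1 - p
  P <- matrix(c(
    q^2 * (q + p^2 / 4), p * q^2 * (1 - p / 2), (p * q / 2)^2,
    p * q^2 * (1 - p / 2), p * q * (1 + p * q), p^2 * q * (1 - q / 2),
    (p * q / 2)^2, p^2 * q * (1 - q / 2), p^2 * (p + q^2 / 4)
  ), nrow = 3, byrow = TRUE, dimnames = list(0:2, 0:2))
  P
}

#' Draw genotype pairs for full siblings
#'
#' Draws i.i.d. sibling genotype pairs from [sibling_joint_table()] by a
#' single categorical draw over the nine joint cells.
#'
#' @inheritParams sibling_joint_table
#' @param n_pairs Number of sibling pairs to draw (>= 1).
#' @param seed Optional integer seed for a self-contained draw; `NULL`
#'   (default) uses the current RNG stream.
#' @return A tibble with integer columns `g1` and `g2` (minor-allele
#'   dosages 0/1/2), one row per pair.
#' @export
draw_sibling_genotype_pairs <- function(p, n_pairs, seed = NULL) {
  stopifnot(n_pairs >= 1)
  local_seed(seed)
  P <- sibling_joint_table(p)
  cell <- sample.int(9L, n_pairs, replace = TRUE, prob = as.vector(P))
  tibble(g1 = as.integer((cell - 1L) %% 3L),
         g2 = as.integer((cell - 1L) %/% 3L))
}

#' Draw genotypes for unrelated individuals
#'
#' Minor-allele dosages for independent individuals under Hardy-Weinberg
#' equilibrium, i.e. Binomial(2, p) per individual.
#'
#' @inheritParams draw_sibling_genotype_pairs
#' @param n_ind Number of individuals (>= 1).
#' @return Integer vector of dosages in `{0, 1, 2}`.
#' @export
draw_independent_genotypes <- function(p, n_ind, seed = NULL) {
  stopifnot(n_ind >= 1)
  assert_scalar_prob(p, "p", max = 0.5)
  local_seed(seed)
  rbinom(n_ind, 2L, p)
}

#' Write a genotype matrix as delimited text
#'
#' @param geno A data frame or matrix of 0/1/2 dosages, columns named per
#'   locus.
#' @param path Output file path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  readr::write_tsv(as_tibble(as.data.frame(geno)), path)
  invisible(path)
}
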