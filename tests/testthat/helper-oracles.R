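# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Exhaustive Mendelian enumeration of the sibling-pair genotype joint
# distribution: sum over the 9 ordered parental genotype pairs (HWE
# frequencies) of the product of the two siblings' independent offspring
# distributions given those parents.
enumerate_sibling_joint <- function(p) {
  q <- 1 - p
  hwe <- c(q^2, 2 * p * q, p^2)
  transmit <- function(g) c(1 - g / 2, g / 2)    # P(allele = 0/1 | dosage g)
  joint <- matrix(0, 3, 3)
  for (gf in 0:2) {
    for (gm in 0:2) {
      tf <- transmit(gf)
      tm <- transmit(gm)
      off <- c(tf[1] * tm[1],
               tf[1] * tm[2] + tf[2] * tm[1],
               tf[2] * tm[2])
      joint <- joint + hwe[gf + 1] * hwe[gm + 1] * outer(off, off)
    }
  }
  joint
}

# Closed-form two-sided t test for the slope of y ~ x (textbook formulas).
slope_t_pvalue <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  list(estimate = b, std.error = se,
       p = 2 * pt(-abs(b / se), df = n - 2))
}

# Efron partial likelihood for a single covariate with tied event times,
# maximized by damped Newton iteration from scratch.
efron_loglik <- function(beta, time, x) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (tt in unique(time)) {
    D <- which(time == tt)            # tied events at tt
    R <- which(time >= tt)            # risk set
    d <- length(D)
    sumR <- sum(w[R]); sumD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - l / d * sumD)
    }
  }
  ll
}

# Exact gradient and Hessian of the Efron partial log-likelihood.
efron_derivs <- function(beta, time, x) {
  w <- exp(beta * x)
  g <- 0
  H <- 0
  for (tt in unique(time)) {
    D <- which(time == tt)
    R <- which(time >= tt)
    d <- length(D)
    s0R <- sum(w[R]);        s0D <- sum(w[D])
    s1R <- sum(w[R] * x[R]); s1D <- sum(w[D] * x[D])
    s2R <- sum(w[R] * x[R]^2); s2D <- sum(w[D] * x[D]^2)
    g <- g + sum(x[D])
    for (l in seq_len(d) - 1) {
      den <- s0R - l / d * s0D
      m1 <- (s1R - l / d * s1D) / den
      m2 <- (s2R - l / d * s2D) / den
      g <- g - m1
      H <- H - (m2 - m1^2)
    }
  }
  list(grad = g, hess = H)
}

efron_newton <- function(time, x, tol = 1e-12) {
  beta <- 0
  for (it in 1:200) {
    d <- efron_derivs(beta, time, x)
    step <- d$grad / d$hess
    beta <- beta - step
    if (abs(step) < tol) break
  }
  H <- efron_derivs(beta, time, x)$hess
  se <- sqrt(-1 / H)
  z <- beta / se
  list(beta = beta, se = se, p = 2 * pnorm(-abs(z)))
}

# Closed-form Gompertz survival under a constant multiplier, independent of
# the package's survival_baseline().
gompertz_surv <- function(t, rate, shape, mult = 1) {
  exp(-mult * rate / shape * (exp(shape * t) - 1))
}

# Small deterministic pair cohort where both members share one value, so bin
# membership is unambiguous.
degenerate_cohort <- function(values, times) {
  v <- rep(values, times)
  tibble::tibble(ga1 = v, ga2 = v)
}
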