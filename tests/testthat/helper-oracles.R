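# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms and fast paths: numerical likelihood maximization,
# naive table enumeration, and direct probability sums.

# random table with every cell >= 1 (interior MLEs), group sizes in m_range
random_positive_table <- function(g, m_range = 5:50) {
  repeat {
    mi <- sample(m_range, g, replace = TRUE)
    pi <- runif(g, 0.25, 0.75)
    gamma <- runif(1, max(gamma_lower_bound(pi)) + 0.05, 0.9)
    tabs <- simulate_tables(pi, gamma, mi, R = 1)
    m <- tabs[, , 1]
    if (g == 1) m <- matrix(m, nrow = 3)
    if (all(m >= 1)) return(bilateral_table(m))
  }
}

# arbitrary random table (boundaries allowed)
random_table <- function(g, m_range = 2:12) {
  mi <- sample(m_range, g, replace = TRUE)
  m <- vapply(mi, function(m1) {
    as.integer(stats::rmultinom(1, m1, prob = runif(3)))
  }, integer(3))
  bilateral_table(m)
}

# numerical maximizer of the trinomial log-likelihood on the transformed
# (unconstrained) scale; the closed-form MLEs never enter
.from_x <- function(x, g, common_gamma) {
  pi <- stats::plogis(x[seq_len(g)])
  if (common_gamma) {
    lb <- max(gamma_lower_bound(pi))
    list(pi = pi, gamma = lb + (1 - lb) * stats::plogis(x[g + 1L]))
  } else {
    lb <- gamma_lower_bound(pi)
    list(pi = pi, gamma = lb + (1 - lb) * stats::plogis(x[(g + 1L):(2L * g)]))
  }
}

numeric_mle <- function(table, common_gamma = FALSE) {
  g <- n_groups(table)
  polish <- function(start, obj) {
    res <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 3000))
    stats::optim(res$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 3000))
  }
  if (common_gamma) {
    obj <- function(x) {
      par <- .from_x(x, g, TRUE)
      -dallal_loglik(table, par$pi, par$gamma)
    }
    best <- polish(rep(0, g + 1L), obj)
    alt <- polish(rep(0.5, g + 1L), obj)
    if (alt$value < best$value) best <- alt
    par <- .from_x(best$par, g, TRUE)
    return(list(pi = par$pi, gamma = par$gamma, loglik = -best$value))
  }
  # groups are likelihood-independent under H1: maximize each separately
  m <- unclass(table)
  pi <- gamma <- numeric(g)
  ll <- 0
  for (i in seq_len(g)) {
    tab_i <- bilateral_table(m[, i])
    obj <- function(x) {
      par <- .from_x(x, 1L, TRUE)
      -dallal_loglik(tab_i, par$pi, par$gamma)
    }
    best <- polish(c(0, 0), obj)
    alt <- polish(c(0.7, -0.7), obj)
    if (alt$value < best$value) best <- alt
    par <- .from_x(best$par, 1L, TRUE)
    pi[i] <- par$pi; gamma[i] <- par$gamma
    ll <- ll - best$value
  }
  list(pi = pi, gamma = gamma, loglik = ll)
}

# naive conditional enumeration: recursive distribution of the response
# totals over groups, probabilities from factorial() directly
naive_conditional <- function(observed) {
  observed <- as_bilateral_table(observed)
  mi <- group_sizes(observed)
  S <- response_totals(observed)
  g <- length(mi)
  out <- list()
  rec <- function(i, s1, s2, acc) {
    if (i > g) {
      if (s1 == 0 && s2 == 0) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (m1 in 0:min(mi[i], s1)) {
      for (m2 in 0:min(mi[i] - m1, s2)) {
        rec(i + 1L, s1 - m1, s2 - m2,
            cbind(acc, c(mi[i] - m1 - m2, m1, m2)))
      }
    }
  }
  rec(1L, S[2], S[3], NULL)
  coef <- vapply(out, function(m) {
    prod(factorial(colSums(m))) / prod(factorial(m))
  }, numeric(1))
  N <- sum(mi)
  denom <- factorial(N) / prod(factorial(S))
  list(tables = out, prob = coef / denom)
}

# naive conditional p-value: direct sum over the naive space
naive_conditional_pvalue <- function(observed, statistic) {
  sp <- naive_conditional(observed)
  tobs <- dallaltest:::asymptotic_stat(observed, statistic)$value
  tv <- vapply(sp$tables, function(m) {
    dallaltest:::asymptotic_stat(bilateral_table(m), statistic)$value
  }, numeric(1))
  sum(sp$prob[tv >= tobs - 1e-9])
}
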