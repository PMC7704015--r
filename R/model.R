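#' Cell probabilities under Dallal's model
#'
#' Dallal's model for bilateral binary data assumes that the conditional
#' probability of response at one organ given response at the other, `gamma`,
#' does not depend on the marginal response rate `pi`. The per-patient
#' probabilities of 0, 1 or 2 responding organs are then
#' \deqn{p_0 = 1 - (2 - \gamma)\pi, \quad p_1 = 2\pi(1 - \gamma), \quad
#'       p_2 = \pi\gamma.}
#' These are a valid trinomial law exactly when
#' \eqn{\max\{0,\, 1 - 1/(2\pi),\, 2 - 1/\pi\} \le \gamma \le 1}.
#'
#' @param pi Marginal response probabilities, in `[0, 1]`. Recycled against
#'   `gamma`.
#' @param gamma Conditional dependence parameters. `gamma = pi` is
#'   independence between the two organs; `gamma = 1` complete dependence.
#'
#' @return A tibble with one row per group and columns `pi`, `gamma`, `p0`,
#'   `p1`, `p2`.
#'
#' @examples
#' dallal_probs(0.5, 0.5)
#' dallal_probs(pi = c(0.2, 0.3), gamma = 0.1)
#' @export
dallal_probs <- function(pi, gamma) {
  n <- max(length(pi), length(gamma))
  pi <- rep_len(pi, n)
  gamma <- rep_len(gamma, n)
  check_dallal_params(pi, gamma)
  tibble::tibble(
    pi = pi, gamma = gamma,
    p0 = 1 - (2 - gamma) * pi,
    p1 = 2 * pi * (1 - gamma),
    p2 = pi * gamma
  )
}

#' Lower bound of the dependence parameter
#'
#' The smallest `gamma` compatible with a given response rate `pi`:
#' `max(0, 1 - 1/(2*pi), 2 - 1/pi)`. Below it either `p1` exceeds 1 or `p0`
#' goes negative. For `pi = 0` the bound is 0 (gamma is then unidentified).
#'
#' @param pi Response probabilities in `[0, 1]`.
#' @return The per-element lower bound for `gamma`.
#' @export
gamma_lower_bound <- function(pi) {
  b <- numeric(length(pi))
  pos <- pi > 0
  b[pos] <- pmax(0, 1 - 1 / (2 * pi[pos]), 2 - 1 / pi[pos])
  b
}

# internal: validate (pi, gamma), naming the violated bound
check_dallal_params <- function(pi, gamma) {
  if (any(pi < -1e-12 | pi > 1 + 1e-12)) {
    stop("pi must lie in [0, 1]", call. = FALSE)
  }
  if (any(gamma > 1 + 1e-12)) {
    stop("gamma must satisfy gamma <= 1 (bound violated at gamma = ",
         format(max(gamma)), ")", call. = FALSE)
  }
  lb <- gamma_lower_bound(pi)
  bad <- which(gamma < lb - 1e-12)
  if (length(bad)) {
    i <- bad[1]
    stop("gamma = ", format(gamma[i]), " is below its lower bound ",
         format(lb[i]), " = max{0, 1 - 1/(2*pi), 2 - 1/pi} at pi = ",
         format(pi[i]), call. = FALSE)
  }
  invisible(TRUE)
}

# x * log(x) with the 0 * log(0) = 0 convention
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# m * log(p): 0 when m = 0, -Inf when p <= 0 and m > 0
mlogp <- function(m, p) {
  out <- numeric(length(m))
  pos <- m > 0
  out[pos] <- ifelse(p[pos] > 0, m[pos] * log(p[pos]), -Inf)
  out
}

#' Log-likelihood of a bilateral table under Dallal's model
#'
#' Each group's count triple is trinomial with the cell probabilities of
#' [dallal_probs()]. The returned value includes the multinomial
#' log-coefficient, so log-likelihoods are comparable across
#' parameterisations; test statistics use differences, in which it cancels.
#' `0 * log(0)` is taken as 0; a positive count on a zero-probability cell
#' yields `-Inf` rather than an error (the maximization-type exact test
#' probes the boundary).
#'
#' @param table A [bilateral_table()].
#' @param pi Length-`g` vector of response probabilities.
#' @param gamma Length-`g` vector of dependence parameters, or a single
#'   common value (the null-hypothesis form).
#' @return The log-likelihood (natural log).
#' @examples
#' tab <- bilateral_table(c(15, 6, 7, 7, 5, 9))
#' fit <- mle_unconstrained(tab)
#' dallal_loglik(tab, fit$pi, fit$gamma)
#' @export
dallal_loglik <- function(table, pi, gamma) {
  table <- as_bilateral_table(table)
  g <- n_groups(table)
  if (length(pi) != g) {
    stop("pi has length ", length(pi), " but the table has ", g, " groups",
         call. = FALSE)
  }
  if (!length(gamma) %in% c(1L, g)) {
    stop("gamma must have length 1 or ", g, call. = FALSE)
  }
  gamma <- rep_len(gamma, g)
  check_dallal_params(pi, gamma)
  m <- unclass(table)
  sum(mlogp(m[1, ], 1 - (2 - gamma) * pi)) +
    sum(mlogp(m[2, ], 2 * pi * (1 - gamma))) +
    sum(mlogp(m[3, ], pi * gamma)) + multinomial_logc(table)
}

# log of the product of per-group multinomial coefficients
multinomial_logc <- function(table) {
  m <- unclass(as_bilateral_table(table))
  sum(lfactorial(colSums(m))) - sum(lfactorial(m))
}

#' Maximum likelihood estimates under Dallal's model
#'
#' Closed-form MLEs of the response rates and dependence parameters.
#' `mle_unconstrained()` fits group-specific `(pi_i, gamma_i)`:
#' \deqn{\hat\pi_i = (m_{1i} + 2 m_{2i}) / (2 m_i), \quad
#'       \hat\gamma_i = 2 m_{2i} / (m_{1i} + 2 m_{2i}).}
#' `mle_constrained()` fits a common `gamma` (the null hypothesis of the
#' homogeneity tests):
#' \deqn{\tilde\gamma = 2 S_2 / (S_1 + 2 S_2), \quad
#'       \tilde\pi_i = (m_{1i} + m_{2i})(S_1 + 2 S_2) / (2 m_i (S_1 + S_2)).}
#' A group with no responding organs (`m_{1i} + 2 m_{2i} = 0`) has
#' `pi_hat = 0` and an unidentified `gamma_hat`, reported as `NA` with
#' `gamma_defined = FALSE`; likewise `gamma_tilde` when `S_1 = S_2 = 0`.
#'
#' @param table A [bilateral_table()] (or coercible).
#' @return A `dallal_mle` object: a list with elements `pi`, `gamma`,
#'   `gamma_defined`, `constrained`, `loglik` and the input `table`.
#'   [tidy()][generics::tidy] gives per-group estimates,
#'   [glance()][generics::glance] the fit summary.
#' @examples
#' rp <- dallal_fixture("rp_table2")
#' mle_unconstrained(rp)
#' mle_constrained(rp)
#' @export
mle_unconstrained <- function(table) {
  table <- as_bilateral_table(table)
  m <- unclass(table)
  mi <- colSums(m)
  if (any(mi < 1L)) stop("every group must contain at least one patient",
                         call. = FALSE)
  num <- m[2, ] + 2 * m[3, ]
  pi_hat <- num / (2 * mi)
  gamma_hat <- ifelse(num > 0, 2 * m[3, ] / num, NA_real_)
  defined <- num > 0
  # unidentified gammas contribute nothing to the likelihood (pi_hat = 0)
  ll <- dallal_loglik(table, pi_hat, ifelse(defined, gamma_hat, 1))
  new_dallal_mle(table, pi_hat, gamma_hat, defined, constrained = FALSE,
                 loglik = ll)
}

#' @rdname mle_unconstrained
#' @export
mle_constrained <- function(table) {
  table <- as_bilateral_table(table)
  m <- unclass(table)
  mi <- colSums(m)
  if (any(mi < 1L)) stop("every group must contain at least one patient",
                         call. = FALSE)
  S <- rowSums(m)
  if (S[2] + S[3] > 0) {
    gamma_t <- 2 * S[3] / (S[2] + 2 * S[3])
    pi_t <- (m[2, ] + m[3, ]) * (S[2] + 2 * S[3]) / (2 * mi * (S[2] + S[3]))
    defined <- TRUE
    ll <- dallal_loglik(table, pi_t, gamma_t)
  } else {
    gamma_t <- NA_real_
    pi_t <- rep(0, ncol(m))
    defined <- FALSE
    ll <- dallal_loglik(table, pi_t, 1)
  }
  new_dallal_mle(table, pi_t, gamma_t, defined, constrained = TRUE,
                 loglik = ll)
}

new_dallal_mle <- function(table, pi, gamma, gamma_defined, constrained,
                           loglik) {
  structure(
    list(pi = unname(pi), gamma = unname(gamma),
         gamma_defined = unname(gamma_defined),
         constrained = constrained, loglik = unname(loglik), table = table),
    class = "dallal_mle"
  )
}

#' @export
print.dallal_mle <- function(x, digits = 4, ...) {
  cat(if (x$constrained) "Constrained (common-gamma) "
      else "Unconstrained ", "MLEs under Dallal's model\n", sep = "")
  print(tidy(x), n = Inf)
  cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dallal_mle <- function(x, ...) {
  tibble::tibble(
    group = colnames(x$table),
    pi = x$pi,
    gamma = rep_len(x$gamma, n_groups(x$table)),
    gamma_defined = rep_len(x$gamma_defined, n_groups(x$table))
  )
}

#' @exportS3Method generics::glance
glance.dallal_mle <- function(x, ...) {
  tibble::tibble(
    constrained = x$constrained,
    loglik = x$loglik,
    n_groups = n_groups(x$table),
    n = sum(group_sizes(x$table)),
    df = if (x$constrained) n_groups(x$table) + 1L else 2L * n_groups(x$table)
  )
}
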