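#' Asymptotic tests of dependence homogeneity
#'
#' Tests `H0: gamma_1 = ... = gamma_g` against a difference in at least one
#' pair, using one or all of three large-sample statistics, each referred to
#' a chi-square distribution with `g - 1` degrees of freedom:
#'
#' * **lrt** — the likelihood ratio statistic, twice the log-likelihood gap
#'   between the unconstrained and common-gamma fits. Its simplified closed
#'   form is
#'   \deqn{T_L = 2\sum_i \left[ m_{1i}\ln\frac{m_{1i}}{S_1} +
#'     m_{2i}\ln\frac{m_{2i}}{S_2} +
#'     (m_{1i}+m_{2i})\ln\frac{S_1+S_2}{m_{1i}+m_{2i}} \right].}
#' * **score** — the score (Rao) statistic, evaluated at the constrained MLEs:
#'   \deqn{T_{SC} = \sum_i \frac{(S_1 m_{2i} - S_2 m_{1i})^2}
#'     {S_1 S_2 (m_{1i} + m_{2i})}.}
#' * **wald** — the Wald-type statistic \eqn{d^\top A^{-1} d} on the contrast
#'   vector `d` of successive `gamma_hat` differences, where `A` is the
#'   symmetric tridiagonal matrix with diagonal \eqn{\hat a_i + \hat a_{i+1}}
#'   and off-diagonal \eqn{-\hat a_{i+1}}, built from the asymptotic variances
#'   \eqn{\hat a_i = 4 m_{1i} m_{2i}(m_{1i}+m_{2i})/(m_{1i}+2m_{2i})^4}.
#'   The quadratic form is evaluated by a linear solve, which is exact for
#'   any `g`.
#'
#' Degenerate tables get deterministic conventions so that every table of an
#' enumerated space has a defined value: `T_L` and `T_SC` are 0 when
#' `S_1 = 0` or `S_2 = 0` (all groups then share a boundary `gamma_hat`);
#' a group with no responders is dropped from the Wald contrast (degrees of
#' freedom reduced, flagged); a singular `A` with a nonzero contrast gives
#' `Inf` (maximal evidence), an all-zero contrast gives 0.
#'
#' @param table A [bilateral_table()] or anything coercible (matrix, data
#'   frame, flat count vector).
#' @param method `"lrt"`, `"score"`, `"wald"`, or `"all"` (default).
#' @param alpha Nominal level used only for the `reject` column.
#' @return A tibble with one row per statistic: `method`, `statistic`, `df`,
#'   `p.value`, `reject`, `flags` (comma-separated diagnostics, `""` if none).
#' @examples
#' rp <- dallal_fixture("rp_table2")
#' dallal_test(rp)
#' @export
dallal_test <- function(table, method = c("all", "lrt", "score", "wald"),
                        alpha = 0.05) {
  method <- match.arg(method)
  table <- check_testable(table)
  methods <- if (method == "all") c("lrt", "score", "wald") else method
  rows <- lapply(methods, function(me) {
    s <- asymptotic_stat(table, me)
    tibble::tibble(
      method = me,
      statistic = s$value,
      df = s$df,
      p.value = asymptotic_pvalue(s$value, s$df),
      flags = paste(s$flags, collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$reject <- out$p.value < alpha
  out[, c("method", "statistic", "df", "p.value", "reject", "flags")]
}

#' Upper-tail chi-square p-value
#'
#' The asymptotic p-value of a homogeneity statistic: `P(chisq_df >= stat)`.
#'
#' @param statistic Nonnegative statistic value (may be `Inf`).
#' @param df Degrees of freedom (`g - 1`, possibly reduced).
#' @return The upper-tail probability.
#' @examples
#' asymptotic_pvalue(4.4569, 3)
#' @export
asymptotic_pvalue <- function(statistic, df) {
  if (any(statistic < 0)) stop("statistic must be nonnegative", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

# internal: one statistic on one table, returning value/df/flags
asymptotic_stat <- function(table, method = c("lrt", "score", "wald")) {
  method <- match.arg(method)
  m <- unclass(as_bilateral_table(table))
  switch(method,
    lrt = lrt_stat(m),
    score = score_stat(m),
    wald = wald_stat(m)
  )
}

lrt_stat <- function(m) {
  g <- ncol(m)
  m1 <- m[2, ]; m2 <- m[3, ]
  S1 <- sum(m1); S2 <- sum(m2)
  flags <- character()
  if (S1 == 0 || S2 == 0) {
    # every gamma_hat sits on the same boundary; no heterogeneity evidence
    return(list(value = 0, df = g - 1L, flags = "degenerate-margin"))
  }
  val <- 2 * sum(xlogx(m1) - m1 * log(S1) + xlogx(m2) - m2 * log(S2) +
                 (m1 + m2) * log(S1 + S2) - xlogx(m1 + m2))
  list(value = max(val, 0), df = g - 1L, flags = flags)
}

score_stat <- function(m) {
  g <- ncol(m)
  m1 <- m[2, ]; m2 <- m[3, ]
  S1 <- sum(m1); S2 <- sum(m2)
  if (S1 == 0 || S2 == 0) {
    return(list(value = 0, df = g - 1L, flags = "degenerate-margin"))
  }
  denom <- m1 + m2
  term <- ifelse(denom > 0, (S1 * m2 - S2 * m1)^2 / (S1 * S2 * denom), 0)
  list(value = sum(term), df = g - 1L, flags = character())
}

wald_stat <- function(m) {
  g <- ncol(m)
  m1 <- m[2, ]; m2 <- m[3, ]
  flags <- character()
  defined <- (m1 + 2 * m2) > 0
  if (any(!defined)) flags <- c(flags, "dropped-groups")
  k <- sum(defined)
  if (k < 2) {
    # at most one informative gamma_hat: no contrast to test
    return(list(value = 0, df = max(k - 1L, 1L),
                flags = c(flags, "undefined-statistic")))
  }
  m1 <- m1[defined]; m2 <- m2[defined]
  gam <- 2 * m2 / (m1 + 2 * m2)
  a <- 4 * m1 * m2 * (m1 + m2) / (m1 + 2 * m2)^4
  d <- gam[-k] - gam[-1]
  if (all(d == 0)) {
    return(list(value = 0, df = k - 1L, flags = flags))
  }
  if (any(a == 0)) {
    # boundary gamma_hat with zero estimated variance but a nonzero contrast
    return(list(value = Inf, df = k - 1L, flags = c(flags, "boundary-MLE")))
  }
  A <- diag(a[-k] + a[-1], nrow = k - 1L)
  if (k > 2) {
    off <- cbind(seq_len(k - 2L), seq_len(k - 2L) + 1L)
    A[off] <- A[off[, 2:1, drop = FALSE]] <- -a[2:(k - 1L)]
  }
  val <- drop(crossprod(d, solve(A, d)))
  list(value = max(val, 0), df = k - 1L, flags = flags)
}
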