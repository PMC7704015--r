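#' Enumerate the space of bilateral tables
#'
#' `enumerate_tables()` lists every 3 x g count table with the given group
#' sizes: group `i` contributes the \eqn{\binom{m_i + 2}{2}} compositions of
#' `m_i` into `(m0, m1, m2)`, and the space is their Cartesian product, in
#' deterministic lexicographic order. `conditional_space()` restricts the
#' space of an observed table to members sharing *both* margins (group sizes
#' and response totals) and attaches each member's probability under the
#' induced multivariate hypergeometric law
#' \deqn{P(\mathbf m) = \frac{\prod_i m_i!/(m_{0i}! m_{1i}! m_{2i}!)}
#'       {N!/(S_0! S_1! S_2!)},}
#' which sums to 1 over the space.
#'
#' @param group_sizes Nonnegative integer vector of group sizes `m_i`.
#' @param cap Refuse to enumerate spaces larger than this many tables
#'   (default `1e7`); the error reports the exact combinatorial count.
#' @return A `table_space` object; see [space_size()], [space_statistics()]
#'   and [as_tibble()] for access.
#' @examples
#' sp <- enumerate_tables(c(10, 10))
#' space_size(sp)                       # 4356 tables
#' sp2 <- conditional_space(bilateral_table(c(1, 0, 1, 0, 2, 0)))
#' sum(sp2$prob)                        # exactly 1
#' @export
enumerate_tables <- function(group_sizes, cap = 1e7) {
  if (any(group_sizes < 0) || any(group_sizes != round(group_sizes))) {
    stop("group sizes must be nonnegative integers", call. = FALSE)
  }
  group_sizes <- as.integer(group_sizes)
  n_each <- choose(group_sizes + 2, 2)
  total <- prod(n_each)
  if (total > cap) {
    stop("table space has ", format(total, big.mark = ","),
         " members, above the cap of ", format(cap, big.mark = ","),
         "; consider the conditional method or raise `cap`", call. = FALSE)
  }
  comps <- lapply(group_sizes, compositions3)
  # lexicographic over groups: group 1 outermost, within-group order as in
  # compositions3 (m0 ascending, then m1 ascending)
  g <- length(group_sizes)
  idx <- as.matrix(rev(expand.grid(rev(lapply(n_each, seq_len)))))
  dimnames(idx) <- NULL
  structure(
    list(group_sizes = group_sizes, comps = comps, idx = idx,
         conditional = FALSE, response_totals = NULL, prob = NULL),
    class = "table_space"
  )
}

# all (m0, m1, m2) with m0 + m1 + m2 = m, ordered by (m0, m1)
compositions3 <- function(m) {
  m0 <- rep(0:m, times = (m:0) + 1L)
  m1 <- unlist(lapply(0:m, function(k) 0:(m - k)))
  cbind(m0 = m0, m1 = m1, m2 = m - m0 - m1)
}

#' @rdname enumerate_tables
#' @param observed A [bilateral_table()]: its two margins define the
#'   conditioning set.
#' @export
conditional_space <- function(observed, cap = 1e7) {
  observed <- as_bilateral_table(observed)
  sp <- enumerate_tables(group_sizes(observed), cap = cap)
  S <- response_totals(observed)
  M0 <- member_counts(sp, 1L); M1 <- member_counts(sp, 2L)
  keep <- rowSums(M0) == S[1] & rowSums(M1) == S[2]
  sp$idx <- sp$idx[keep, , drop = FALSE]
  sp$conditional <- TRUE
  sp$response_totals <- S
  # multivariate hypergeometric: product of multinomial coefficients over
  # the fixed-margin normalizer
  lognum <- member_logcoef(sp)
  N <- sum(sp$group_sizes)
  logden <- lfactorial(N) - sum(lfactorial(S))
  sp$prob <- exp(lognum - logden)
  sp
}

#' Table-space accessors
#'
#' @param space A `table_space` from [enumerate_tables()] or
#'   [conditional_space()].
#' @return `space_size()`: the number of member tables. `space_statistics()`:
#'   the numeric vector of a homogeneity statistic evaluated on every member
#'   (degenerate-table conventions of [dallal_test()] apply, so every member
#'   has a value, possibly 0 or `Inf`). `member_table()`: one member as a
#'   [bilateral_table()].
#' @export
space_size <- function(space) nrow(space$idx)

#' @rdname space_size
#' @param statistic One of `"lrt"`, `"score"`, `"wald"`.
#' @export
space_statistics <- function(space, statistic = c("score", "lrt", "wald")) {
  statistic <- match.arg(statistic)
  M1 <- member_counts(space, 2L)
  M2 <- member_counts(space, 3L)
  S1 <- rowSums(M1); S2 <- rowSums(M2)
  ok <- S1 > 0 & S2 > 0
  n <- nrow(M1)
  if (statistic == "score") {
    denom <- M1 + M2
    term <- (S1 * M2 - S2 * M1)^2
    term <- ifelse(denom > 0, term / (S1 * S2 * denom), 0)
    val <- ifelse(ok, rowSums(term), 0)
  } else if (statistic == "lrt") {
    lS1 <- ifelse(ok, log(S1), 0); lS2 <- ifelse(ok, log(S2), 0)
    val <- 2 * rowSums(xlogx(M1) + xlogx(M2) - xlogx(M1 + M2)) +
      2 * (-S1 * lS1 - S2 * lS2 + (S1 + S2) * ifelse(ok, log(S1 + S2), 0))
    val <- ifelse(ok, pmax(val, 0), 0)
  } else {
    M0 <- member_counts(space, 1L)
    val <- vapply(seq_len(n), function(r) {
      wald_stat(rbind(M0[r, ], M1[r, ], M2[r, ]))$value
    }, numeric(1))
  }
  val
}

#' @rdname space_size
#' @param i Member index.
#' @export
member_table <- function(space, i) {
  g <- length(space$group_sizes)
  counts <- vapply(seq_len(g), function(j) {
    space$comps[[j]][space$idx[i, j], ]
  }, numeric(3))
  bilateral_table(counts)
}

# counts of response level l (1 = none, 2 = one, 3 = both) for all members:
# an n x g matrix
member_counts <- function(space, l) {
  g <- length(space$group_sizes)
  out <- matrix(0L, nrow(space$idx), g)
  for (j in seq_len(g)) out[, j] <- space$comps[[j]][space$idx[, j], l]
  out
}

# per-member log product of multinomial coefficients
member_logcoef <- function(space) {
  g <- length(space$group_sizes)
  out <- numeric(nrow(space$idx))
  for (j in seq_len(g)) {
    comp <- space$comps[[j]]
    lc <- lfactorial(space$group_sizes[j]) - rowSums(lfactorial(comp))
    out <- out + lc[space$idx[, j]]
  }
  out
}

#' @export
print.table_space <- function(x, ...) {
  cat("Table space:", space_size(x), "tables,",
      length(x$group_sizes), "group(s) of sizes (",
      paste(x$group_sizes, collapse = ", "), ")\n")
  if (x$conditional) {
    cat("Conditional on response totals (",
        paste(x$response_totals, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.table_space <- function(x, ...) {
  g <- length(x$group_sizes)
  cols <- list()
  for (j in seq_len(g)) {
    comp <- x$comps[[j]][x$idx[, j], , drop = FALSE]
    cols[[paste0("m0_", j)]] <- comp[, 1]
    cols[[paste0("m1_", j)]] <- comp[, 2]
    cols[[paste0("m2_", j)]] <- comp[, 3]
  }
  out <- tibble::as_tibble(cols)
  if (!is.null(x$prob)) out$prob <- x$prob
  out
}

#' Exact tests of dependence homogeneity
#'
#' Exact small-sample p-values for `H0: gamma_1 = ... = gamma_g`, built on
#' the same three statistics as [dallal_test()].
#'
#' The **conditional (C)** p-value fixes both margins and sums the
#' multivariate hypergeometric probabilities of all tables whose statistic
#' is at least the observed one.
#'
#' The **maximization (M)** p-value fixes only the group sizes and maximizes
#' the tail probability over the null parameter space — response rates
#' `pi_i` free in `[0, 1]` and a *common* `gamma` between its lower bound
#' and 1:
#' \deqn{p^M = \sup_{\pi,\,\gamma}\; \sum_{\mathbf m :\; T(\mathbf m) \ge
#'   T(\mathbf m^*)} \prod_i \mathrm{Tri}(\mathbf m_i;\, m_i,\,
#'   p(\pi_i, \gamma)).}
#' The supremum is approached by a full grid (`grid_points` per dimension,
#' intersected with the parameter constraint) followed by Nelder-Mead
#' refinement from the best `refine_starts` grid points on a transformed
#' unconstrained scale; the reported value is the best found and is a
#' guaranteed lower bound on the mathematical supremum. Tail membership uses
#' tolerance `1e-9` against floating-point ties.
#'
#' @param table Observed [bilateral_table()] (or coercible).
#' @param method `"conditional"` (C) or `"maximization"` (M).
#' @param statistic `"score"`, `"lrt"` or `"wald"`.
#' @param grid_points Grid resolution per parameter dimension for M.
#' @param refine Run local refinement from the best grid points (M only).
#' @param refine_starts Number of refinement starts.
#' @param cap Enumeration cap, as in [enumerate_tables()].
#' @return A `dallal_exact` object; `tidy()` yields a one-row tibble with
#'   `method`, `statistic`, `observed_statistic`, `p.value`, `tail_size`,
#'   `space_size`, and for M the maximizing `pi` and `gamma`.
#' @examples
#' tab <- bilateral_table(c(1, 0, 1, 0, 2, 0))
#' exact_test(tab, "conditional", "score")
#' exact_test(bilateral_table(c(0, 0, 1, 0, 1, 0)), "maximization", "score")
#' @export
exact_test <- function(table, method = c("conditional", "maximization"),
                       statistic = c("score", "lrt", "wald"),
                       grid_points = 21, refine = TRUE, refine_starts = 5,
                       cap = 1e7) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  table <- check_testable(table)
  if (method == "conditional") {
    conditional_pvalue(table, statistic, cap = cap)
  } else {
    m_pvalue(table, statistic, grid_points = grid_points, refine = refine,
             refine_starts = refine_starts, cap = cap)
  }
}

#' @rdname exact_test
#' @export
conditional_pvalue <- function(table, statistic = c("score", "lrt", "wald"),
                               cap = 1e7) {
  statistic <- match.arg(statistic)
  table <- check_testable(table)
  sp <- conditional_space(table, cap = cap)
  tvals <- space_statistics(sp, statistic)
  tobs <- asymptotic_stat(table, statistic)$value
  tail <- tvals >= tobs - 1e-9
  new_dallal_exact(
    method = "C", statistic = statistic, observed = tobs,
    p_value = sum(sp$prob[tail]), tail_size = sum(tail),
    space_size = space_size(sp)
  )
}

#' @rdname exact_test
#' @export
m_pvalue <- function(table, statistic = c("score", "lrt", "wald"),
                     grid_points = 21, refine = TRUE, refine_starts = 5,
                     cap = 1e7) {
  statistic <- match.arg(statistic)
  table <- check_testable(table)
  sp <- enumerate_tables(group_sizes(table), cap = cap)
  tvals <- space_statistics(sp, statistic)
  tobs <- asymptotic_stat(table, statistic)$value
  tail <- which(tvals >= tobs - 1e-9)
  opt <- maximize_tail(sp, tail, grid_points = grid_points, refine = refine,
                       refine_starts = refine_starts)
  new_dallal_exact(
    method = "M", statistic = statistic, observed = tobs,
    p_value = min(opt$value, 1), tail_size = length(tail),
    space_size = space_size(sp),
    pi_max = opt$pi, gamma_max = opt$gamma, grid_points = grid_points,
    trace = opt$trace
  )
}

# tail probability at one null point: sum over tail members of the product
# of per-group trinomial probabilities
tail_probability <- function(space, tail, pi, gamma) {
  g <- length(space$group_sizes)
  lb <- max(gamma_lower_bound(pi))
  if (gamma < lb - 1e-12 || gamma > 1 || any(pi < 0) || any(pi > 1)) {
    return(-Inf)
  }
  lp <- numeric(length(tail))
  for (j in seq_len(g)) {
    lq <- group_logprobs(space$comps[[j]], space$group_sizes[j], pi[j], gamma)
    lp <- lp + lq[space$idx[tail, j]]
  }
  sum(exp(lp))
}

# log trinomial probability of every composition of one group
group_logprobs <- function(comp, m, pi, gamma) {
  p0 <- max(1 - (2 - gamma) * pi, 0)
  p1 <- max(2 * pi * (1 - gamma), 0)
  p2 <- pi * gamma
  lfactorial(m) - rowSums(lfactorial(comp)) +
    mlogp(comp[, 1], rep(p0, nrow(comp))) +
    mlogp(comp[, 2], rep(p1, nrow(comp))) +
    mlogp(comp[, 3], rep(p2, nrow(comp)))
}

# grid search + Nelder-Mead refinement of the tail probability over the
# H0 parameter space (free pi_i, common gamma)
maximize_tail <- function(space, tail, grid_points, refine, refine_starts) {
  g <- length(space$group_sizes)
  if (length(tail) == space_size(space)) {
    # whole space: probability 1 at every parameter point
    return(list(value = 1, pi = rep(0.5, g), gamma = 0.5,
                trace = list(n_eval = 0L, grid_best = 1)))
  }
  grid <- seq(0, 1, length.out = grid_points)
  pts <- as.matrix(expand.grid(rep(list(grid), g + 1L)))
  colnames(pts) <- NULL
  lb <- apply(pts[, seq_len(g), drop = FALSE], 1L, function(p)
    max(gamma_lower_bound(p)))
  feasible <- pts[, g + 1L] >= lb - 1e-12
  pts <- pts[feasible, , drop = FALSE]
  vals <- if (g == 2L) {
    tail_prob_grid2(space, tail, pts)
  } else {
    apply(pts, 1L, function(x)
      tail_probability(space, tail, x[seq_len(g)], x[g + 1L]))
  }
  ord <- order(vals, decreasing = TRUE)
  best_val <- vals[ord[1]]
  best_par <- pts[ord[1], ]
  n_eval <- nrow(pts)
  if (refine) {
    starts <- pts[ord[seq_len(min(refine_starts, length(ord)))], ,
                  drop = FALSE]
    for (s in seq_len(nrow(starts))) {
      res <- refine_from(space, tail, starts[s, ], g)
      n_eval <- n_eval + res$counts
      if (res$value > best_val) {
        best_val <- res$value
        best_par <- res$par
      }
    }
  }
  list(value = best_val, pi = best_par[seq_len(g)], gamma = best_par[g + 1L],
       trace = list(n_eval = n_eval, grid_best = vals[ord[1]]))
}

# fast two-group grid evaluation: for each gamma slice the tail probability
# over all (pi_1, pi_2) pairs is Q1 %*% Z %*% t(Q2) with Z the tail indicator
tail_prob_grid2 <- function(space, tail, pts) {
  n1 <- nrow(space$comps[[1]]); n2 <- nrow(space$comps[[2]])
  Z <- matrix(0, n1, n2)
  Z[cbind(space$idx[tail, 1], space$idx[tail, 2])] <- 1
  out <- numeric(nrow(pts))
  for (gam in unique(pts[, 3])) {
    rows <- which(pts[, 3] == gam)
    pis <- sort(unique(c(pts[rows, 1], pts[rows, 2])))
    Q1 <- vapply(pis, function(p)
      exp(group_logprobs(space$comps[[1]], space$group_sizes[1], p, gam)),
      numeric(n1))
    Q2 <- if (space$group_sizes[1] == space$group_sizes[2]) Q1 else
      vapply(pis, function(p)
        exp(group_logprobs(space$comps[[2]], space$group_sizes[2], p, gam)),
        numeric(n2))
    TP <- t(Q1) %*% Z %*% Q2    # [pi1 index, pi2 index]
    i1 <- match(pts[rows, 1], pis)
    i2 <- match(pts[rows, 2], pis)
    out[rows] <- TP[cbind(i1, i2)]
  }
  out
}

# Nelder-Mead on the transformed scale: pi = plogis(x), gamma = lb(pi) +
# (1 - lb(pi)) * plogis(x[g+1]) keeps every iterate feasible
refine_from <- function(space, tail, start, g) {
  to_x <- function(pi, gamma) {
    pi <- pmin(pmax(pi, 1e-6), 1 - 1e-6)
    lb <- max(gamma_lower_bound(pi))
    u <- (gamma - lb) / max(1 - lb, 1e-12)
    c(stats::qlogis(pi), stats::qlogis(pmin(pmax(u, 1e-6), 1 - 1e-6)))
  }
  from_x <- function(x) {
    pi <- stats::plogis(x[seq_len(g)])
    lb <- max(gamma_lower_bound(pi))
    gamma <- lb + (1 - lb) * stats::plogis(x[g + 1L])
    list(pi = pi, gamma = gamma)
  }
  obj <- function(x) {
    par <- from_x(x)
    -tail_probability(space, tail, par$pi, par$gamma)
  }
  res <- stats::optim(to_x(start[seq_len(g)], start[g + 1L]), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  par <- from_x(res$par)
  list(value = -res$value, par = c(par$pi, par$gamma),
       counts = unname(res$counts[1]))
}

new_dallal_exact <- function(method, statistic, observed, p_value, tail_size,
                             space_size, pi_max = NULL, gamma_max = NULL,
                             grid_points = NULL, trace = NULL) {
  structure(
    list(method = method, statistic = statistic,
         observed_statistic = observed, p_value = p_value,
         tail_size = tail_size, space_size = space_size,
         pi_max = pi_max, gamma_max = gamma_max, grid_points = grid_points,
         trace = trace),
    class = "dallal_exact"
  )
}

#' @export
print.dallal_exact <- function(x, digits = 4, ...) {
  cat("Exact ", if (x$method == "C") "conditional" else "maximization",
      " test (", x$statistic, " statistic)\n", sep = "")
  cat("observed statistic:", format(x$observed_statistic, digits = digits),
      "  p-value:", format(x$p_value, digits = digits), "\n")
  cat("tail:", x$tail_size, "of", x$space_size, "tables\n")
  if (x$method == "M") {
    cat("attained at pi = (", paste(round(x$pi_max, 4), collapse = ", "),
        "), gamma = ", round(x$gamma_max, 4),
        " (grid ", x$grid_points, ", ", x$trace$n_eval,
        " evaluations); lower bound on the supremum\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dallal_exact <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method, statistic = x$statistic,
    observed_statistic = x$observed_statistic,
    p.value = x$p_value, tail_size = x$tail_size, space_size = x$space_size
  )
  if (x$method == "M") {
    out$pi_max <- list(x$pi_max)
    out$gamma_max <- x$gamma_max
  }
  out
}
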