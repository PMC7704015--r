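#' Simulate bilateral tables from Dallal's model
#'
#' Draws `R` independent tables: group `i` is trinomial with size `m_i` and
#' the cell probabilities of [dallal_probs()].
#'
#' @param pi,gamma Length-`g` parameter vectors (`gamma` may be a common
#'   scalar).
#' @param group_sizes Length-`g` positive integer group sizes.
#' @param R Number of tables.
#' @param seed Optional integer seed for reproducibility.
#' @return A 3 x g x R integer array; `[, , r]` is the `r`-th table.
#' @examples
#' x <- simulate_tables(c(0.2, 0.3), 0.6, c(10, 10), R = 3, seed = 1)
#' bilateral_table(x[, , 1])
#' @export
simulate_tables <- function(pi, gamma, group_sizes, R, seed = NULL) {
  g <- length(group_sizes)
  pi <- rep_len(pi, g)
  gamma <- rep_len(gamma, g)
  p <- dallal_probs(pi, gamma)
  if (!is.null(seed)) set.seed(seed)
  out <- array(0L, dim = c(3L, g, R))
  for (j in seq_len(g)) {
    pj <- pmax(c(p$p0[j], p$p1[j], p$p2[j]), 0)
    out[, j, ] <- stats::rmultinom(R, size = group_sizes[j], prob = pj)
  }
  out
}

# deterministic substream seed for grid point k under a master seed
derive_seed <- function(master, k) {
  as.integer((as.double(master) %% 2147483647 + 104729 * as.double(k)) %%
               2147483647) + 1L
}

# rejection indicators of the asymptotic tests over a 3 x g x R array
reject_asymptotic <- function(tabs, tests, alpha) {
  R <- dim(tabs)[3]
  g <- dim(tabs)[2]
  out <- matrix(NA, R, length(tests), dimnames = list(NULL, tests))
  M1 <- t(tabs[2, , , drop = TRUE]); M2 <- t(tabs[3, , , drop = TRUE])
  if (g == 1L) { M1 <- t(M1); M2 <- t(M2) }
  S1 <- rowSums(M1); S2 <- rowSums(M2)
  ok <- S1 > 0 & S2 > 0
  crit <- stats::qchisq(1 - alpha, df = g - 1)
  if ("lrt" %in% tests) {
    v <- 2 * rowSums(xlogx(M1) + xlogx(M2) - xlogx(M1 + M2)) +
      2 * (-S1 * ifelse(ok, log(S1), 0) - S2 * ifelse(ok, log(S2), 0) +
             (S1 + S2) * ifelse(ok, log(S1 + S2), 0))
    out[, "lrt"] <- ifelse(ok, pmax(v, 0), 0) > crit
  }
  if ("score" %in% tests) {
    denom <- M1 + M2
    term <- ifelse(denom > 0, (S1 * M2 - S2 * M1)^2 / (S1 * S2 * denom), 0)
    out[, "score"] <- ifelse(ok, rowSums(term), 0) > crit
  }
  if ("wald" %in% tests) {
    num <- M1 + 2 * M2
    regular <- rowSums(num == 0) == 0 & rowSums(M1 * M2 == 0) == 0
    gam <- 2 * M2 / ifelse(num > 0, num, 1)
    a <- 4 * M1 * M2 * (M1 + M2) / ifelse(num > 0, num, 1)^4
    w <- rep(NA_real_, R)
    if (g == 2L) {
      w[regular] <- (gam[regular, 1] - gam[regular, 2])^2 /
        (a[regular, 1] + a[regular, 2])
    } else {
      for (r in which(regular)) w[r] <- wald_stat(tabs[, , r])$value
    }
    for (r in which(!regular)) {
      s <- wald_stat(tabs[, , r])
      w[r] <- if (s$value > stats::qchisq(1 - alpha, df = s$df)) Inf else 0
    }
    out[, "wald"] <- w > crit
  }
  out
}

#' Monte Carlo type-I-error study
#'
#' Simulates tables under the null (a common `gamma` shared by all groups,
#' equal response rate `pi`) on a grid of `(pi, gamma)` values and records
#' each asymptotic test's empirical rejection proportion (TIE) at level
#' `alpha`. Grid points violating the parameter constraint
#' `gamma >= gamma_lower_bound(pi)` are skipped. Each grid point uses its own
#' substream seed derived from `seed`, so results are reproducible and
#' independent of evaluation order.
#'
#' @param group_sizes Length-`g` group sizes.
#' @param pi,gamma Numeric vectors spanning the null grid (all combinations
#'   are evaluated).
#' @param R Replications per grid point (default 2000).
#' @param alpha Nominal level.
#' @param tests Subset of `c("lrt", "score", "wald")`.
#' @param seed Master seed.
#' @return A `dallal_study` tibble: `pi`, `gamma`, `test`, `R`, `rejections`,
#'   `tie`, `se` (binomial Monte Carlo standard error), `robustness`,
#'   `seed`. Plot with [autoplot()][ggplot2::autoplot].
#' @examples
#' tie_study(c(15, 15), pi = 0.3, gamma = c(0.4, 0.6), R = 200, seed = 1)
#' @export
tie_study <- function(group_sizes, pi, gamma, R = 2000, alpha = 0.05,
                      tests = c("lrt", "score", "wald"), seed = 1) {
  tests <- match.arg(tests, several.ok = TRUE)
  grid <- expand.grid(pi = pi, gamma = gamma)
  grid <- grid[grid$gamma >= gamma_lower_bound(grid$pi) - 1e-12, ,
               drop = FALSE]
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sk <- derive_seed(seed, k)
    tabs <- simulate_tables(rep(grid$pi[k], length(group_sizes)),
                            grid$gamma[k], group_sizes, R, seed = sk)
    rej <- reject_asymptotic(tabs, tests, alpha)
    rows[[k]] <- tibble::tibble(
      pi = grid$pi[k], gamma = grid$gamma[k], test = tests,
      R = R, rejections = colSums(rej)[tests], seed = sk
    )
  }
  out <- dplyr::bind_rows(rows)
  out$tie <- out$rejections / out$R
  out$se <- sqrt(out$tie * (1 - out$tie) / out$R)
  out$robustness <- classify_robustness(out$tie)
  new_dallal_study(out, type = "tie", alpha = alpha)
}

#' Monte Carlo power study
#'
#' Simulates tables under the alternative: group 1 has dependence `gamma1`
#' (swept over a grid) while the remaining groups share `gamma_other`, with
#' group-specific response rates `pi`. Rejection proportions of each
#' asymptotic test are returned in long format.
#'
#' @inheritParams tie_study
#' @param pi Length-`g` response rates (group-specific).
#' @param gamma1 Grid of dependence values for group 1.
#' @param gamma_other Common dependence of groups `2..g`.
#' @return A `dallal_study` tibble with columns `gamma1`, `gamma_other`,
#'   `test`, `R`, `rejections`, `power`, `se`, `seed`.
#' @examples
#' power_study(c(15, 15), pi = c(0.2, 0.3), gamma1 = c(0.3, 0.9),
#'             gamma_other = 0.1, R = 200, seed = 1)
#' @export
power_study <- function(group_sizes, pi, gamma1, gamma_other = 0.1, R = 2000,
                        alpha = 0.05, tests = c("lrt", "score", "wald"),
                        seed = 1) {
  tests <- match.arg(tests, several.ok = TRUE)
  g <- length(group_sizes)
  pi <- rep_len(pi, g)
  gamma1 <- gamma1[gamma1 >= gamma_lower_bound(pi[1]) - 1e-12]
  rows <- vector("list", length(gamma1))
  for (k in seq_along(gamma1)) {
    sk <- derive_seed(seed, k)
    gam <- c(gamma1[k], rep(gamma_other, g - 1L))
    tabs <- simulate_tables(pi, gam, group_sizes, R, seed = sk)
    rej <- reject_asymptotic(tabs, tests, alpha)
    rows[[k]] <- tibble::tibble(
      gamma1 = gamma1[k], gamma_other = gamma_other, test = tests,
      R = R, rejections = colSums(rej)[tests], seed = sk
    )
  }
  out <- dplyr::bind_rows(rows)
  out$power <- out$rejections / out$R
  out$se <- sqrt(out$power * (1 - out$power) / out$R)
  new_dallal_study(out, type = "power", alpha = alpha)
}

#' Robustness label of an empirical type I error rate
#'
#' At nominal level 0.05 a test is called *liberal* when its empirical TIE
#' exceeds 0.06, *conservative* below 0.04, and *robust* otherwise.
#'
#' @param tie Empirical type-I-error proportions in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' classify_robustness(c(0.039, 0.05, 0.061))
#' @export
classify_robustness <- function(tie) {
  if (any(tie < 0 | tie > 1)) stop("tie must lie in [0, 1]", call. = FALSE)
  dplyr::case_when(tie > 0.06 ~ "liberal",
                   tie < 0.04 ~ "conservative",
                   TRUE ~ "robust")
}

#' Exact size of a testing procedure by full enumeration
#'
#' For small group sizes the type I error can be computed without sampling:
#' every table of the space is enumerated, the procedure's rejection region
#' is determined once, and the region's probability is evaluated at each
#' point of a null grid (common `pi`, common `gamma`). This is the defining
#' check for the maximization (M) exact test, whose size can never exceed
#' `alpha` up to the accuracy of its inner maximization.
#'
#' @param group_sizes Group sizes (the whole space is enumerated; keep the
#'   product of `choose(m_i + 2, 2)` modest).
#' @param statistic `"score"`, `"lrt"` or `"wald"`.
#' @param approach `"asymptotic"`, `"conditional"` or `"maximization"`.
#' @param alpha Nominal level.
#' @param pi,gamma Null-grid vectors (combinations violating the constraint
#'   are skipped).
#' @param grid_points Inner grid resolution for the M p-values.
#' @param cap Enumeration cap.
#' @return A `dallal_study` tibble with `pi`, `gamma`, `size` (exact
#'   rejection probability), `robustness`, plus attributes `region_size` and
#'   `space_size`.
#' @examples
#' exact_size_study(c(5, 5), "score", "asymptotic",
#'                  pi = c(0.3, 0.5), gamma = c(0.5, 0.7))
#' @export
exact_size_study <- function(group_sizes,
                             statistic = c("score", "lrt", "wald"),
                             approach = c("asymptotic", "conditional",
                                          "maximization"),
                             alpha = 0.05,
                             pi = seq(0.05, 0.95, by = 0.05),
                             gamma = seq(0.05, 1, by = 0.05),
                             grid_points = 21, cap = 1e7) {
  statistic <- match.arg(statistic)
  approach <- match.arg(approach)
  sp <- enumerate_tables(group_sizes, cap = cap)
  region <- rejection_region(sp, statistic, approach, alpha, grid_points)
  grid <- expand.grid(pi = pi, gamma = gamma)
  grid <- grid[grid$gamma >= gamma_lower_bound(grid$pi) - 1e-12, ,
               drop = FALSE]
  g <- length(group_sizes)
  idx <- which(region)
  size <- vapply(seq_len(nrow(grid)), function(k) {
    if (!length(idx)) return(0)
    tail_probability(sp, idx, rep(grid$pi[k], g), grid$gamma[k])
  }, numeric(1))
  out <- tibble::tibble(pi = grid$pi, gamma = grid$gamma, size = size,
                        robustness = classify_robustness(pmin(pmax(size, 0), 1)))
  out <- new_dallal_study(out, type = "exact_size", alpha = alpha)
  attr(out, "region_size") <- length(idx)
  attr(out, "space_size") <- space_size(sp)
  out
}

# per-member p-values over a space, then the alpha rejection region
rejection_region <- function(space, statistic, approach, alpha, grid_points) {
  tvals <- space_statistics(space, statistic)
  g <- length(space$group_sizes)
  if (approach == "asymptotic") {
    if (statistic == "wald") {
      M0 <- member_counts(space, 1L); M1 <- member_counts(space, 2L)
      M2 <- member_counts(space, 3L)
      p <- vapply(seq_len(space_size(space)), function(r) {
        s <- wald_stat(rbind(M0[r, ], M1[r, ], M2[r, ]))
        asymptotic_pvalue(s$value, s$df)
      }, numeric(1))
    } else {
      p <- asymptotic_pvalue(tvals, g - 1L)
    }
    return(p < alpha)
  }
  if (approach == "conditional") {
    M1 <- member_counts(space, 2L); M2 <- member_counts(space, 3L)
    cls <- paste(rowSums(M1), rowSums(M2))
    lognum <- member_logcoef(space)
    p <- numeric(space_size(space))
    for (cl in unique(cls)) {
      ii <- which(cls == cl)
      pr <- exp(lognum[ii] - logsumexp(lognum[ii]))
      tv <- tvals[ii]
      p[ii] <- vapply(tv, function(t0) sum(pr[tv >= t0 - 1e-9]), numeric(1))
    }
    return(p < alpha)
  }
  # maximization: tails are nested in the threshold, so only unique
  # statistic values need maximizing
  thr <- sort(unique(tvals), decreasing = TRUE)
  pm <- vapply(thr, function(t0) {
    tail <- which(tvals >= t0 - 1e-9)
    min(maximize_tail(space, tail, grid_points = grid_points, refine = TRUE,
                      refine_starts = 5)$value, 1)
  }, numeric(1))
  p <- pm[match(tvals, thr)]
  p < alpha
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_dallal_study <- function(data, type, alpha) {
  structure(data, class = c("dallal_study", class(data)),
            study_type = type, alpha = alpha)
}
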