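test_that("cell probabilities follow the model map and its constraint", {
  p <- dallal_probs(0.5, 1)
  expect_equal(unlist(p[, c("p0", "p1", "p2")], use.names = FALSE),
               c(0.5, 0, 0.5))
  p <- dallal_probs(0.5, 0.5)
  expect_equal(unlist(p[, c("p0", "p1", "p2")], use.names = FALSE),
               c(0.25, 0.5, 0.25))
  # gamma below 2 - 1/pi makes p0 negative
  expect_error(dallal_probs(0.6, 0.2), "lower bound")
  expect_error(dallal_probs(0.5, 1.2), "gamma")
  expect_error(dallal_probs(1.5, 0.9), "pi")
})

test_that("probabilities sum to one across the whole valid region", {
  set.seed(11)
  for (k in 1:300) {
    pi <- runif(1)
    lb <- gamma_lower_bound(pi)
    gamma <- runif(1, lb, 1)
    p <- dallal_probs(pi, gamma)
    expect_true(all(p$p0 >= -1e-12 & p$p1 >= -1e-12 & p$p2 >= -1e-12))
    expect_equal(p$p0 + p$p1 + p$p2, 1, tolerance = 1e-12)
  }
})

test_that("log-likelihood handles point masses and zero cells", {
  tab <- bilateral_table(c(0, 0, 5))
  expect_equal(dallal_loglik(tab, pi = 1, gamma = 1), 0)
  # positive count on a zero-probability cell: -Inf, not an error
  expect_equal(dallal_loglik(bilateral_table(c(0, 2, 3)), pi = 1, gamma = 1),
               -Inf)
  expect_error(dallal_loglik(tab, pi = c(0.5, 0.5), gamma = 0.5), "length")
})

test_that("closed-form unconstrained MLEs maximize the likelihood", {
  set.seed(21)
  tab <- random_positive_table(3)
  fit <- mle_unconstrained(tab)
  for (k in 1:1000) {
    pi <- runif(3, 0.01, 0.99)
    gamma <- vapply(pi, function(p) runif(1, gamma_lower_bound(p), 1),
                    numeric(1))
    expect_lte(dallal_loglik(tab, pi, gamma), fit$loglik + 1e-12)
  }
})

test_that("unconstrained MLEs: worked example and boundary groups", {
  rp <- dallal_fixture("rp_table2")
  fit <- mle_unconstrained(rp)
  expect_equal(round(fit$pi, 4), c(0.3571, 0.5476, 0.7895, 0.4662),
               ignore_attr = TRUE)
  expect_equal(round(fit$gamma, 4), c(0.7000, 0.7826, 0.9333, 0.8261),
               ignore_attr = TRUE)
  none <- mle_unconstrained(bilateral_table(c(7, 0, 0)))
  expect_equal(none$pi, 0, ignore_attr = TRUE)
  expect_true(is.na(none$gamma))
  expect_false(none$gamma_defined)
  all2 <- mle_unconstrained(bilateral_table(c(0, 0, 7)))
  expect_equal(all2$pi, 1, ignore_attr = TRUE)
  expect_equal(all2$gamma, 1, ignore_attr = TRUE)
})

test_that("constrained MLEs: worked example, degenerate margins, closed form", {
  rp <- dallal_fixture("rp_table2")
  fit <- mle_constrained(rp)
  expect_equal(round(fit$gamma, 4), 0.8246)
  expect_equal(round(fit$pi[1], 4), 0.3950, ignore_attr = TRUE)
  # no bilateral responders anywhere: common gamma estimated 0
  noS2 <- mle_constrained(bilateral_table(c(3, 2, 0, 4, 1, 0)))
  expect_equal(noS2$gamma, 0)
  # S1 = S2 = 0: gamma unidentified
  empty <- mle_constrained(bilateral_table(c(3, 0, 0, 4, 0, 0)))
  expect_true(is.na(empty$gamma))
  g2 <- mle_constrained(bilateral_table(c(1, 2, 3, 4, 5, 6)))
  expect_equal(g2$gamma, 18 / 25)
  expect_equal(g2$pi[1], 125 / 192, ignore_attr = TRUE)
})

test_that("closed-form MLEs agree with a numerical maximizer", {
  set.seed(31)
  for (k in 1:30) {
    tab <- random_positive_table(sample(2:4, 1))
    un <- mle_unconstrained(tab)
    co <- mle_constrained(tab)
    nu <- numeric_mle(tab, common_gamma = FALSE)
    nc <- numeric_mle(tab, common_gamma = TRUE)
    expect_equal(un$pi, nu$pi, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(un$gamma, nu$gamma, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(co$pi, nc$pi, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(co$gamma, nc$gamma, tolerance = 1e-6, ignore_attr = TRUE)
    expect_lte(co$loglik, un$loglik + 1e-10)
  }
})

test_that("estimates are equivariant under group relabeling", {
  set.seed(41)
  for (k in 1:20) {
    tab <- random_table(4)
    perm <- sample(4)
    ptab <- bilateral_table(unclass(tab)[, perm])
    un <- mle_unconstrained(tab); pun <- mle_unconstrained(ptab)
    expect_equal(pun$pi, un$pi[perm], ignore_attr = TRUE)
    expect_equal(pun$gamma, un$gamma[perm], ignore_attr = TRUE)
    co <- mle_constrained(tab); pco <- mle_constrained(ptab)
    expect_equal(pco$gamma, co$gamma)
    expect_equal(pco$pi, co$pi[perm], ignore_attr = TRUE)
  }
})

test_that("tidy and glance summarise fits", {
  fit <- mle_unconstrained(dallal_fixture("rp_table2"))
  td <- tidy(fit)
  expect_named(td, c("group", "pi", "gamma", "gamma_defined"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$n, 216)
  expect_false(gl$constrained)
})

test_that("information matrix inverse matches Eq-form entries and identity", {
  # direct evaluation: gamma*(gamma-1)*(gamma-2)/(2*m*pi) at (0.5, 0.5, 10)
  Ii <- information_inverse(0.5, 0.5, 10)
  expect_equal(Ii[1, 1], 0.0375)
  set.seed(51)
  for (k in 1:100) {
    g <- sample(1:4, 1)
    pi <- runif(g, 0.15, 0.85)
    gamma <- vapply(pi, function(p)
      runif(1, gamma_lower_bound(p) + 0.05, 0.95), numeric(1))
    m <- sample(5:60, g, replace = TRUE)
    I <- information_matrix(pi, gamma, m)
    Iinv <- information_inverse(pi, gamma, m)
    expect_true(isSymmetric(I))
    expect_true(all(eigen(I, symmetric = TRUE, only.values = TRUE)$values > 0))
    expect_lt(max(abs(I %*% Iinv - diag(2 * g))), 1e-8)
    # the gamma-block inverse entries are variances, never negative
    expect_true(all(diag(Iinv)[seq_len(g)] >= 0))
  }
  expect_error(information_matrix(0.5, 1, 10), "interior")
})

test_that("information matrix is the curvature of the log-likelihood", {
  # numerical Hessian of the expected log-likelihood at the truth
  pi <- 0.4; gamma <- 0.6; m <- 30
  p <- dallal_probs(pi, gamma)
  eps <- 1e-4
  ell <- function(g2, p2) {
    q <- dallal_probs(p2, g2)
    m * (p$p0 * log(q$p0) + p$p1 * log(q$p1) + p$p2 * log(q$p2))
  }
  hgg <- (ell(gamma + eps, pi) - 2 * ell(gamma, pi) +
            ell(gamma - eps, pi)) / eps^2
  I <- information_matrix(pi, gamma, m)
  expect_equal(I[1, 1], -hgg, tolerance = 1e-4)
})
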