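test_that("enumeration counts are exact binomial-coefficient products", {
  expect_equal(space_size(enumerate_tables(c(10, 10))), 4356L)
  sp1 <- enumerate_tables(1)
  expect_equal(space_size(sp1), 3L)
  tabs <- lapply(1:3, function(i) as.integer(unclass(member_table(sp1, i))))
  expect_setequal(
    vapply(tabs, paste, collapse = ",", FUN.VALUE = character(1)),
    c("1,0,0", "0,1,0", "0,0,1")
  )
  # choose(12, 2)^3, not the commonly mis-stated 287,492
  expect_equal(space_size(enumerate_tables(c(10, 10, 10))), 66L^3)
  expect_error(enumerate_tables(c(100, 100, 100), cap = 1e6),
               "136,670,457,951")
  expect_error(enumerate_tables(c(-1, 3)), "nonnegative")
})

test_that("enumeration is duplicate-free and respects group sizes", {
  sp <- enumerate_tables(c(3, 2))
  tib <- as_tibble(sp)
  expect_equal(nrow(tib), choose(5, 2) * choose(4, 2))
  expect_equal(nrow(dplyr::distinct(tib)), nrow(tib))
  expect_true(all(tib$m0_1 + tib$m1_1 + tib$m2_1 == 3))
  expect_true(all(tib$m0_2 + tib$m1_2 + tib$m2_2 == 2))
})

test_that("conditional spaces carry the multivariate hypergeometric law", {
  # two patients, totals (0, 1, 1): the two assignments are equally likely
  sp <- conditional_space(bilateral_table(c(0, 1, 0, 0, 0, 1)))
  expect_equal(space_size(sp), 2L)
  expect_equal(sp$prob, c(0.5, 0.5))
  # degenerate margin: a single table with probability one
  sp0 <- conditional_space(bilateral_table(c(2, 0, 0, 3, 0, 0)))
  expect_equal(space_size(sp0), 1L)
  expect_equal(sp0$prob, 1)
  # the (2,2) / (1,2,1) worked space: coefficients 4, 2, 2, 4 over 12
  sp4 <- conditional_space(bilateral_table(c(1, 0, 1, 0, 2, 0)))
  expect_equal(space_size(sp4), 4L)
  expect_equal(sort(sp4$prob), c(2, 2, 4, 4) / 12)
  expect_equal(sum(sp4$prob), 1, tolerance = 1e-12)
})

test_that("conditional probabilities sum to one on random spaces", {
  set.seed(71)
  for (k in 1:20) {
    tab <- random_table(sample(2:3, 1), m_range = 2:8)
    sp <- conditional_space(tab)
    expect_equal(sum(sp$prob), 1, tolerance = 1e-12)
  }
})

test_that("conditional p-values match hand enumeration on the worked space", {
  obs <- bilateral_table(c(1, 0, 1, 0, 2, 0))
  res <- conditional_pvalue(obs, "score")
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$tail_size, 2L)
  # the minimum-statistic member has the whole space as its tail
  low <- bilateral_table(c(1, 1, 0, 0, 1, 1))
  expect_equal(conditional_pvalue(low, "score")$p_value, 1)
  # a table alone in its conditional space has p = 1
  alone <- bilateral_table(c(2, 0, 0, 3, 0, 0))
  expect_equal(conditional_pvalue(alone, "score")$p_value, 1)
})

test_that("conditional p-values equal a naive independent enumeration", {
  set.seed(72)
  for (k in 1:12) {
    tab <- random_table(2, m_range = 2:6)
    for (statistic in c("score", "lrt", "wald")) {
      expect_equal(conditional_pvalue(tab, statistic)$p_value,
                   naive_conditional_pvalue(tab, statistic),
                   tolerance = 1e-12)
    }
  }
  tab3 <- random_table(3, m_range = 2:4)
  expect_equal(conditional_pvalue(tab3, "score")$p_value,
               naive_conditional_pvalue(tab3, "score"), tolerance = 1e-12)
})

test_that("maximization p-value on the two-patient space matches a dense grid", {
  obs <- bilateral_table(c(0, 0, 1, 0, 1, 0))
  res <- m_pvalue(obs, "score", grid_points = 101, refine = FALSE)
  # dense-grid oracle: direct sum over the 9 tables, 101 points per parameter
  stats9 <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- matrix(0L, 3, 2); m[i, 1] <- 1L; m[j, 2] <- 1L
    stats9[i, j] <- dallaltest:::asymptotic_stat(bilateral_table(m),
                                                 "score")$value
  }
  tobs <- stats9[3, 2]
  intail <- stats9 >= tobs - 1e-9
  grid <- seq(0, 1, length.out = 101)
  best <- 0
  for (gam in grid) {
    P <- cbind(1 - (2 - gam) * grid, 2 * grid * (1 - gam), grid * gam)
    valid <- P[, 1] >= -1e-12   # pi compatible with this gamma
    P[P < 0] <- 0
    P <- P[valid, , drop = FALSE]
    if (!nrow(P)) next
    tp <- P %*% intail %*% t(P)   # [pi1 index, pi2 index]
    best <- max(best, tp)
  }
  expect_equal(res$p_value, best, tolerance = 1e-4)
  # the default (refined) search can only do better than the plain grid
  expect_gte(m_pvalue(obs, "score")$p_value, best - 1e-10)
})

test_that("maximization p-value dominates the tail at the constrained MLEs", {
  set.seed(73)
  for (k in 1:8) {
    tab <- random_table(2, m_range = 2:5)
    res <- m_pvalue(tab, "score")
    sp <- enumerate_tables(group_sizes(tab))
    tvals <- space_statistics(sp, "score")
    tail <- which(tvals >= res$observed_statistic - 1e-9)
    co <- mle_constrained(tab)
    gam <- if (is.na(co$gamma)) 1 else co$gamma
    at_tilde <- dallaltest:::tail_probability(sp, tail, co$pi, gam)
    expect_gte(res$p_value + 1e-10, at_tilde)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
})

test_that("a space-wide minimum statistic forces p = 1", {
  # equal groups give the minimum (zero) score statistic
  obs <- bilateral_table(c(1, 1, 1, 1, 1, 1))
  expect_equal(m_pvalue(obs, "score")$p_value, 1)
})

test_that("exact p-values are invariant under group permutation", {
  set.seed(74)
  for (k in 1:5) {
    tab <- random_table(3, m_range = 2:4)
    perm <- sample(3)
    ptab <- bilateral_table(unclass(tab)[, perm])
    expect_equal(conditional_pvalue(tab, "score")$p_value,
                 conditional_pvalue(ptab, "score")$p_value,
                 tolerance = 1e-12)
  }
  tab <- bilateral_table(c(1, 2, 1, 3, 0, 1))
  ptab <- bilateral_table(unclass(tab)[, 2:1])
  expect_equal(m_pvalue(tab, "score")$p_value,
               m_pvalue(ptab, "score")$p_value, tolerance = 1e-9)
})

test_that("refining on a denser grid never lowers the maximized p-value", {
  tab <- bilateral_table(c(1, 1, 1, 0, 1, 2))
  for (statistic in c("score", "lrt")) {
    p21 <- m_pvalue(tab, statistic, grid_points = 21, refine = FALSE)$p_value
    p41 <- m_pvalue(tab, statistic, grid_points = 41, refine = FALSE)$p_value
    expect_gte(p41, p21 - 1e-10)
    # refinement can only improve on its own grid
    pr <- m_pvalue(tab, statistic, grid_points = 21, refine = TRUE)$p_value
    expect_gte(pr, p21 - 1e-10)
  }
})

test_that("exact_test dispatches and records the optimizer trace", {
  tab <- bilateral_table(c(2, 1, 2, 1, 2, 2))
  rc <- exact_test(tab, "conditional", "lrt")
  expect_s3_class(rc, "dallal_exact")
  expect_equal(rc$method, "C")
  rm <- exact_test(tab, "maximization", "score", grid_points = 11)
  expect_equal(rm$method, "M")
  expect_true(rm$trace$n_eval > 0)
  expect_true(!is.null(rm$pi_max) && length(rm$pi_max) == 2)
  td <- tidy(rm)
  expect_equal(td$p.value, rm$p_value)
})
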