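test_that("rank correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_test(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_test(1:8, -(1:8))$statistic, -1)
  expect_error(spearman_test(1:5, rep(2, 5)), "constant")
  expect_error(spearman_test(1:2, 1:2), ">= 3")
  # tie handling via mid-ranks agrees with cor()
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 8, 9, 11, 12)
  y <- c(2, 1, 3, 3, 5, 4, 7, 6, 8, 10, 9, 12)
  expect_equal(spearman_test(x, y)$statistic, cor(rank(x), rank(y)))
})

test_that("small-sample rank correlation p is the exact permutation value", {
  out <- spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_true(out$exact)
  expect_equal(out$statistic, 0.8)
  # independent oracle: the exact branch of cor.test
  ct <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                 method = "spearman", exact = TRUE)
  expect_equal(out$statistic, unname(ct$estimate))
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
})

test_that("rank correlation exact and approximate branches agree near n = 10", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(10); y <- 0.5 * x + rnorm(10)
    pe <- spearman_test(x, y)$p
    pa <- spearman_test(x, y, exact_n = 0)$p
    expect_lt(abs(pe - pa), 0.05)
  }
})

test_that("Mann-Whitney handles identical, separated and transformed samples", {
  same <- mann_whitney_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p, 0.99)
  out <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(out$exact)
  expect_equal(out$statistic, 0)        # no pair with the first sample ahead
  expect_equal(out$p, 0.1)              # 2/20 splits as extreme
  # rank test: invariant under a common monotone transform
  a <- c(0.3, 1.2, 2.5, 4.1); b <- c(0.9, 2.2, 3.3, 5.5)
  expect_equal(mann_whitney_test(a, b)$p, mann_whitney_test(exp(a), exp(b))$p)
  expect_error(mann_whitney_test(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney exact and normal branches agree at the crossover", {
  set.seed(17)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)   # n_a * n_b = 64: exact branch
    pe <- mann_whitney_test(a, b)$p
    pw <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pw), 0.02)
  }
})

test_that("Mann-Whitney U matches the independent base-R implementation", {
  set.seed(23)
  a <- rnorm(12); b <- rnorm(15, 0.3)
  expect_equal(mann_whitney_test(a, b)$statistic,
               unname(wilcox.test(a, b)$statistic))
})

test_that("Kruskal-Wallis matches a hand rank calculation and degenerates", {
  out <- kruskal_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(out$statistic, 32 / 7, tolerance = 1e-12)   # ranks 1..6 by hand
  expect_equal(out$df, 2)
  same <- kruskal_test(list(c(1, 2, 3), c(1.1, 2.1, 2.9), c(0.9, 2, 3.2)))
  expect_gt(same$p, 0.5)
  tied <- kruskal_test(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
})

test_that("two-group Kruskal-Wallis is the squared standardized U", {
  set.seed(5)
  a <- rnorm(9); b <- rnorm(11, 0.4)
  H <- kruskal_test(list(a, b))$statistic
  na <- 9; nb <- 11
  u <- mann_whitney_test(a, b)$statistic
  z <- (u - na * nb / 2) / sqrt(na * nb * (na + nb + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("Dunn-Sidak adjustment follows the closed form", {
  expect_equal(dunn_sidak(0.05, 3), 1 - 0.95^3)
  expect_equal(dunn_sidak(0, 10), 0)
  expect_equal(dunn_sidak(0.2, 1), 0.2)
  expect_equal(dunn_sidak(0.9, 50), 1)
  expect_error(dunn_sidak(0.05, 0), "m must be")
  expect_error(dunn_sidak(1.5, 2), "in \\[0, 1\\]")
})

test_that("Dunn post-hoc comparisons are adjusted over all pairs", {
  set.seed(6)
  groups <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10))
  out <- dunn_posthoc(groups)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adj >= out$p - 1e-12))
  expect_lt(out$p_adj[out$group1 == "a" & out$group2 == "b"], 0.05)
})

test_that("Fleiss' kappa matches hand computation and edge cases", {
  # 4 subjects, 3 raters, 2 categories, worked by hand: kappa = 1/3
  tab <- matrix(c(3, 2, 1, 0, 0, 1, 2, 3), 4)
  expect_equal(fleiss_kappa(tab)$kappa, 1 / 3, tolerance = 1e-12)
  # perfect agreement across categories actually used
  perfect <- matrix(c(3, 0, 0, 3, 3, 0, 0, 3, 3, 0, 0, 3), 6, 2)
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  # single category everywhere: chance agreement is 1, kappa undefined
  degen <- fleiss_kappa(matrix(c(3, 3, 3, 0, 0, 0), 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$kappa))
  expect_error(fleiss_kappa(matrix(c(3, 2, 0, 2), 2)), "same rater count")
})

test_that("Fleiss' kappa is near zero for random ratings", {
  inside <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    ratings <- matrix(sample(1:2, 600, replace = TRUE), 200, 3)
    counts <- t(apply(ratings, 1, tabulate, nbins = 2))
    k <- fleiss_kappa(counts)$kappa
    if (abs(k) < 0.15) inside <- inside + 1
  }
  expect_gte(inside / 60, 0.95)
})

test_that("ICC(2,1) matches its definition and the anova decomposition", {
  M <- cbind(1:8, 1:8)
  expect_equal(icc21(M)$icc, 1)
  # absolute agreement penalizes a systematic offset
  expect_lt(icc21(cbind(1:8, 1:8 + 10))$icc, 0.5)
  # cross-check the mean squares against anova(lm())
  set.seed(12)
  vals <- rnorm(20, rep(rnorm(10, sd = 3), each = 2), 1)
  df <- data.frame(subject = factor(rep(1:10, each = 2)),
                   rater = factor(rep(1:2, 10)),
                   value = vals)
  M2 <- matrix(vals, 10, 2, byrow = TRUE)
  ms <- anova(lm(value ~ subject + rater, df))["Mean Sq"][[1]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_ref <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 10)
  expect_equal(icc21(M2)$icc, icc_ref, tolerance = 1e-10)
  expect_error(icc21(M[1:3, ]), "subjects")
})

test_that("ICC recovers a known variance-component ratio", {
  set.seed(44)
  iccs <- replicate(30, {
    subj <- rnorm(200, sd = 3)
    icc21(cbind(subj + rnorm(200), subj + rnorm(200)))$icc
  })
  expect_lt(abs(mean(iccs) - 0.9), 0.05)
})

test_that("tests are invariant to input ordering", {
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  ord <- sample(12)
  expect_equal(spearman_test(x, y)$p, spearman_test(x[ord], y[ord])$p)
  a <- rnorm(7); b <- rnorm(9)
  expect_equal(mann_whitney_test(a, b)$p,
               mann_whitney_test(sample(a), sample(b))$p)
})

test_that("data-frame-first interfaces match the vector interfaces", {
  df <- tibble::tibble(g = rep(c("x", "y"), each = 5),
                       v = c(1:5, 3:7), w = c(2, 1, 4, 3, 5, 6, 8, 7, 9, 10))
  expect_equal(mann_whitney_test(df, v, g)$p,
               mann_whitney_test(df$v[df$g == "x"], df$v[df$g == "y"])$p)
  expect_equal(spearman_test(df, v, w)$statistic,
               spearman_test(df$v, df$w)$statistic)
  expect_equal(kruskal_test(df, v, g)$statistic,
               kruskal_test(split(df$v, df$g))$statistic)
  tt <- compare_groups(df, v, g, parametric = TRUE)
  expect_equal(tt$p, t.test(df$v[df$g == "x"], df$v[df$g == "y"])$p.value)
})
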