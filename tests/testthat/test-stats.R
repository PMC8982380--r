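test_that("exact Mann-Whitney matches hand enumeration on the extreme case", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 * (1 / C(6,3))
  expect_equal(r$p_value, mwu_enum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("identical samples give p = 1", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(x, x, mode = "exact")$p_value, 1)
  expect_equal(mann_whitney_u(x, x, mode = "asymptotic")$p_value, 1)
})

test_that("exact p equals the full-enumeration oracle for tie-free and tied data", {
  withr::with_seed(11, {
    for (i in 1:25) {
      nx <- sample(2:6, 1); ny <- sample(2:6, 1)
      x <- stats::rnorm(nx); y <- stats::rnorm(ny)
      expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                   mwu_enum_p(x, y), tolerance = 1e-12)
    }
    for (i in 1:10) { # heavy ties
      x <- sample(1:3, 5, replace = TRUE)
      y <- sample(1:3, 5, replace = TRUE)
      expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                   mwu_enum_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("exact and asymptotic p agree within 0.02 at n = 6 + 6 without ties", {
  withr::with_seed(13, {
    for (i in 1:40) {
      x <- stats::rnorm(6); y <- stats::rnorm(6, mean = stats::runif(1, 0, 2))
      pe <- mann_whitney_u(x, y, mode = "exact")$p_value
      pa <- mann_whitney_u(x, y, mode = "asymptotic")$p_value
      expect_lt(abs(pe - pa), 0.02)
    }
  })
})

test_that("rank tests are invariant under monotone transformation", {
  withr::with_seed(17, {
    x <- stats::rnorm(7); y <- stats::rnorm(5, 1)
    g <- list(stats::rnorm(4), stats::rnorm(4, 1), stats::rnorm(4, 2))
    f <- function(v) exp(v)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 mann_whitney_u(f(x), f(y))$p_value)
    expect_equal(kruskal_wallis(g)$p_value,
                 kruskal_wallis(lapply(g, f))$p_value)
    expect_equal(dunn_posthoc(g)$p_value, dunn_posthoc(lapply(g, f))$p_value)
  })
})

test_that("Kruskal-Wallis agrees with the reference implementation and handles ties", {
  withr::with_seed(19, {
    g <- list(stats::rnorm(8), stats::rnorm(6, 0.5), stats::rnorm(7, 1))
    r <- kruskal_wallis(g)
    kt <- stats::kruskal.test(g)
    expect_equal(r$statistic, unname(kt$statistic))
    expect_equal(r$p_value, unname(kt$p.value))
  })
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("two-group exact Kruskal-Wallis equals the exact Mann-Whitney p", {
  withr::with_seed(23, {
    for (i in 1:10) {
      x <- stats::rnorm(4); y <- stats::rnorm(5)
      pk <- kruskal_wallis(list(x, y), mode = "exact")$p_value
      pm <- mann_whitney_u(x, y, mode = "exact")$p_value
      expect_equal(pk, pm, tolerance = 1e-12)
    }
  })
})

test_that("three-group exact permutation p approaches the chi-square reference", {
  withr::with_seed(29, {
    g <- list(stats::rnorm(3), stats::rnorm(3, 2), stats::rnorm(3, 4))
    pe <- kruskal_wallis(g, mode = "exact")$p_value
    pc <- kruskal_wallis(g, mode = "chisq")$p_value
    # the permutation p is exact; chi-square is an approximation at n = 9
    expect_lt(abs(pe - pc), 0.05)
    expect_gte(pe, 0)
    expect_lte(pe, 1)
  })
})

test_that("Dunn comparisons use Bonferroni over the vs-control family", {
  g <- list(ctrl = c(1, 2, 3, 4), a = c(1, 2, 3, 4), b = c(10, 11, 12, 13))
  r <- dunn_posthoc(g, control = 1)
  expect_equal(r$p_value[1], 1) # identical group vs control
  expect_equal(r$p_value, pmin(1, 2 * r$p_raw)) # m = 2 comparisons
  expect_true(all(r$adjusted))

  r1 <- dunn_posthoc(g[1:2], control = 1)
  expect_equal(r1$p_value, r1$p_raw) # single comparison: no change
  expect_error(dunn_posthoc(g, control = 9), "out of range")
})

test_that("Fisher's exact test matches enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / 184756, tolerance = 1e-9)
  withr::with_seed(31, {
    for (i in 1:25) {
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      p <- fisher_exact_2x2(tab)$p_value
      expect_equal(p, fisher_enum_p(tab), tolerance = 1e-9)
      expect_equal(p, fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
    }
  })
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the t-based confidence interval behaves at its edges and asymptotically", {
  r <- mean_ci95(rep(3.5, 6))
  expect_equal(unlist(r[, c("mean", "lower", "upper")], use.names = FALSE),
               c(3.5, 3.5, 3.5))
  expect_error(mean_ci95(2), "n >= 2")

  withr::with_seed(37, {
    v <- stats::rnorm(10000)
    r2 <- mean_ci95(v)
    expect_equal(r2$upper - r2$mean, r2$mean - r2$lower, tolerance = 1e-9)
    width <- r2$upper - r2$lower
    expect_lt(abs(width - 2 * 1.96 / 100) / (2 * 1.96 / 100), 0.1)
    rb <- mean_ci95(v, method = "bootstrap", seed = 5)
    expect_lt(abs((rb$upper - rb$lower) - width) / width, 0.15)
  })
})
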