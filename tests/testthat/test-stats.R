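test_that("paired_wilcoxon handles degenerate and all-positive cases exactly", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(paired_wilcoxon(a, a)$p_value, 1)
  expect_true(paired_wilcoxon(a, a)$degenerate)
  # six strictly positive differences: one-sided tail 1/64, two-sided 1/32
  res <- paired_wilcoxon(a + 1, a)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$method, "exact")
  expect_error(paired_wilcoxon(1:4, 2:5), "at least 5")
  expect_error(paired_wilcoxon(1:6, 1:5), "equal length")
})

test_that("paired_wilcoxon matches exhaustive sign-flip enumeration at n = 10", {
  set.seed(101)
  for (rep in 1:8) {
    d <- round(rnorm(10), if (rep %% 2 == 0) 0 else 3)  # force ties half the time
    a <- rnorm(10)
    b <- a - d
    if (all(a == b)) next
    expect_equal(paired_wilcoxon(a, b)$p_value, enumerate_signed_rank_p(a - b),
                 tolerance = 1e-12)
  }
})

test_that("paired_wilcoxon agrees with the reference exact test when tie-free", {
  set.seed(7)
  a <- rnorm(12)
  b <- rnorm(12)
  ours <- paired_wilcoxon(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("mann_whitney is exact for small tie-free samples", {
  x <- c(10, 11, 12, 13)
  y <- c(1, 2, 3, 4)
  res <- mann_whitney(x, y)
  expect_equal(res$statistic, 16)
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  # identical multisets sit at the null centre
  same <- mann_whitney(c(1, 2, 3), c(2, 3, 1))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("mann_whitney matches exhaustive enumeration for n <= 10", {
  set.seed(202)
  for (rep in 1:6) {
    m <- sample(3:5, 1)
    n <- sample(3:5, 1)
    x <- rnorm(m)
    y <- rnorm(n)
    expect_equal(mann_whitney(x, y)$p_value, enumerate_mann_whitney_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("log_fold_change is zero at equality and tracks the mean ordering", {
  expect_equal(log_fold_change(3, 3, 0), 0)
  expect_equal(log_fold_change(4, 2, 0), log(2))
  set.seed(5)
  a <- runif(50, 0, 10)
  b <- runif(50, 0, 10)
  expect_equal(sign(log_fold_change(a, b, 0.01)), sign(a - b))
  expect_error(log_fold_change(0, 0, 0), "undefined")
  expect_error(log_fold_change(-1, 1), "nonnegative")
})

test_that("site_logistic reproduces the closed-form 2x2 log odds ratio", {
  # binary methylation predictor, no covariates: log OR = log(ad/bc)
  level <- rep(c(1, 0), c(30, 30))
  group <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 12), rep(FALSE, 18))
  res <- site_logistic(group, level)
  a <- 20; b <- 10; c <- 12; d <- 18
  expect_equal(res$effect, log((a * d) / (b * c)), tolerance = 1e-6)
  expect_false(res$flagged)
})

test_that("site_logistic flags degenerate fits instead of emitting infinities", {
  group <- rep(c(TRUE, FALSE), each = 10)
  expect_true(site_logistic(group, rep(2, 20))$flagged)
  # perfect separation
  sep <- site_logistic(group, c(rep(10, 10), rep(0, 10)))
  expect_true(sep$flagged)
  expect_error(site_logistic(rep(TRUE, 10), rnorm(10)), "Both groups")
})

test_that("site_age_association recovers an exact linear signal", {
  ages <- c(20, 25, 30, 40, 50, 60, 70, 80)
  res <- suppressWarnings(site_age_association(0.1 * ages, ages))
  expect_equal(res$effect, 0.1, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  # without covariates the coefficient equals the Pearson slope
  set.seed(31)
  lev <- rnorm(20, 2, 0.5)
  ag <- runif(20, 20, 80)
  res2 <- site_age_association(lev, ag)
  expect_equal(res2$effect, cor(lev, ag) * sd(lev) / sd(ag), tolerance = 1e-10)
  expect_error(site_age_association(rnorm(20), rep(50, 20)), "non-constant")
  expect_error(site_age_association(rnorm(5), rnorm(5)), "n >= 8")
})

test_that("select_sites thresholds strictly and nests across alphas", {
  res <- tibble::tibble(position = 1:6, strand = "+",
                        p_value = c(0.001, 0.004, 0.02, 0.049, 0.05, 0.2),
                        flagged = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(select_sites(res, 0.05)$position, 1:4)  # 0.05 itself excluded
  loose <- select_sites(res, 0.05)$position
  strict <- select_sites(res, 0.005)$position
  expect_true(all(strict %in% loose))
  res$flagged[1] <- TRUE
  expect_false(1 %in% select_sites(res, 0.05)$position)
  expect_error(select_sites(res, 0), "alpha")
})

test_that("chi_square_independence matches printed two-group comparisons", {
  alcohol <- rbind(c(7, 32), c(2, 12))
  expect_lt(abs(chi_square_independence(alcohol)$p_value - 0.754), 5e-4)
  cod <- cbind(c(17, 3, 2, 15, 2), c(4, 5, 3, 1, 1))
  res <- chi_square_independence(cod)
  expect_equal(res$df, 4)
  expect_lt(abs(res$p_value - 0.015), 5e-4)
})

test_that("chi_square_independence is invariant to permutation and transpose", {
  set.seed(8)
  tab <- matrix(rpois(12, 20), 3, 4)
  base <- chi_square_independence(tab)
  perm <- chi_square_independence(tab[c(2, 3, 1), c(4, 1, 3, 2)])
  trans <- chi_square_independence(t(tab))
  expect_equal(perm$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(trans$p_value, base$p_value, tolerance = 1e-12)
  expect_equal(chi_square_independence(rbind(c(10, 20), c(5, 10)))$statistic, 0)
  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 10))), "marginal")
})

test_that("pearson_power agrees with a Monte-Carlo simulation oracle", {
  set.seed(55)
  n <- 39
  r <- 0.5
  n_sim <- 100000
  # bivariate normal with correlation r, vectorised across simulations
  x <- matrix(rnorm(n_sim * n), n_sim, n)
  y <- r * x + sqrt(1 - r^2) * matrix(rnorm(n_sim * n), n_sim, n)
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  r_hat <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  t_stat <- r_hat * sqrt((n - 2) / (1 - r_hat^2))
  mc_power <- mean(abs(t_stat) > qt(0.975, n - 2))
  expect_lt(abs(pearson_power(r, n, 0.05) - mc_power), 0.01)
})

test_that("pearson_power obeys its limits and the study's design claim", {
  expect_gt(pearson_power(0.5, 39, 0.05), 0.9)
  # vanishing correlation: power tends to alpha/2 from the upper tail
  expect_equal(pearson_power(1e-9, 39, 0.05), 0.025, tolerance = 1e-3)
  expect_gt(pearson_power(0.5, 100), pearson_power(0.5, 20))
  expect_error(pearson_power(1.2, 39), "in \\(0, 1\\)")
  expect_error(pearson_power(0.5, 3), "exceed 3")
})
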