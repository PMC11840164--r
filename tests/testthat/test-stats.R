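test_that("the Shapiro-Wilk gate routes by normality", {
  set.seed(1)
  expect_true(shapiro_gate(rnorm(100)))
  # exponential data fail the gate with high power at n = 100
  reject <- vapply(1:50, function(i) {
    set.seed(1000 + i)
    !shapiro_gate(rexp(100))
  }, TRUE)
  expect_gt(mean(reject), 0.95)
  expect_warning(flag <- shapiro_gate(rep(2, 10)), "constant")
  expect_false(flag)
})

test_that("ANCOVA tests the group term and reports adjusted means", {
  set.seed(4)
  n <- 60
  group <- rep(c("a", "b"), each = n / 2)
  age <- rnorm(n, 60, 8)
  y <- 2 + 0.1 * age + 0.8 * (group == "b") + rnorm(n, 0, 0.5)
  res <- ancova_group_compare(y, group, cbind(age = age))
  expect_equal(res$method, "ancova")
  expect_lt(res$p_value, 0.001)
  expect_equal(unname(diff(res$adjusted_means)), 0.8, tolerance = 0.3)
  # agrees with the textbook linear-model F test
  fit <- lm(y ~ factor(group) + age)
  expect_equal(res$f, summary(fit)$coefficients[2, "t value"]^2,
               tolerance = 1e-10)
  # a large covariate effect with no group effect is absorbed
  y0 <- 2 + 0.5 * age + rnorm(n, 0, 0.5)
  res0 <- ancova_group_compare(y0, group, cbind(age = age))
  expect_gt(res0$p_value, 0.01)
  expect_error(
    ancova_group_compare(y, group, cbind(age = age, age2 = 2 * age)),
    "age2")
})

test_that("the Quade rank ANCOVA is invariant to monotone transforms", {
  set.seed(8)
  n <- 50
  group <- rep(c("a", "b"), each = n / 2)
  cov <- rnorm(n)
  y <- 0.3 * cov + 0.8 * (group == "b") + rt(n, df = 2)
  r1 <- quade_rank_ancova(y, group, cbind(cov = cov))
  r2 <- quade_rank_ancova(exp(y), group, cbind(cov = cov))
  expect_equal(r1$f, r2$f, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$method, "quade")
  expect_error(quade_rank_ancova(rep(1, n), group, cbind(cov = cov)), "tied")
})

test_that("Quade detects a strong shift under exponential noise", {
  hits <- vapply(1:60, function(i) {
    set.seed(2000 + i)
    group <- rep(c("pd", "nc"), c(51, 30))
    cov <- rnorm(81)
    y <- rexp(81) + ifelse(group == "pd", 0, 1)
    quade_rank_ancova(y, group, cbind(cov = cov))$p_value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("chi-square matches the hand oracle on the printed sex table", {
  # PD 28 male / 23 female vs NC 11 male / 19 female
  res <- chi2_independence(matrix(c(28, 23, 11, 19), 2, byrow = TRUE))
  expect_equal(res$statistic, 2.515869424693, tolerance = 1e-9)
  expect_equal(res$p_value, 0.112705458313, tolerance = 1e-9)
  # perfect independence
  flat <- chi2_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # doubling all cells doubles the statistic
  res2 <- chi2_independence(2 * matrix(c(28, 23, 11, 19), 2, byrow = TRUE))
  expect_equal(res2$statistic, 2 * res$statistic, tolerance = 1e-9)
  expect_error(chi2_independence(matrix(c(0, 0, 5, 3), 2)), "marginal")
  expect_error(chi2_independence(matrix(c(1.5, 2, 5, 3), 2)), "integers")
})

test_that("partial correlation equals Pearson r with no covariates", {
  set.seed(3)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(pc$df, 38)
})

test_that("partial correlation equals the recursive-formula oracle", {
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  y <- c(2.3, 2.5, 4.6, 4.1, 6.4, 6.2)
  z <- c(1.2, 0.4, 2.1, 1.0, 2.5, 0.8)
  r_oracle <- (cor(x, y) - cor(x, z) * cor(y, z)) /
    sqrt((1 - cor(x, z)^2) * (1 - cor(y, z)^2))
  pc <- partial_correlation(x, y, cbind(z = z))
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  expect_equal(pc$df, 3)
  t_oracle <- r_oracle * sqrt(3) / sqrt(1 - r_oracle^2)
  expect_equal(pc$p_value, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-12)
})

test_that("a shared confounder is fully removed by adjustment", {
  set.seed(10)
  n <- 1e5
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)
  expect_gt(partial_correlation(x, y)$r, 0.4)       # confounded
  expect_lt(abs(partial_correlation(x, y, cbind(z = z))$r), 0.01)
})

test_that("ROC/AUC follows the Mann-Whitney construction", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("n", "p"), each = 3), positive = "p")$auc, 1.0)
  # uninformative scores
  set.seed(6)
  null_auc <- roc_auc(rnorm(4000), rep(c("n", "p"), 2000), positive = "p")$auc
  expect_lt(abs(null_auc - 0.5), 0.03)
  # ties count one half
  expect_equal(roc_auc(c(1, 1), c("n", "p"), positive = "p")$auc, 0.5)
  # the curve is monotone
  r <- roc_auc(rnorm(100), rep(c("n", "p"), 50), positive = "p")
  expect_true(all(diff(r$sensitivities) <= 0))
  expect_true(all(diff(r$specificities) >= 0))
  expect_error(roc_auc(1:5, rep("p", 5)), "two classes")
})

test_that("AUC agrees with pROC and the binormal closed form", {
  skip_if_not_installed("pROC")
  set.seed(12)
  n <- 5000
  scores <- c(rnorm(n, 1.45, 0.17), rnorm(n, 1.64, 0.17))
  labels <- rep(c("PD", "NC"), each = n)
  mine <- roc_auc(scores, labels, positive = "NC")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("PD", "NC"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
  expect_lt(abs(mine - pnorm(0.19 / (0.17 * sqrt(2)))),
            3 * sqrt(0.25 / n))  # generous MC band around the closed form
})

test_that("BH adjustment matches the step-up construction", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
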