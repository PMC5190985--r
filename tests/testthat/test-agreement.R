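test_that("perfect agreement gives the optimum of every metric", {
  rep <- agreement_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_identical(rep$rrmse, 0)
  expect_identical(rep$mae, 0)
  expect_identical(rep$ef, 1)
  expect_identical(rep$crm, 0)
  expect_equal(rep$r2, 1)
  expect_equal(rep$slope, 1)
  expect_equal(rep$intercept, 0)
})

test_that("metrics match hand computation on a shifted series", {
  rep <- agreement_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(rep$mae, 1)
  expect_equal(rep$rrmse, 50)
  expect_equal(rep$ef, -0.5)
  expect_equal(rep$crm, -0.5)
  expect_equal(rep$r2, 1)
})

test_that("CRM is positive under underestimation and antisymmetric", {
  obs <- c(1, 2, 3, 4)
  under <- agreement_metrics(obs, obs - 0.5)
  over <- agreement_metrics(obs, obs + 0.5)
  expect_gt(under$crm, 0)
  expect_lt(over$crm, 0)
  expect_equal(under$crm, -over$crm)
})

test_that("metric suite agrees with brute-force loops on random series", {
  withr::with_seed(51, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      obs <- runif(n, 0.1, 3)
      est <- obs * runif(1, 0.5, 1.5) + rnorm(n, sd = 0.3)
      rep <- agreement_metrics(obs, est)
      oracle <- brute_agreement(obs, est)
      for (m in names(oracle))
        expect_equal(rep[[m]], oracle[[m]], tolerance = 1e-10, label = m)
    }
  })
})

test_that("metrics are invariant under reordering of pairs", {
  withr::with_seed(52, {
    obs <- runif(12, 0.2, 3)
    est <- obs + rnorm(12, sd = 0.2)
    ord <- sample(12)
  })
  a <- agreement_metrics(obs, est)
  b <- agreement_metrics(obs[ord], est[ord])
  for (m in c("rrmse", "mae", "ef", "crm", "r2", "slope", "intercept"))
    expect_equal(a[[m]], b[[m]], label = m)
})

test_that("MAE never exceeds the RMSE implied by RRMSE", {
  withr::with_seed(53, {
    for (i in 1:30) {
      obs <- runif(10, 0.5, 3)
      est <- obs + rnorm(10, sd = 0.5)
      rep <- agreement_metrics(obs, est)
      rmse <- rep$rrmse * mean(obs) / 100
      expect_lte(rep$mae, rmse + 1e-12)
    }
  })
})

test_that("degenerate series raise informative errors", {
  expect_error(agreement_metrics(1:3, 1:2), "equal length")
  expect_error(agreement_metrics(1, 1), "at least two")
  expect_error(agreement_metrics(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(agreement_metrics(c(-1, 0, 1), c(1, 2, 3)), "mean of 'obs' is zero")
})

test_that("significance flag mirrors the correlation t-test", {
  obs <- seq(0.2, 3, length.out = 16)
  strong <- agreement_metrics(obs, obs * 1.1 + 0.05)
  expect_true(strong$significant)
  withr::with_seed(54, noise <- rnorm(16))
  weak <- agreement_metrics(obs, noise + 2)
  expect_false(weak$significant)
})

test_that("excluding a planted outlier reduces RRMSE", {
  obs <- c(seq(0.2, 1.4, length.out = 15), 2.84)
  est <- c(seq(0.2, 1.4, length.out = 15) * 1.05, 1.2)  # saturated estimate
  full <- agreement_metrics(obs, est)
  red <- exclude_outlier(obs, est, 16)
  expect_length(red$obs, 15)
  expect_equal(red$removed$index, 16)
  expect_equal(red$removed$obs, 2.84)
  reduced <- agreement_metrics(red$obs, red$est)
  expect_lt(reduced$rrmse, full$rrmse)
  expect_gt(reduced$r2, full$r2)
})

test_that("exclusion rules are enforced", {
  expect_error(exclude_outlier(1:2, 1:2, 1), "at least 3")
  expect_error(exclude_outlier(1:5, 1:5, 6), "out of range")
  # removing a collinear point keeps the rest perfectly collinear
  obs <- c(1, 2, 3, 4)
  red <- exclude_outlier(obs, 2 * obs, 2)
  expect_equal(agreement_metrics(red$obs, red$est)$r2, 1)
})
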