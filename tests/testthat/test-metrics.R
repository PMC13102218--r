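test_that("RMSE of discriminations matches its definition", {
  a <- c(0.8, 1.2, 2.0)
  expect_equal(rmse_a(a, a), 0)
  expect_equal(rmse_a(a + 0.1, a), 0.1)
  expect_equal(rmse_a(c(1.0, 2.0), c(1.3, 1.6)), sqrt(0.125))
  expect_error(rmse_a(1:2, 1:3), class = "grmsim_invalid_argument")
})

test_that("item-count correction follows sqrt(J/(J-1)) and tends to 1", {
  expect_equal(fpc_a(2), sqrt(2))
  expect_equal(fpc_a(10), sqrt(10 / 9))
  f <- sapply(c(2, 5, 10, 50, 500), fpc_a)
  expect_true(all(diff(f) < 0) && all(f > 1))
  expect_equal(fpc_a(1e6), 1, tolerance = 1e-6)
  expect_equal(fpc_a(10, correction = "raw"), 10 / 9)
  expect_error(fpc_a(1), class = "grmsim_invalid_argument")
})

test_that("standardized RMSE divides by the observed range", {
  expect_equal(rmse_a_standardized(0, c(0.5, 2.5)), 0)
  expect_equal(rmse_a_standardized(0.2, c(0.5, 2.5)), 0.1)
  # scale-consistency: common rescaling of deviations and range cancels
  expect_equal(rmse_a_standardized(0.2 * 3, c(0.5, 2.5) * 3),
               rmse_a_standardized(0.2, c(0.5, 2.5)))
  expect_error(rmse_a_standardized(0.1, c(1, 1)),
               class = "grmsim_undefined_standardization")
})

test_that("latent-trait RMSE and sampling-fraction correction behave", {
  th <- c(-1, 0, 2)
  expect_equal(rmse_theta(th, th), 0)
  expect_equal(rmse_theta(th + 0.4, th), 0.4)
  expect_equal(rmse_theta(c(0, 0), c(1, -1)), 1)
  expect_equal(fpc_theta(500, 500), 0)
  expect_equal(fpc_theta(500, 500000), sqrt(0.999))
  expect_equal(fpc_theta(1, 1e9), 1, tolerance = 1e-6)
  # at the study's 0.1% fraction the correction touches only the 3rd decimal
  expect_lt(1 - fpc_theta(500, 500000), 1e-3)
  expect_equal(fpc_theta(500, 500000, correction = "raw"), 0.999)
  expect_error(fpc_theta(10, 5), class = "grmsim_invalid_argument")
})

test_that("Pearson correlation matches its closed form and validates input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:2, 1:2), class = "grmsim_invalid_argument")
  expect_error(pearson_r(rep(1, 5), 1:5), class = "grmsim_undefined_correlation")
})

test_that("Fisher-z averaging is a fixed point, odd, and bounded by its inputs", {
  expect_equal(fisher_mean_r(rep(0.62, 7)), 0.62)
  expect_equal(fisher_mean_r(c(0.5, -0.5)), 0)
  expect_equal(fisher_mean_r(c(0.5, 0.9)), 0.7660773415974732, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:50) {
    rs <- runif(sample(2:10, 1), -0.95, 0.99)
    m <- fisher_mean_r(rs)
    expect_true(m >= min(rs) - 1e-12 && m <= max(rs) + 1e-12)
  }
  expect_error(fisher_mean_r(c(0.2, 1)), class = "grmsim_infinite_z")
})

test_that("agreement bands follow the stated cutpoints with strict upper bound", {
  expect_identical(classify_agreement(0.75), "high")
  expect_identical(classify_agreement(0.60), "moderate")
  expect_identical(classify_agreement(0.30), "low")
  expect_identical(classify_agreement(0.70), "moderate")
  expect_identical(classify_agreement(0.50), "moderate")
})

test_that("correction factorizations hold exactly in replication metrics", {
  lf <- cached_largen_fit()
  m <- replication_metrics(lf$fit, lf$theta, lf$bank$a, N_pop = 5000000)
  expect_identical(m$rmse_a_fpc, m$rmse_a * m$fpc_a)
  expect_identical(m$rmse_theta_fpc, m$rmse_theta * m$fpc_theta)
  expect_identical(m$rmse_a_std_fpc, m$rmse_a_std * m$fpc_a)
  expect_true(m$rmse_a >= 0 && m$r >= -1 && m$r <= 1)
  # standardized RMSE is invariant to the discrimination scale choice
  mc <- replication_metrics(lf$fit, lf$theta, lf$bank$a, N_pop = 5000000,
                            a_scale = "classic")
  expect_equal(m$rmse_a_std, mc$rmse_a_std, tolerance = 1e-12)
  expect_equal(mc$rmse_a * lf$fit$D, m$rmse_a, tolerance = 1e-12)
})

test_that("metrics are permutation-invariant", {
  set.seed(62)
  a_hat <- runif(8, 0.5, 2.5); a_true <- runif(8, 0.5, 2.5)
  perm <- sample(8)
  expect_equal(rmse_a(a_hat, a_true), rmse_a(a_hat[perm], a_true[perm]))
  x <- rnorm(30); y <- x + rnorm(30)
  perm <- sample(30)
  expect_equal(rmse_theta(y, x), rmse_theta(y[perm], x[perm]))
  expect_equal(pearson_r(x, y), pearson_r(x[perm], y[perm]))
})

test_that("posterior spread is consistent with observed EAP error", {
  lf <- cached_largen_fit()
  fit <- lf$fit
  # the discrete posterior's variance should track the squared EAP error
  mse <- mean((fit$theta_eap - lf$theta)^2)
  expect_lt(abs(mse - mean(fit$theta_psd^2)) / mse, 0.35)
})
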