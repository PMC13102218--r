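test_that("quadrature grids discretize the standard-normal prior", {
  q <- make_quadrature(61, 6)
  expect_equal(sum(q$weight), 1, tolerance = 1e-12)
  # symmetric nodes and weights
  expect_equal(q$node, -rev(q$node), tolerance = 1e-12)
  expect_equal(q$weight, rev(q$weight), tolerance = 1e-12)
  # prior moments
  expect_equal(sum(q$node * q$weight), 0, tolerance = 1e-12)
  expect_equal(sum(q$node^2 * q$weight), 1, tolerance = 1e-3)
  expect_error(make_quadrature(5), class = "grmsim_invalid_argument")
  expect_error(make_quadrature(21, -1), class = "grmsim_invalid_argument")
})

test_that("EM fits recover parameters at large n and ascend the likelihood", {
  lf <- cached_largen_fit()
  fit <- lf$fit
  expect_true(fit$converged)
  expect_true(all(fit$a1_hat > 0))
  expect_true(all(apply(fit$b_hat, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_lt(mean(abs(fit$a_hat - lf$bank$a)), 0.1)
  # EAP shrinkage toward the prior mean
  expect_lt(var(fit$theta_eap), var(lf$theta))
})

test_that("EM log-likelihood is nondecreasing on random small instances", {
  set.seed(51)
  for (i in 1:30) {
    K <- sample(2:5, 1)
    bank <- generate_item_bank(J = 3, K = K)
    resp <- simulate_responses(rnorm(60), bank)
    if (any(apply(resp, 2, function(x) length(unique(x))) == 1L)) next
    fit <- fit_grm(resp, K = K, max_cycles = 25)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("discrimination RMSE shrinks as the sample grows", {
  set.seed(52)
  bank <- generate_item_bank(J = 10, K = 5)
  rmse_at <- function(n) {
    resp <- simulate_responses(rnorm(n), bank)
    fit <- fit_grm(resp, K = 5)
    rmse_a(fit$a_hat, bank$a)
  }
  r1 <- rmse_at(1000)
  r2 <- rmse_at(5000)
  r3 <- rmse_at(20000)
  expect_true(r1 > r2 && r2 > r3)
})

test_that("degenerate and undersized inputs are rejected", {
  resp <- cbind(rep(0L, 100), sample(0:2, 100, replace = TRUE))
  expect_error(fit_grm(resp, K = 3), class = "grmsim_degenerate_item")
  expect_error(fit_grm(resp, K = 3), "1")  # names the offending item
  expect_error(fit_grm(matrix(0:1, 10, 4), K = 2),
               class = "grmsim_invalid_argument")
})

test_that("mirrored responses yield antisymmetric location estimates", {
  set.seed(53)
  K <- 4
  bank <- symmetric_bank(J = 4, K = K, a = 1.3)
  resp <- simulate_responses(rnorm(400), bank)
  mirrored <- rbind(resp, (K - 1L) - resp)
  fit <- fit_grm(mirrored, K = K, tol = 1e-6)
  # the mirrored dataset is invariant under category reversal, so the
  # fitted locations must be antisymmetric: b_k = -b_{K-k}
  expect_equal(fit$b_hat, -fit$b_hat[, (K - 1):1], tolerance = 5e-3)
})

test_that("EAP scores match a dense-quadrature brute-force oracle", {
  set.seed(54)
  bank <- generate_item_bank(J = 8, K = 5)
  patterns <- matrix(sample(0:4, 5 * 8, replace = TRUE), 5, 8)
  got <- eap_scores(patterns, bank)
  # independent brute force: direct likelihood on a 10,001-point grid
  grid <- seq(-6, 6, length.out = 10001)
  w <- dnorm(grid); w <- w / sum(w)
  b <- as.matrix(bank[paste0("b_", 1:4)])
  for (i in 1:5) {
    L <- rep(1, length(grid))
    for (j in 1:8) {
      P <- category_prob(grid, bank$a[j], b[j, ])
      L <- L * P[cbind(seq_along(grid), patterns[i, j] + 1L)]
    }
    eap <- sum(grid * w * L) / sum(w * L)
    expect_equal(got$theta_eap[i], eap, tolerance = 1e-3)
  }
})

test_that("EAP equals the prior mean for an information-free bank", {
  flat <- item_bank(a = rep(0, 4), b = t(replicate(4, c(-1, 0, 1))))
  resp <- matrix(sample(0:3, 40, replace = TRUE), 10, 4)
  sc <- eap_scores(resp, flat)
  expect_equal(sc$theta_eap, rep(0, 10), tolerance = 1e-12)
  expect_equal(sc$theta_psd, rep(sqrt(sum(make_quadrature()$node^2 *
                                            make_quadrature()$weight)), 10),
               tolerance = 1e-8)
})

test_that("reversed response patterns flip the EAP sign under a symmetric bank", {
  bank <- symmetric_bank(J = 5, K = 4)
  pat <- matrix(c(0L, 1L, 3L, 2L, 0L), 1)
  rev_pat <- 3L - pat
  s <- eap_scores(rbind(pat, rev_pat), bank)
  expect_equal(s$theta_eap[1], -s$theta_eap[2], tolerance = 1e-10)
})

test_that("simulating from a fitted bank reproduces category margins", {
  set.seed(55)
  bank <- generate_item_bank(J = 6, K = 4)
  theta <- rnorm(2000)
  resp <- simulate_responses(theta, bank)
  fit <- fit_grm(resp, K = 4)
  refit_bank <- item_bank(a = fit$a_hat, b = fit$b_hat, D = fit$D)
  resp2 <- simulate_responses(rnorm(2000), refit_bank)
  for (j in 1:6) {
    p <- tabulate(resp[, j] + 1L, 4) / 2000
    p2 <- tabulate(resp2[, j] + 1L, 4) / 2000
    se <- sqrt(pmax(p * (1 - p), 1e-4) / 2000)
    expect_true(all(abs(p - p2) < 3 * sqrt(2) * se + 0.02))
  }
})

test_that("fits expose tidy parameter tables and one-row summaries", {
  lf <- cached_largen_fit()
  td <- tidy(lf$fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 10L * 9L)   # J items x (a + 4 b + 4 d)
  expect_setequal(unique(td$term), c("a", paste0("b_", 1:4), paste0("d_", 1:4)))
  gl <- glance(lf$fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_identical(gl$n, 5000L)
})
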