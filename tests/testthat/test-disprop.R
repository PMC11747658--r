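test_that("ROR point estimate and Woolf interval match direct arithmetic", {
  # symmetric table: odds ratio exactly 1, interval spans 1
  r1 <- ror(10, 90, 10, 90)
  expect_equal(r1$ror, 1.0)
  expect_lt(r1$ci_low, 1)
  expect_gt(r1$ci_high, 1)
  # frozen values computed by hand: (5*9900)/(95*100), Woolf se, z = 1.959964
  r2 <- ror(5, 95, 100, 9900)
  expect_equal(r2$ror, 5.2105263, tolerance = 1e-6)
  expect_equal(r2$ci_low, 2.0752186, tolerance = 1e-6)
  expect_equal(r2$ci_high, 13.0827586, tolerance = 1e-6)
  expect_error(ror(-1, 2, 3, 4), "negative")
})

test_that("zero cells invalidate the estimate unless the Haldane flag is set", {
  r <- ror(0, 10, 5, 100)
  expect_false(r$valid)
  expect_true(is.na(r$ror))
  rh <- ror(0, 10, 5, 100, haldane = TRUE)
  expect_false(rh$valid)
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
})

test_that("ROR is reciprocal under swapping exposure columns and log-symmetric", {
  set.seed(4)
  a <- sample(1:50, 25, TRUE); b <- sample(1:500, 25, TRUE)
  c_ <- sample(1:50, 25, TRUE); d <- sample(1:5000, 25, TRUE)
  fwd <- ror(a, b, c_, d)
  rev <- ror(b, a, d, c_)
  expect_equal(rev$ror, 1 / fwd$ror, tolerance = 1e-12)
  expect_equal(rev$ci_low, 1 / fwd$ci_high, tolerance = 1e-12)
  expect_equal(rev$ci_high, 1 / fwd$ci_low, tolerance = 1e-12)
  # geometric mean of the bounds recovers the point estimate
  expect_equal(sqrt(fwd$ci_low * fwd$ci_high), fwd$ror, tolerance = 1e-9)
})

test_that("closed-form EBGM agrees with the quadrature oracle", {
  prior <- structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0,
                          beta2 = 4.0, P = 1 / 3, loglik = NA,
                          converged = TRUE, n_cells = NA),
                     class = "ebgm_prior")
  res <- ebgm_cell(5, 1, prior)
  expect_equal(log(res$ebgm), quad_posterior(5, 1, prior, "log_mean"),
               tolerance = 1e-6)
  expect_equal(res$ebgm05, quad_quantile(5, 1, prior, 0.05),
               tolerance = 1e-6)
  expect_equal(res$ebgm95, quad_quantile(5, 1, prior, 0.95),
               tolerance = 1e-6)
})

test_that("EBGM oracle equivalence holds across a small (N, E, theta) grid", {
  thetas <- list(c(1, 1, 3, 3, 0.5))
  grid <- expand.grid(N = c(0, 1, 3, 10, 60), E = c(0.3, 1, 5, 25))
  for (th in thetas) {
    prior <- structure(list(alpha1 = th[1], beta1 = th[2], alpha2 = th[3],
                            beta2 = th[4], P = th[5], loglik = NA,
                            converged = TRUE, n_cells = NA),
                       class = "ebgm_prior")
    res <- ebgm_cell(grid$N, grid$E, prior)
    for (i in seq_len(nrow(grid))) {
      expect_equal(log(res$ebgm[i]),
                   quad_posterior(grid$N[i], grid$E[i], prior, "log_mean"),
                   tolerance = 1e-6)
      expect_equal(res$ebgm05[i],
                   quad_quantile(grid$N[i], grid$E[i], prior, 0.05),
                   tolerance = 1e-6)
    }
  }
})

test_that("posterior quantiles are ordered and EBGM shrinks toward the null", {
  prior <- structure(list(alpha1 = 0.3, beta1 = 0.2, alpha2 = 2, beta2 = 2,
                          P = 0.25, loglik = NA, converged = TRUE,
                          n_cells = NA),
                     class = "ebgm_prior")
  set.seed(7)
  N <- rpois(2000, 4)
  E <- rgamma(2000, 2, 0.5) + 0.05
  res <- ebgm_cell(N, E, prior)
  expect_true(all(res$ebgm05 < res$ebgm))
  expect_true(all(res$ebgm < res$ebgm95))
  expect_true(all(res$ebgm > 0))
  # monotone in N at fixed E
  resN <- ebgm_cell(0:30, rep(2, 31), prior)
  expect_true(all(diff(resN$ebgm) > -1e-10))
  # large-count limit: posterior concentrates at N/E
  big <- ebgm_cell(1000, 1000, prior)
  expect_gt(big$ebgm, 0.9); expect_lt(big$ebgm, 1.1)
})

test_that("a null-fitted prior keeps EBGM between 1 and N/E for N > E", {
  set.seed(12)
  E <- rgamma(5000, 2, 1) + 0.1
  N <- rpois(5000, E)            # lambda = 1 everywhere
  prior <- fit_mgps_prior(N, E)
  res <- ebgm_cell(c(6, 12, 30), c(2, 4, 10), prior)
  expect_true(all(res$ebgm >= 1 - 1e-6))
  expect_true(all(res$ebgm <= c(3, 3, 3) + 1e-6))
  # dominant mixture component centred near the true lambda of 1
  means <- c(prior$alpha1 / prior$beta1, prior$alpha2 / prior$beta2)
  weights <- c(prior$P, 1 - prior$P)
  expect_gt(means[which.max(weights)], 0.8)
  expect_lt(means[which.max(weights)], 1.2)
})

test_that("hyperparameter fitting recovers the likelihood of the truth", {
  set.seed(5)
  th <- c(0.2, 0.1, 2.0, 4.0, 1 / 3)
  n <- 20000
  E <- rgamma(n, 2, 1) + 0.05
  comp <- runif(n) < th[5]
  lam <- ifelse(comp, rgamma(n, th[1], th[2]), rgamma(n, th[3], th[4]))
  N <- rpois(n, lam * E)
  fit <- fit_mgps_prior(N, E)
  expect_true(fit$converged)
  ll_truth <- pvsignal:::nbmix_loglik(th, N, E)
  expect_gte(fit$loglik, ll_truth - 1.0)
})

test_that("squashed fitting reproduces the exact likelihood optimum", {
  set.seed(6)
  E <- rgamma(4000, 2, 1) + 0.05
  N <- rpois(4000, E)
  f1 <- fit_mgps_prior(N, E)
  f2 <- fit_mgps_prior(N, E, squash = TRUE)
  ll2 <- pvsignal:::nbmix_loglik(c(f2$alpha1, f2$beta1, f2$alpha2, f2$beta2,
                                   f2$P), N, E)
  expect_lt(abs(ll2 - f1$loglik), 0.5)
})

test_that("degenerate prior inputs never crash", {
  p1 <- fit_mgps_prior(3, 1.5)
  expect_false(p1$converged)
  expect_true(all(unlist(p1[c("alpha1", "beta1", "alpha2", "beta2")]) > 0))
  expect_error(fit_mgps_prior(c(1, 2), c(1, -1)), "positive")
  expect_error(ebgm_cell(1, 0, p1), "E > 0")
})

test_that("the dual positivity criteria follow count, CI and EBGM05 rules", {
  rr <- tibble::tibble(ci_low = c(10, 10, 0.8, 1.2))
  eb <- tibble::tibble(ebgm05 = c(2.05, 3, 1.2, 1.9))
  cls <- classify_signals(a = c(2, 3, 50, 10), ror_result = rr,
                          ebgm_result = eb)
  expect_equal(cls$ror_positive, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cls$ebgm_positive, c(TRUE, TRUE, FALSE, FALSE))
  # strict mode needs more than min_count reports
  strict <- classify_signals(a = c(3, 4), ror_result = rr[1:2, ],
                             ebgm_result = eb[1:2, ], strict = TRUE)
  expect_equal(strict$ror_positive, c(FALSE, TRUE))
})
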