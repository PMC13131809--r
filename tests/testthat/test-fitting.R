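test_that("psychometric fit recovers a known curve and flags degeneracy", {
  set.seed(14)
  n <- 3000
  x <- runif(n, 0, 5)
  p <- 0.05 + 0.9 * pnorm((x - 1.5) / 0.7)
  r <- rbinom(n, 1, p)
  fit <- psychometric_fit(x, r)
  expect_false(fit$boundary)
  expect_equal(fit$mu, 1.5, tolerance = 0.15)
  expect_equal(fit$sigma, 0.7, tolerance = 0.2)
  # predictions are monotone in |x| and match at the midpoint
  xg <- seq(0, 6, by = 0.1)
  pred <- psychometric_predict(fit, xg)
  expect_true(all(diff(pred) >= -1e-12))
  expect_lt(abs(psychometric_predict(fit, 1.5) - 0.5), 0.05)

  # all-1 responses cannot constrain the curve: constant at the upper bound
  all1 <- psychometric_fit(x[1:50], rep(1, 50))
  expect_true(all1$boundary)
  expect_equal(psychometric_predict(all1, c(0, 3)), c(1, 1))
  expect_error(psychometric_fit(rep(1, 10), rbinom(10, 1, 0.5)), "distinct")
})

test_that("two shifted priors keep their shift sign after fitting", {
  set.seed(15)
  n <- 2500
  x <- runif(n, 0, 5)
  r_low <- rbinom(n, 1, 0.05 + 0.9 * pnorm((x - 2.0) / 0.7))
  r_high <- rbinom(n, 1, 0.05 + 0.9 * pnorm((x - 1.2) / 0.7))
  f_low <- psychometric_fit(x, r_low)
  f_high <- psychometric_fit(x, r_high)
  expect_gt(f_low$mu, f_high$mu)
})

test_that("negative log likelihood matches a streaming oracle", {
  banks <- gaussian_banks()
  par <- setNames(c(0.1, 0.1, 1, 2, 0.5, 1, 1, 1, 2.5, 0.2, 0.5, 0.8),
                  ssdprior:::free_param_names())
  tr <- simulate_fit_family(par, banks, n_trials = 400, seed = 2)

  # compiled kernel vs the plain-R reference path
  p_cpp <- ssdprior:::predict_combined(par, tr, banks)
  p_ref <- ssdprior:::predict_combined_ref(par, tr, banks)
  expect_equal(p_cpp, p_ref, tolerance = 1e-12)

  # streaming Bernoulli log likelihood recomputed trial by trial
  acc <- 0
  for (i in seq_len(nrow(tr))) {
    pi <- min(max(p_ref[i], 1e-9), 1 - 1e-9)
    acc <- acc - (tr$response[i] * log(pi) + (1 - tr$response[i]) * log(1 - pi))
  }
  expect_equal(negative_log_likelihood(par, tr, banks), acc,
               tolerance = 1e-9)

  # invariant to trial order
  perm <- sample(nrow(tr))
  expect_equal(negative_log_likelihood(par, tr[perm, ], banks),
               negative_log_likelihood(par, tr, banks), tolerance = 1e-9)

  # constant-1/2 prediction gives exactly n log 2
  flat <- gaussian_banks(midpoints = c(0, 0, 0), slope = 1,
                         floor = 0.5, ceiling = 0.5)
  expect_equal(negative_log_likelihood(par, tr, flat, w_bayes = 0),
               nrow(tr) * log(2), tolerance = 1e-9)

  # ill-posed widths are rejected
  bad <- par
  bad[["sigma_nojump_saccade_low"]] <- 3
  expect_error(negative_log_likelihood(bad, tr, banks), "ill-posed")
})

test_that("profile prefers truth over random parameter draws", {
  banks <- gaussian_banks()
  truth <- setNames(c(0.1, 0.1, 1, 2, 0.5, 1, 1, 1, 2.5, 0.2, 0.5, 0.8),
                    ssdprior:::free_param_names())
  tr <- simulate_fit_family(truth, banks, n_trials = 2000, seed = 33)
  nll_true <- negative_log_likelihood(truth, tr, banks)
  set.seed(34)
  nll_rand <- replicate(40, {
    sj <- runif(1, 1.5, 5)
    par <- setNames(c(runif(4, 0.05, 3), runif(4, 0.1, 0.9 * sj), sj,
                      sort(runif(3, 0.05, 0.95))),
                    ssdprior:::free_param_names())
    negative_log_likelihood(par, tr, banks)
  })
  expect_lte(nll_true, quantile(nll_rand, 0.1))
})

test_that("a refit of its own predictions cannot beat the fitted optimum", {
  banks <- gaussian_banks()
  truth <- setNames(c(0.2, 0.2, 1, 1.8, 0.5, 1, 1, 1, 2.5, 0.2, 0.5, 0.8),
                    ssdprior:::free_param_names())
  tr <- simulate_fit_family(truth, banks, n_trials = 900, seed = 44)
  fit <- fit_combined(tr, banks = banks, n_restarts = 3, seed = 1,
                      maxit = 150)
  expect_true(fit$converged)
  expect_true(is.finite(fit$nll))
  expect_length(fit$estimates, 12)
  # the optimum is at least as good on this sample as the generator
  expect_lte(fit$nll, negative_log_likelihood(truth, tr, banks))
  expect_s3_class(fit$restarts, "data.frame")
})

test_that("halving the data widens the spread of restart endpoints", {
  banks <- gaussian_banks()
  truth <- setNames(c(0.1, 0.1, 1, 2, 0.5, 1, 1, 1, 2.5, 0.2, 0.5, 0.8),
                    ssdprior:::free_param_names())
  full <- simulate_fit_family(truth, banks, n_trials = 2000, seed = 55)
  half <- full[seq_len(1000), ]
  est_prior <- function(tr, seeds) {
    vapply(seeds, function(s) {
      fit_combined(tr, banks = banks, n_restarts = 2, seed = s,
                   maxit = 120)$estimates[["prior_half"]]
    }, numeric(1))
  }
  spread_full <- diff(range(est_prior(full, 1:4)))
  spread_half <- diff(range(est_prior(half, 1:4)))
  expect_lte(spread_full, spread_half + 0.15)
})

test_that("association banks are built from the low-image-noise trials", {
  set.seed(77)
  truth <- ground_truth(behavioral_model = "logistic")
  tab <- gen_behavior(truth, n_trials = 3000, seed = 78,
                      include_half_prior = TRUE)
  ab <- association_banks(tab)
  expect_equal(dim(ab$banks), c(75, 3))
  expect_true(all(ab$banks >= 0 & ab$banks <= 1))
  # higher prior learns the higher association at small displacements
  small <- 1:20
  expect_gt(mean(ab$banks[small, 3]), mean(ab$banks[small, 1]))
})
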