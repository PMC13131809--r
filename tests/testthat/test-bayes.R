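test_that("decision criterion matches the closed form", {
  # variances chosen so sigma_J^2+sigma_t^2 = 2 and sigma_nJ^2+sigma_t^2 = 1:
  # criterion = log(2) / (1 - 1/2) = 2 log 2
  p <- bayes_params(sigma_t = 0.1, sigma_jump = sqrt(1.99),
                    sigma_nojump = sqrt(0.99), prior_jump = 0.5)
  expect_equal(decision_criterion(p), 2 * log(2), tolerance = 1e-12)

  # strong jump prior drives the criterion negative (always report jump)
  p_high <- bayes_params(0.1, sqrt(1.99), sqrt(0.99), 0.999)
  expect_lt(decision_criterion(p_high), 0)
  expect_equal(jump_probability(c(-2, 0, 5), p_high), c(1, 1, 1))

  # equal widths are rejected at construction (degenerate denominator)
  expect_error(bayes_params(0.1, 1, 1, 0.5), "exceed")
})

test_that("criterion agrees with the sign change of the posterior ratio", {
  # independent oracle: scan the log posterior ratio over xhat and find the
  # displacement where the preferred hypothesis flips
  p <- bayes_params(0.4, 5, 0.75, 0.3)
  vj <- p$sigma_jump^2 + p$sigma_t^2
  vn <- p$sigma_nojump^2 + p$sigma_t^2
  log_ratio <- function(xh) {
    stats::dnorm(xh, 0, sqrt(vj), log = TRUE) + log(p$prior_jump) -
      stats::dnorm(xh, 0, sqrt(vn), log = TRUE) - log(1 - p$prior_jump)
  }
  grid <- seq(0.001, 6, by = 1e-4)
  flip <- grid[which(diff(sign(log_ratio(grid))) != 0)[1]]
  expect_equal(flip^2, decision_criterion(p), tolerance = 1e-3)
})

test_that("jump probability reduces to the central chi-square tail at x = 0", {
  # with criterion 1 and unit sensory noise the report probability is the
  # two-sided standard normal tail beyond 1
  p <- bayes_params(sigma_t = 1, sigma_jump = 10, sigma_nojump = 0.1,
                    prior_jump = 0.5)
  xc2 <- decision_criterion(p)
  d0 <- 1 - pchisq(1, df = 1)
  expect_equal(d0, 2 * (1 - pnorm(1)), tolerance = 1e-12)
  # same identity through the package function with its own criterion
  expect_equal(jump_probability(0, p),
               2 * (1 - pnorm(sqrt(xc2) / p$sigma_t)), tolerance = 1e-10)
})

test_that("jump probability is a symmetric probability, increasing in |x|", {
  p <- bayes_params(0.65, 5, 0.75, 0.2)
  x <- seq(-6, 6, by = 0.25)
  d <- jump_probability(x, p)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, rev(d))  # exact symmetry
  curve <- psychometric_curve(p, seq(0, 8, by = 0.1))
  expect_true(all(diff(curve$p_jump) >= -1e-12))
  expect_gt(jump_probability(50, p), 0.999)
  expect_error(psychometric_curve(p, numeric(0)), "empty")
})

test_that("jump probability is nondecreasing in the prior at every x", {
  x <- seq(0, 4, by = 0.5)
  for (sig in list(c(0.4, 5, 0.1), c(0.9, 5, 0.75), c(0.1, 2.5, 1))) {
    priors <- seq(0.05, 0.95, by = 0.05)
    d <- sapply(priors, function(pj) {
      jump_probability(x, bayes_params(sig[1], sig[2], sig[3], pj))
    })
    expect_true(all(apply(d, 1, function(v) all(diff(v) >= -1e-12))))
  }
})

test_that("Monte-Carlo draws reproduce the decision probability", {
  # empirical fraction of percepts exceeding the criterion vs the
  # non-central chi-square tail, 5 settings at 1e5 draws
  set.seed(11)
  for (i in 1:5) {
    st <- runif(1, 0.2, 1.2)
    sj <- runif(1, 2, 6)
    sn <- runif(1, 0.1, 1.2)
    pj <- runif(1, 0.15, 0.85)
    x <- runif(1, 0, 3)
    p <- bayes_params(st, sj, sn, pj)
    d <- jump_probability(x, p)
    xc2 <- decision_criterion(p)
    draws <- rnorm(1e5, x, st)
    mc <- mean(draws^2 > xc2)
    se <- sqrt(max(d * (1 - d), 1e-12) / 1e5)
    expect_lt(abs(mc - d), 3 * se + 1e-9)
  }
})

test_that("Bayesian prior use is positive and needs matched noise fields", {
  lo <- bayes_params(0.4, 5, 0.75, 0.2)
  hi <- bayes_params(0.4, 5, 0.75, 0.8)
  pu <- bayes_prior_use(lo, hi)
  expect_gt(pu, 0)
  expect_equal(bayes_prior_use(lo, lo), 0)
  # single-point window reduces to a difference of two evaluations
  expect_equal(bayes_prior_use(lo, hi, window = c(0, 0)),
               jump_probability(0, hi) - jump_probability(0, lo))
  mismatched <- bayes_params(0.5, 5, 0.75, 0.8)
  expect_error(bayes_prior_use(lo, mismatched), "prior_jump")
})

test_that("prior use grows with both saccade and image noise (ideal observer)", {
  # over the stated noise grids the Bayesian prior-use surface is monotone
  for (st in c(0.4, 0.65, 0.9)) {
    pu <- vapply(c(0.1, 0.4, 0.75), function(sn) {
      bayes_prior_use(bayes_params(st, 5, sn, 0.2),
                      bayes_params(st, 5, sn, 0.8))
    }, numeric(1))
    expect_true(all(diff(pu) >= 0))
  }
  for (sn in c(0.1, 0.75)) {
    pu <- vapply(c(0.4, 0.65, 0.9), function(st) {
      bayes_prior_use(bayes_params(st, 5, sn, 0.2),
                      bayes_params(st, 5, sn, 0.8))
    }, numeric(1))
    expect_true(all(diff(pu) >= 0))
  }
})

test_that("parameter sets round-trip through JSON", {
  p <- bayes_params(0.4, 5, 0.75, 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  write_bayes_params(p, path)
  expect_equal(read_bayes_params(path), p)
})
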