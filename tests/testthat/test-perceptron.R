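test_that("input grid tiles the displacement range", {
  g <- input_grid()
  expect_equal(g$n_units, 75)
  expect_equal(g$centers[1], 0.05)
  expect_equal(g$centers[75], 7.45)
  expect_error(input_grid(bin_width = 0.4), "tile")
})

test_that("encoding is a normalized population code", {
  g <- input_grid()
  # zero noise gives a one-hot at the nearest bin
  a <- encode_input(1.02, 0, g)
  expect_equal(sum(a), 1)
  expect_equal(which(a == 1), 11)  # bin covering [1.0, 1.1)
  # total activation is always 1, for any x and noise, including values
  # beyond the range (mass piles at the clamped edge)
  for (x in c(-2, 0, 0.32, 3.7, 9)) {
    for (s in c(0.1, 1, 2)) {
      expect_equal(sum(encode_input(x, s, g)), 1, tolerance = 1e-12)
    }
  }
  # activation at x = 0 decreases monotonically away from the edge; oracle
  # is the truncated-Gaussian density at bin centers, brute-force normalized
  a0 <- encode_input(0, 1, g)
  expect_true(all(diff(a0) <= 0))
  oracle <- dnorm(g$centers, 0, 1)
  expect_equal(a0, oracle / sum(oracle), tolerance = 1e-12)
})

test_that("forward pass normalizes the two outputs", {
  net <- perceptron_net()
  g <- net$grid
  # all-equal weights give exactly (0.5, 0.5)
  o <- net_forward(net, encode_input(2, 0.5, g), 0.2)
  expect_equal(unname(o), c(0.5, 0.5))
  # one-hot input reduces to the row weights, normalized
  net$weights[["0.8"]][30, ] <- c(0.9, 0.3)
  oh <- encode_input(g$centers[30], 0, g)
  expect_equal(unname(net_forward(net, oh, 0.8)),
               c(0.9, 0.3) / 1.2)
  # property over random nonnegative weights and valid activations
  set.seed(4)
  for (i in 1:25) {
    net$weights[["0.2"]] <- matrix(runif(150), ncol = 2)
    act <- encode_input(runif(1, 0, 7.5), runif(1, 0.05, 2), g)
    o <- net_forward(net, act, 0.2)
    expect_equal(sum(o), 1, tolerance = 1e-12)
    expect_true(all(o >= 0 & o <= 1))
  }
  # degenerate zero weights are an error, not NaN
  net$weights[["0.2"]][] <- 0
  expect_error(net_forward(net, oh, 0.2), "degenerate")
})

test_that("training step implements the error-based rule", {
  net <- perceptron_net(learning_rate = 0.5)
  g <- net$grid
  oh <- encode_input(g$centers[10], 0, g)
  # from the symmetric start o = (0.5, 0.5); a jump trial moves the hot
  # bin's weights by +0.25 / -0.25
  net2 <- net_train_step(net, oh, jump = TRUE, prior = 0.2)
  dw <- net2$weights[["0.2"]] - net$weights[["0.2"]]
  expect_equal(dw[10, ], c(jump = 0.25, nojump = -0.25))
  expect_true(all(dw[-10, ] == 0))
  # the other prior's bank is untouched
  expect_equal(net2$weights[["0.8"]], net$weights[["0.8"]])
  # zero learning rate changes nothing
  net0 <- perceptron_net(learning_rate = 0)
  expect_equal(net_train_step(net0, oh, TRUE, 0.2)$weights, net0$weights)
  # output already at the desired state gives zero change
  sat <- net
  sat$weights[["0.2"]][10, ] <- c(1, 0)
  out <- net_forward(sat, oh, 0.2)
  expect_equal(unname(out), c(1, 0))
  expect_equal(net_train_step(sat, oh, TRUE, 0.2)$weights[["0.2"]],
               sat$weights[["0.2"]])
})

test_that("training yields monotone jump outputs and prior separation", {
  set.seed(21)
  params <- combined_params()
  net <- perceptron_net(learning_rate = 0.5)
  trials <- data.frame(prior = sample(c(0.2, 0.8), 1000, TRUE))
  jump <- runif(1000) < trials$prior
  trials$x <- abs(rnorm(1000, 0, ifelse(jump, 2.5, 0.2)))
  trials$jump <- jump
  net <- net_train(net, trials, noise_sigma = 0.1)
  # monotone trend over the displacement range the training actually
  # covered (bins far beyond the jump distribution stay near their
  # symmetric initialization)
  xg <- seq(0.25, 4, by = 0.25)
  for (pr in c(0.2, 0.8)) {
    o <- net_jump_output(net, xg, 0.1, pr)
    fit <- lm(o ~ xg)
    expect_gt(coef(fit)[2], 0)
    expect_gt(mean(o[xg > 2.5]), mean(o[xg < 1]))
  }
  # higher prior learns a higher jump output at small displacements
  expect_gt(mean(net_jump_output(net, seq(0, 2, 0.1), 0.1, 0.8)),
            mean(net_jump_output(net, seq(0, 2, 0.1), 0.1, 0.2)))
})

test_that("all-jump training drives the jump output toward 1", {
  set.seed(3)
  net <- perceptron_net(learning_rate = 0.5)
  trials <- data.frame(x = runif(300, 0, 4), jump = TRUE, prior = 0.8)
  net <- net_train(net, trials, noise_sigma = 0.5)
  expect_gt(min(net_jump_output(net, c(0.5, 1, 2, 3), 0.5, 0.8)), 0.95)
})

test_that("image noise at test collapses the learned prior difference", {
  # trained at low noise; the prior gap in the jump output over 0-2 deg
  # shrinks as the encoding noise rises through 0.1, 1, 2 deg
  set.seed(8)
  params <- combined_params()
  net <- perceptron_net(learning_rate = 0.5)
  trials <- data.frame(prior = sample(c(0.2, 0.8), 1500, TRUE))
  jump <- runif(1500) < trials$prior
  trials$x <- abs(rnorm(1500, 0, ifelse(jump, 2.5, 0.2)))
  trials$jump <- jump
  net <- net_train(net, trials, noise_sigma = 0.1)
  xg <- seq(0, 2, by = 0.1)
  gaps <- vapply(c(0.1, 1, 2), function(s) {
    mean(net_jump_output(net, xg, s, 0.8) - net_jump_output(net, xg, s, 0.2))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("weights round-trip through JSON", {
  set.seed(5)
  net <- perceptron_net()
  net$weights[["0.2"]] <- matrix(runif(150), ncol = 2,
                                 dimnames = list(NULL, c("jump", "nojump")))
  path <- withr::local_tempfile(fileext = ".json")
  write_net_weights(net, path)
  back <- read_net_weights(perceptron_net(), path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
})
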