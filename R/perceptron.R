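#' Input grid of the category-learning network
#'
#' Displacement magnitudes are encoded by a bank of input units tiling
#' 0 to 7.5 degrees in 0.1-degree bins (75 units). Activation is a truncated
#' Gaussian over bin centers, renormalized so total input activation is
#' always 1.
#'
#' @param bin_width Bin width, degrees.
#' @param range Length-2 displacement range, degrees.
#' @return An object of class `input_grid` with bin `centers`.
#' @export
input_grid <- function(bin_width = 0.1, range = c(0, 7.5)) {
  n_units <- round(diff(range) / bin_width)
  if (!isTRUE(all.equal(n_units * bin_width, diff(range)))) {
    stop("bins must tile the range exactly")
  }
  structure(list(bin_width = bin_width, range = range, n_units = n_units,
                 centers = range[1] + (seq_len(n_units) - 0.5) * bin_width),
            class = "input_grid")
}

#' Population-code encoding of a displacement
#'
#' The activation of unit i is the Gaussian density centered at `|x|` with SD
#' `noise_sigma`, evaluated at the unit's bin center, truncated to the grid
#' range and renormalized to sum to 1. Zero noise gives a one-hot activation
#' at the nearest bin; displacements beyond the range are clamped to the
#' boundary so activation mass piles at the edge.
#'
#' @param x Displacement, signed degrees (the network codes magnitude).
#' @param noise_sigma Sensory noise SD, degrees (>= 0).
#' @param grid An [input_grid()].
#' @return Numeric activation vector summing to 1.
#' @export
encode_input <- function(x, noise_sigma, grid = input_grid()) {
  stopifnot(noise_sigma >= 0, length(x) == 1L)
  x <- min(max(abs(x), grid$range[1]), grid$range[2])
  if (noise_sigma == 0) {
    a <- numeric(grid$n_units)
    a[which.min(abs(grid$centers - x))] <- 1
    return(a)
  }
  a <- stats::dnorm(grid$centers, mean = x, sd = noise_sigma)
  a / sum(a)
}

#' A two-layer perceptron-like category-learning network
#'
#' One weight matrix (`n_units` inputs by two outputs, jump and no-jump) per
#' prior condition: each cued prior has its own set of inputs, so training
#' under one prior never changes another prior's weights. Weights start at a
#' symmetric positive constant, which makes the initial output exactly
#' (0.5, 0.5) for any input.
#'
#' @param priors Numeric vector of cued prior levels indexing weight banks.
#' @param learning_rate Learning rate (beta) of the error-based update.
#' @param grid An [input_grid()].
#' @param init_weight Initial value of every weight.
#' @return An object of class `perceptron_net`.
#' @export
perceptron_net <- function(priors = c(0.2, 0.8), learning_rate = 0.5,
                           grid = input_grid(), init_weight = 0.5) {
  stopifnot(length(priors) >= 1, learning_rate >= 0, init_weight > 0)
  weights <- lapply(priors, function(p) {
    matrix(init_weight, nrow = grid$n_units, ncol = 2,
           dimnames = list(NULL, c("jump", "nojump")))
  })
  names(weights) <- format_prior(priors)
  structure(list(weights = weights, learning_rate = learning_rate,
                 grid = grid),
            class = "perceptron_net")
}

format_prior <- function(p) formatC(p, format = "g")

#' Forward pass of the network
#'
#' Output-unit activation is the weighted sum of input activations; the final
#' outputs are normalized so the jump and no-jump outputs sum to 1.
#'
#' @param net A [perceptron_net()].
#' @param act Input activation vector (from [encode_input()]).
#' @param prior Cued prior selecting the weight bank.
#' @return Named numeric vector `c(jump = , nojump = )` summing to 1.
#' @export
net_forward <- function(net, act, prior) {
  W <- net_weights(net, prior)
  aj <- as.vector(act %*% W)
  tot <- sum(aj)
  if (tot == 0) stop("degenerate weights: output activations sum to zero")
  out <- aj / tot
  names(out) <- c("jump", "nojump")
  out
}

net_weights <- function(net, prior) {
  key <- format_prior(prior)
  W <- net$weights[[key]]
  if (is.null(W)) stop("no weight bank for prior ", prior)
  W
}

#' One error-based weight update
#'
#' Applies the perceptron-like rule: the weight from input i to output j
#' changes by `beta * a_i * (d_j - o_j)`, where the desired outputs are (1, 0)
#' on jump trials and (0, 1) on non-jump trials. Only the cued prior's weight
#' bank is touched.
#'
#' @param net A [perceptron_net()].
#' @param act Input activation vector.
#' @param jump Logical label: did the probe jump?
#' @param prior Cued prior selecting the weight bank.
#' @return The updated network.
#' @export
net_train_step <- function(net, act, jump, prior) {
  o <- net_forward(net, act, prior)
  d <- if (isTRUE(jump)) c(1, 0) else c(0, 1)
  key <- format_prior(prior)
  net$weights[[key]] <- net$weights[[key]] +
    net$learning_rate * outer(act, d - o)
  net
}

#' Train the network on a trial sequence
#'
#' Sequentially encodes and updates in the given trial order; deterministic
#' given the trial table (encoding itself is noise-width-parameterized but
#' not stochastic).
#'
#' @param net A [perceptron_net()].
#' @param trials Data frame with columns `x` (displacement, degrees), `jump`
#'   (logical) and `prior` (cued prior level).
#' @param noise_sigma Encoding noise SD during training, degrees.
#' @return The trained network.
#' @export
net_train <- function(net, trials, noise_sigma) {
  stopifnot(nrow(trials) > 0)
  for (i in seq_len(nrow(trials))) {
    act <- encode_input(trials$x[i], noise_sigma, net$grid)
    net <- net_train_step(net, act, trials$jump[i], trials$prior[i])
  }
  net
}

#' Network output for a batch of displacements
#'
#' Vectorized forward pass: encodes each displacement at the given noise
#' level and returns the jump output.
#'
#' @param net A [perceptron_net()].
#' @param x Displacements, degrees.
#' @param noise_sigma Encoding noise SD, degrees.
#' @param prior Cued prior selecting the weight bank.
#' @return Numeric vector of jump-output probabilities.
#' @export
net_jump_output <- function(net, x, noise_sigma, prior) {
  W <- net_weights(net, prior)
  A <- encode_matrix(x, noise_sigma, net$grid)
  out <- A %*% W
  as.vector(out[, 1] / rowSums(out))
}

# Trial-by-bin activation matrix (each row sums to 1).
encode_matrix <- function(x, noise_sigma, grid = input_grid()) {
  x <- pmin(pmax(abs(x), grid$range[1]), grid$range[2])
  if (noise_sigma == 0) {
    A <- matrix(0, length(x), grid$n_units)
    idx <- vapply(x, function(xi) which.min(abs(grid$centers - xi)), integer(1))
    A[cbind(seq_along(x), idx)] <- 1
    return(A)
  }
  A <- exp(-outer(x, grid$centers, "-")^2 / (2 * noise_sigma^2))
  A / rowSums(A)
}

#' Serialize trained weights as JSON
#'
#' Weights are stored as one matrix per prior bank, rows by input bin and
#' columns `jump`, `nojump`.
#'
#' @param net A [perceptron_net()].
#' @param path File path.
#' @export
write_net_weights <- function(net, path) {
  jsonlite::write_json(lapply(net$weights, unname), path, digits = NA)
  invisible(path)
}

#' @rdname write_net_weights
#' @param net Template network whose banks are replaced by the stored values.
#' @export
read_net_weights <- function(net, path) {
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(sort(names(w)), sort(names(net$weights))))
  for (k in names(w)) {
    m <- w[[k]]
    dimnames(m) <- list(NULL, c("jump", "nojump"))
    net$weights[[k]] <- m
  }
  net
}
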