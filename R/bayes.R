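#' Parameters of the Bayesian ideal observer
#'
#' The observer decides whether a probe jumped during a saccade from a noisy
#' percept of its displacement. `sigma_t` is the sensory (image) uncertainty
#' about the true displacement, `sigma_jump` and `sigma_nojump` are the widths
#' of the zero-mean displacement distributions under the jump and non-jump
#' hypotheses, and `prior_jump` is the prior probability of a jump.
#'
#' @param sigma_t Image/probe uncertainty, degrees (> 0).
#' @param sigma_jump Width of the jump displacement distribution, degrees.
#' @param sigma_nojump Width of the non-jump distribution, degrees; must be
#'   smaller than `sigma_jump` for a well-posed criterion.
#' @param prior_jump Prior probability of a jump, in (0, 1).
#' @return An object of class `bayes_params`.
#' @export
bayes_params <- function(sigma_t, sigma_jump, sigma_nojump, prior_jump) {
  stopifnot(sigma_t > 0, sigma_jump > 0, sigma_nojump > 0,
            prior_jump > 0, prior_jump < 1)
  if (sigma_jump <= sigma_nojump) {
    stop("`sigma_jump` must exceed `sigma_nojump` for a well-posed criterion")
  }
  structure(list(sigma_t = sigma_t, sigma_jump = sigma_jump,
                 sigma_nojump = sigma_nojump, prior_jump = prior_jump),
            class = "bayes_params")
}

#' Squared decision criterion of the ideal observer
#'
#' The observer reports "jumped" when the squared perceived displacement
#' exceeds
#' \deqn{\hat{x}_C^2 = \frac{\log\frac{\sigma_J^2+\sigma_t^2}{\sigma_{\neg J}^2+\sigma_t^2}
#'   + 2\log\frac{1-P(J)}{P(J)}}
#'   {\frac{1}{\sigma_{\neg J}^2+\sigma_t^2} - \frac{1}{\sigma_J^2+\sigma_t^2}}}
#' The criterion can be negative (strong jump prior), in which case every
#' percept exceeds it and the observer always reports a jump.
#'
#' @param params A [bayes_params()] object.
#' @return The squared criterion, degrees squared (possibly negative).
#' @export
decision_criterion <- function(params) {
  stopifnot(inherits(params, "bayes_params"))
  vj <- params$sigma_jump^2 + params$sigma_t^2
  vn <- params$sigma_nojump^2 + params$sigma_t^2
  if (vj == vn) stop("criterion undefined: sigma_jump equals sigma_nojump")
  num <- log(vj / vn) +
    2 * log((1 - params$prior_jump) / params$prior_jump)
  den <- 1 / vn - 1 / vj
  num / den
}

#' Probability that the ideal observer reports "jumped"
#'
#' With a Gaussian percept \eqn{\hat{x} \sim N(x, \sigma_t^2)},
#' \eqn{\hat{x}^2/\sigma_t^2} is non-central chi-square with 1 df and
#' non-centrality \eqn{x^2/\sigma_t^2}, so the report probability is the upper
#' tail of that distribution above the scaled criterion. A non-positive
#' criterion yields probability exactly 1. The result is symmetric in
#' \eqn{x \leftrightarrow -x}.
#'
#' @param x True displacement(s), signed degrees.
#' @param params A [bayes_params()] object.
#' @return Probability vector in `[0, 1]`, one element per displacement.
#' @export
jump_probability <- function(x, params) {
  xc2 <- decision_criterion(params)
  if (xc2 <= 0) return(rep(1, length(x)))
  s2 <- params$sigma_t^2
  1 - stats::pchisq(xc2 / s2, df = 1, ncp = x^2 / s2)
}

#' Psychometric curve of the ideal observer
#'
#' @param params A [bayes_params()] object.
#' @param displacements Nonempty grid of displacements, degrees.
#' @return Data frame with columns `displacement` and `p_jump`; `p_jump` is
#'   nondecreasing in `|displacement|`.
#' @export
psychometric_curve <- function(params, displacements) {
  if (length(displacements) == 0) stop("displacement grid is empty")
  data.frame(displacement = displacements,
             p_jump = jump_probability(displacements, params))
}

#' Bayesian prior use over a displacement window
#'
#' Prior use is the mean difference between the high-prior and low-prior
#' psychometric curves over small displacements (0 to 2 degrees by default),
#' the behavioral measure used throughout. The two parameter sets must differ
#' only in their prior.
#'
#' @param params_low,params_high [bayes_params()] differing only in
#'   `prior_jump` (low vs high).
#' @param window Length-2 interval of displacement magnitudes, degrees.
#' @param step Grid step within the window, degrees.
#' @return Scalar mean curve difference (high minus low prior).
#' @export
bayes_prior_use <- function(params_low, params_high,
                            window = c(0, 2), step = 0.05) {
  stopifnot(inherits(params_low, "bayes_params"),
            inherits(params_high, "bayes_params"))
  same <- c("sigma_t", "sigma_jump", "sigma_nojump")
  if (!isTRUE(all.equal(params_low[same], params_high[same]))) {
    stop("parameter sets must differ only in `prior_jump`")
  }
  grid <- seq(window[1], window[2], by = step)
  mean(jump_probability(grid, params_high) - jump_probability(grid, params_low))
}

#' Read/write Bayesian observer parameters as JSON
#'
#' @param params A [bayes_params()] object.
#' @param path File path.
#' @export
write_bayes_params <- function(params, path) {
  stopifnot(inherits(params, "bayes_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bayes_params
#' @export
read_bayes_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bayes_params(x$sigma_t, x$sigma_jump, x$sigma_nojump, x$prior_jump)
}
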