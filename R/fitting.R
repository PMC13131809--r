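#' Maximum-likelihood psychometric curve fit
#'
#' Fits the probability of a "jumped" report as a function of displacement
#' magnitude with a cumulative Gaussian bracketed by guess and lapse rates,
#' \eqn{\psi(x) = \gamma + (1-\gamma-\lambda)\,\Phi((|x|-\mu)/\sigma)},
#' by minimizing the Bernoulli negative log likelihood. Guess and lapse are
#' constrained to `[0, 0.5]`. Degenerate data in which every response is the
#' same cannot constrain the curve; the fit is then flagged `boundary` and
#' predicts the constant observed rate.
#'
#' @param x Displacements, degrees (the magnitude is used).
#' @param response Binary responses (1 = reported "jumped").
#' @return Object of class `psychometric_fit` with fields `mu`, `sigma`,
#'   `guess`, `lapse`, `nll`, `converged`, `boundary`.
#' @export
psychometric_fit <- function(x, response) {
  stopifnot(length(x) == length(response), all(response %in% c(0, 1)))
  x <- abs(x)
  if (length(unique(x)) < 2) stop("need at least 2 distinct |displacement| values")
  if (length(unique(response)) == 1L) {
    return(structure(list(mu = NA_real_, sigma = NA_real_,
                          guess = NA_real_, lapse = NA_real_,
                          constant = mean(response), nll = 0,
                          converged = TRUE, boundary = TRUE),
                     class = "psychometric_fit"))
  }
  nll <- function(th) {
    g <- stats::plogis(th[3]) * 0.5
    l <- stats::plogis(th[4]) * 0.5
    p <- g + (1 - g - l) * stats::pnorm((x - th[1]) / exp(th[2]))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(response * log(p) + (1 - response) * log(1 - p))
  }
  start <- c(stats::median(x), log(max(stats::sd(x), 0.1)),
             stats::qlogis(0.1), stats::qlogis(0.1))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 1000))
  structure(list(mu = opt$par[1], sigma = exp(opt$par[2]),
                 guess = stats::plogis(opt$par[3]) * 0.5,
                 lapse = stats::plogis(opt$par[4]) * 0.5,
                 constant = NA_real_, nll = opt$value,
                 converged = opt$convergence == 0, boundary = FALSE),
            class = "psychometric_fit")
}

#' Evaluate a fitted psychometric curve
#'
#' @param fit A [psychometric_fit()] object.
#' @param x Displacements, degrees.
#' @return Predicted report probabilities (monotone in `|x|`).
#' @export
psychometric_predict <- function(fit, x) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (fit$boundary) return(rep(fit$constant, length(x)))
  fit$guess + (1 - fit$guess - fit$lapse) *
    stats::pnorm((abs(x) - fit$mu) / fit$sigma)
}

#' Per-prior association banks from psychometric fits
#'
#' Instantiates the perceptron component of the fitted model: for each cued
#' prior, the input-to-jump association at every input-grid bin center is set
#' to the psychometric curve fitted to that prior's trials. Only the two
#' low-image-noise conditions (no-saccade and common) are used to estimate
#' the association, so that the condition-specific encoding blur applied at
#' prediction time is not double-counted.
#'
#' @param trials Session trial table with columns `condition`, `prior`,
#'   displacement (`displacement` or `displacement_deg`) and `response`.
#' @param priors Cued prior levels (bank order).
#' @param grid An [input_grid()].
#' @return List with `banks` (bin-by-prior matrix of association values),
#'   `fits` (the psychometric fits) and `priors`.
#' @export
association_banks <- function(trials, priors = c(0.2, 0.5, 0.8),
                              grid = input_grid()) {
  disp <- if ("displacement" %in% names(trials)) trials$displacement
          else trials$displacement_deg
  cond <- as.character(trials$condition)
  low <- cond %in% c("no_saccade", "saccade_low")
  fits <- lapply(priors, function(pr) {
    m <- low & trials$prior == pr
    if (sum(m) == 0) stop("no low-image-noise trials for prior ", pr)
    psychometric_fit(disp[m], trials$response[m])
  })
  banks <- vapply(fits, function(f) psychometric_predict(f, grid$centers),
                  numeric(grid$n_units))
  list(banks = banks, fits = fits, priors = priors)
}

free_param_names <- function() {
  c(paste0("sigma_t_", condition_levels()),
    paste0("sigma_nojump_", condition_levels()),
    "sigma_jump", "prior_low", "prior_half", "prior_high")
}

check_free_params <- function(par) {
  stopifnot(is.numeric(par), length(par) == 12L)
  if (is.null(names(par))) names(par) <- free_param_names()
  stopifnot(identical(names(par), free_param_names()))
  if (any(par[1:9] <= 0)) stop("sigmas must be positive")
  if (any(par[10:12] <= 0 | par[10:12] >= 1)) stop("priors must be in (0,1)")
  par
}

# Prediction of the fitted combined model for a trial table; thin wrapper
# over the compiled kernel. Trials must carry condition, prior, displacement.
predict_combined <- function(par, trials, banks, w_bayes = 0.1,
                             sigma_t_bayes = 0.1, grid = input_grid()) {
  par <- check_free_params(par)
  disp <- if ("displacement" %in% names(trials)) trials$displacement
          else trials$displacement_deg
  cond_idx <- match(as.character(trials$condition), condition_levels())
  prior_idx <- match(trials$prior, banks$priors)
  if (anyNA(cond_idx) || anyNA(prior_idx)) {
    stop("trials contain conditions or priors outside the fitted grid")
  }
  if (any(par[5:8] >= par[["sigma_jump"]])) {
    stop("sigma_nojump must stay below sigma_jump (criterion ill-posed)")
  }
  combined_predict_cpp(abs(disp), cond_idx, prior_idx,
                       par[1:4], par[5:8], par[["sigma_jump"]],
                       banks$priors, sigma_t_bayes, w_bayes,
                       banks$banks, grid$centers,
                       grid$range[1], grid$range[2])
}

# Pure-R reference for the compiled kernel; used as a cross-check in tests.
predict_combined_ref <- function(par, trials, banks, w_bayes = 0.1,
                                 sigma_t_bayes = 0.1, grid = input_grid()) {
  par <- check_free_params(par)
  disp <- abs(if ("displacement" %in% names(trials)) trials$displacement
              else trials$displacement_deg)
  p <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    ci <- match(as.character(trials$condition[i]), condition_levels())
    pi <- match(trials$prior[i], banks$priors)
    bp <- bayes_params(sigma_t_bayes, par[["sigma_jump"]], par[4 + ci],
                       par[9 + pi])
    ob <- jump_probability(disp[i], bp)
    a <- encode_input(disp[i], par[ci], grid)
    op <- sum(a * banks$banks[, pi])
    p[i] <- combined_output(ob, op, w_bayes)
  }
  p
}

#' Negative log likelihood of the combined model
#'
#' Bernoulli negative log likelihood of the binary responses under the
#' combined-model prediction, with probabilities clamped to
#' `[1e-9, 1 - 1e-9]` so the value is always finite. Invariant to trial
#' order.
#'
#' @param par Named 12-parameter vector (see [fit_combined()]): per-condition
#'   image noise (4), per-condition non-jump width (4), jump width (1) and
#'   the three fitted priors.
#' @param trials Session trial table.
#' @param banks Association banks from [association_banks()].
#' @param w_bayes Bayesian weight (fixed during fitting).
#' @param sigma_t_bayes Bayesian image noise, degrees (pinned).
#' @return Scalar negative log likelihood.
#' @export
negative_log_likelihood <- function(par, trials, banks, w_bayes = 0.1,
                                    sigma_t_bayes = 0.1) {
  p <- predict_combined(par, trials, banks, w_bayes, sigma_t_bayes)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  r <- trials$response
  -sum(r * log(p) + (1 - r) * log(1 - p))
}

#' Fit the 12-parameter combined model to a session
#'
#' Bounded maximum-likelihood estimation of the combined model's free
#' parameters: the image noise and the non-jump width for each of the four
#' noise conditions, the jump-distribution width, and the three priors. The
#' perceptron component is instantiated from psychometric curves fitted per
#' prior ([association_banks()]); the Bayesian weight is fixed (0.1 by
#' default, overridable). Optimization is bounded quasi-Newton (L-BFGS-B on
#' log-sigma / logit-prior scale) from one canonical start (protocol default
#' values) plus seeded random restarts, followed by a Nelder-Mead polish of
#' the best endpoint.
#'
#' @param trials Session trial table (should pass the inclusion filter).
#' @param w_bayes Fixed Bayesian weight.
#' @param sigma_t_bayes Pinned Bayesian image noise, degrees.
#' @param banks Association banks. `NULL` (the default) estimates them from
#'   the session's psychometric curves, the procedure used on real data.
#'   Parameter-recovery experiments pass the generating banks instead, so
#'   that the recovery isolates the 12 free parameters rather than the bank
#'   estimate (a data-estimated bank partially absorbs the Bayesian
#'   component, which is a known leak of the procedure).
#' @param n_restarts Total number of starts (including the canonical one).
#' @param seed Integer seed for the restart draws; the fit is deterministic
#'   given the seed.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param sigma_bounds,prior_bounds Box constraints on the natural scale.
#' @return List of class `combined_fit`: `estimates` (named 12-vector),
#'   `nll`, `converged`, `restarts` (per-start endpoints for diagnostics),
#'   `banks`, `w_bayes`, `seed`. If no restart converges the result carries
#'   `converged = FALSE` rather than an error.
#' @export
fit_combined <- function(trials, w_bayes = 0.1, sigma_t_bayes = 0.1,
                         banks = NULL,
                         n_restarts = 8, seed = 1, maxit = 300,
                         sigma_bounds = c(0.01, 10),
                         prior_bounds = c(0.01, 0.99)) {
  if (is.null(banks)) banks <- association_banks(trials)
  theta_to_par <- function(theta) {
    stats::setNames(c(exp(theta[1:9]), stats::plogis(theta[10:12])),
                    free_param_names())
  }
  lower <- c(rep(log(sigma_bounds[1]), 9), rep(stats::qlogis(prior_bounds[1]), 3))
  upper <- c(rep(log(sigma_bounds[2]), 9), rep(stats::qlogis(prior_bounds[2]), 3))
  # large finite value outside the box or the well-posed region
  # (sigma_nojump < sigma_jump), so unconstrained polish steps cannot escape
  obj <- function(theta) {
    if (any(theta < lower - 1e-8) || any(theta > upper + 1e-8)) return(1e10)
    par <- theta_to_par(theta)
    if (any(par[5:8] >= par[["sigma_jump"]])) return(1e10)
    negative_log_likelihood(par, trials, banks, w_bayes, sigma_t_bayes)
  }

  set.seed(seed)
  canonical <- c(log(c(rep(0.5, 4), rep(0.7, 4), 2.5)),
                 stats::qlogis(c(0.2, 0.5, 0.8)))
  starts <- c(list(canonical),
              lapply(seq_len(max(0, n_restarts - 1)), function(i) {
                sj <- stats::runif(1, 1, 5)
                c(log(c(stats::runif(4, 0.05, 3),
                        stats::runif(4, 0.1, 0.9 * sj), sj)),
                  stats::qlogis(sort(stats::runif(3, 0.05, 0.95))))
              }))
  runs <- lapply(seq_along(starts), function(i) {
    fit <- tryCatch(
      stats::optim(starts[[i]], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(start = i, theta = fit$par, nll = fit$value,
         converged = fit$convergence == 0)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) {
    return(structure(list(estimates = NULL, nll = NA_real_,
                          converged = FALSE, restarts = NULL,
                          banks = banks, w_bayes = w_bayes, seed = seed),
                     class = "combined_fit"))
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "nll"))]]
  polish <- stats::optim(best$theta, obj, method = "Nelder-Mead",
                         control = list(maxit = 1000))
  if (polish$value < best$nll) {
    best$theta <- polish$par
    best$nll <- polish$value
  }
  restarts <- do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r$start, nll = r$nll, converged = r$converged)
  }))
  structure(list(estimates = theta_to_par(best$theta), nll = best$nll,
                 converged = TRUE, restarts = restarts, banks = banks,
                 w_bayes = w_bayes, seed = seed),
            class = "combined_fit")
}

#' Simulate a session from the fitted-model family
#'
#' Draws an interleaved session (four noise conditions at priors 0.2/0.8 plus
#' the 0.5-prior variant of the two low-image-noise conditions) and samples
#' binary responses from the combined-model probability under the given
#' 12-parameter vector and association banks. This is the generator used for
#' parameter-recovery experiments: the data come from exactly the family the
#' fit searches.
#'
#' @param par Named 12-parameter vector (see [fit_combined()]).
#' @param banks Association banks (matrix plus prior levels), e.g. built from
#'   cumulative-Gaussian association curves or a trained network.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param w_bayes,sigma_t_bayes As in [fit_combined()].
#' @param jump_draw_sd,nojump_draw_sd True displacement draw widths, degrees.
#' @param session_id Session label for the output table.
#' @return Trial table with columns `session_id`, `condition`, `prior`,
#'   `saccade`, `image_noise`, `probe_sigma`, `displacement_deg`,
#'   `displacement`, `response`, `valid`, `p_true`.
#' @export
simulate_fit_family <- function(par, banks, n_trials = 2000, seed = 1,
                                w_bayes = 0.1, sigma_t_bayes = 0.1,
                                jump_draw_sd = 2.5, nojump_draw_sd = 0.2,
                                session_id = "synthetic") {
  par <- check_free_params(par)
  set.seed(seed)
  grid <- standard_condition_grid(include_half_prior = TRUE)
  idx <- sample.int(nrow(grid), n_trials, replace = TRUE)
  cells <- grid[idx, ]
  jump <- stats::runif(n_trials) < cells$prior
  x <- abs(stats::rnorm(n_trials, 0, ifelse(jump, jump_draw_sd, nojump_draw_sd)))
  trials <- data.frame(session_id = session_id,
                       condition = cells$condition, prior = cells$prior,
                       saccade = cells$saccade, image_noise = cells$image_noise,
                       probe_sigma = cells$probe_sigma,
                       displacement_deg = x, displacement = x,
                       response = 0L, valid = 1L,
                       stringsAsFactors = FALSE)
  p <- predict_combined(par, trials, banks, w_bayes, sigma_t_bayes)
  trials$p_true <- p
  trials$response <- as.integer(stats::runif(n_trials) < p)
  trials
}

#' Cumulative-Gaussian association banks
#'
#' Convenience constructor of ground-truth association banks for recovery
#' experiments: one cumulative Gaussian per prior with a prior-dependent
#' midpoint (higher prior, lower category boundary), bracketed by a floor and
#' ceiling.
#'
#' @param priors Prior levels.
#' @param midpoints Curve midpoints per prior, degrees.
#' @param slope Common curve SD, degrees.
#' @param floor,ceiling Lower/upper asymptotes.
#' @param grid An [input_grid()].
#' @return Banks list as used by [fit_combined()].
#' @export
gaussian_banks <- function(priors = c(0.2, 0.5, 0.8),
                           midpoints = c(1.6, 1.1, 0.6), slope = 0.6,
                           floor = 0.05, ceiling = 0.95,
                           grid = input_grid()) {
  stopifnot(length(priors) == length(midpoints))
  banks <- vapply(midpoints, function(m) {
    floor + (ceiling - floor) * stats::pnorm((grid$centers - m) / slope)
  }, numeric(grid$n_units))
  list(banks = banks, fits = NULL, priors = priors)
}
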