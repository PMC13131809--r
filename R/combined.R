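#' Parameters of the combined Bayesian + category-learning model
#'
#' The combined observer mixes a Bayesian ideal observer, which carries the
#' saccade-driven uncertainty (wider internal non-jump distribution with an
#' intervening saccade), with a perceptron-like categorization network, which
#' carries the external image noise (wider input-activation encoding). The
#' two outputs are combined as `w_bayes * O_B + (1 - w_bayes) * O_P`.
#'
#' Defaults follow the standard simulation protocol: jump width 2.5 deg,
#' non-jump width 0.5 deg (no saccade) or 1.0 deg (with saccade), Bayesian
#' image noise pinned at 0.1 deg in all conditions, perceptron encoding noise
#' 0.1/1/2 deg for low/medium/high image noise, learning rate 0.5, Bayesian
#' weight 0.1, and 1000 training plus 1000 test trials. Displacements are
#' drawn from zero-mean Gaussians of SD 2.5 deg (jump) and 0.2 deg (no jump).
#'
#' @param w_bayes Weight of the Bayesian component, in `[0, 1]`; the
#'   perceptron weight is `1 - w_bayes`.
#' @param sigma_jump Width of the jump distribution assumed by the Bayesian
#'   observer, degrees.
#' @param sigma_nojump Non-jump widths assumed by the Bayesian observer,
#'   named per condition (`no_saccade` and the three saccade conditions).
#' @param sigma_t_bayes Bayesian image noise, degrees, constant across
#'   conditions.
#' @param perceptron_noise Encoding noise per image-noise level, degrees.
#' @param learning_rate Perceptron learning rate.
#' @param n_train,n_test Trial counts for the training and test phases.
#' @param priors Cued prior levels simulated.
#' @param jump_draw_sd,nojump_draw_sd SDs of the true displacement draws.
#' @return An object of class `combined_params`.
#' @export
combined_params <- function(w_bayes = 0.1,
                            sigma_jump = 2.5,
                            sigma_nojump = c(no_saccade = 0.5, saccade = 1.0),
                            sigma_t_bayes = 0.1,
                            perceptron_noise = c(low = 0.1, medium = 1, high = 2),
                            learning_rate = 0.5,
                            n_train = 1000, n_test = 1000,
                            priors = c(0.2, 0.8),
                            jump_draw_sd = 2.5, nojump_draw_sd = 0.2) {
  stopifnot(w_bayes >= 0, w_bayes <= 1,
            all(c("no_saccade", "saccade") %in% names(sigma_nojump)),
            all(c("low", "medium", "high") %in% names(perceptron_noise)))
  structure(list(w_bayes = w_bayes, w_perceptron = 1 - w_bayes,
                 sigma_jump = sigma_jump, sigma_nojump = sigma_nojump,
                 sigma_t_bayes = sigma_t_bayes,
                 perceptron_noise = perceptron_noise,
                 learning_rate = learning_rate,
                 n_train = n_train, n_test = n_test, priors = priors,
                 jump_draw_sd = jump_draw_sd, nojump_draw_sd = nojump_draw_sd),
            class = "combined_params")
}

#' Weighted combination of Bayesian and perceptron outputs
#'
#' @param o_b,o_p Component outputs, probabilities in `[0, 1]`.
#' @param w_b Bayesian weight in `[0, 1]`; the perceptron gets `1 - w_b`.
#' @return `w_b * o_b + (1 - w_b) * o_p`.
#' @export
combined_output <- function(o_b, o_p, w_b) {
  if (any(o_b < 0 | o_b > 1) || any(o_p < 0 | o_p > 1)) {
    stop("component outputs must be probabilities in [0, 1]")
  }
  if (any(w_b < 0 | w_b > 1)) stop("`w_b` must be in [0, 1]")
  w_b * o_b + (1 - w_b) * o_p
}

# Bayesian parameter set for one noise condition of the combined model.
condition_bayes_params <- function(params, condition, prior) {
  snj <- if (condition == "no_saccade") params$sigma_nojump[["no_saccade"]]
         else params$sigma_nojump[["saccade"]]
  bayes_params(sigma_t = params$sigma_t_bayes, sigma_jump = params$sigma_jump,
               sigma_nojump = snj, prior_jump = prior)
}

condition_image_level <- function(condition) {
  c(no_saccade = "low", saccade_low = "low",
    saccade_medium = "medium", saccade_high = "high")[[condition]]
}

# Draw interleaved trials: condition cells i.i.d. uniform, jump by the cued
# prior, displacement magnitude from the matching zero-mean Gaussian.
draw_trials <- function(n, cells, params) {
  idx <- sample.int(nrow(cells), n, replace = TRUE)
  prior <- cells$prior[idx]
  jump <- stats::runif(n) < prior
  x <- abs(stats::rnorm(n, 0,
                        ifelse(jump, params$jump_draw_sd, params$nojump_draw_sd)))
  data.frame(condition = cells$condition[idx], prior = prior,
             jump = jump, x = x, stringsAsFactors = FALSE)
}

#' Simulate the full training-plus-test protocol of the combined model
#'
#' Each simulation has `n_train + n_test` trials. During training the
#' perceptron weights are updated in the with-saccade, low-image-noise
#' (common) condition only; during the test phase the weights are frozen and
#' the four noise conditions (crossed with the cued priors) are interleaved.
#' Binary responses are Bernoulli draws from the combined output, which is
#' also retained per trial for deterministic checks.
#'
#' @param params A [combined_params()] object.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A list of class `ssd_simulation` with elements `trials` (test
#'   phase: condition, prior, displacement, component and combined outputs,
#'   response), `net` (trained perceptron) and `prior_use` (response-rate
#'   difference per condition over the 0-2 degree window).
#' @export
simulate_experiment <- function(params = combined_params(), seed = 1) {
  stopifnot(inherits(params, "combined_params"))
  set.seed(seed)
  net <- perceptron_net(priors = params$priors,
                        learning_rate = params$learning_rate)

  train_cells <- data.frame(condition = "saccade_low", prior = params$priors)
  train <- draw_trials(params$n_train, train_cells, params)
  net <- net_train(net, train, params$perceptron_noise[["low"]])

  test_cells <- expand.grid(condition = condition_levels(),
                            prior = params$priors, stringsAsFactors = FALSE)
  test <- draw_trials(params$n_test, test_cells, params)
  test$o_bayes <- NA_real_
  test$o_perceptron <- NA_real_
  for (cond in condition_levels()) {
    for (pr in params$priors) {
      m <- test$condition == cond & test$prior == pr
      if (!any(m)) next
      bp <- condition_bayes_params(params, cond, pr)
      test$o_bayes[m] <- jump_probability(test$x[m], bp)
      noise <- params$perceptron_noise[[condition_image_level(cond)]]
      # unclamped learning can push the normalized output slightly outside
      # the unit interval for sparsely visited inputs; clamp at use
      test$o_perceptron[m] <- pmin(pmax(
        net_jump_output(net, test$x[m], noise, pr), 0), 1)
    }
  }
  test$o_combined <- combined_output(test$o_bayes, test$o_perceptron,
                                     params$w_bayes)
  test$response <- as.integer(stats::runif(nrow(test)) < test$o_combined)
  test$displacement <- test$x
  res <- structure(list(trials = test, net = net, params = params,
                        seed = seed),
                   class = "ssd_simulation")
  res$prior_use <- behavioral_prior_use(test)
  res
}

#' Behavioral prior use per noise condition
#'
#' The difference in the proportion of "jumped" reports between the high
#' (0.8) and low (0.2) prior conditions, over trials with displacement
#' magnitude inside the window (0-2 degrees by default, the range prevalent
#' under both priors).
#'
#' @param trials Data frame with columns `condition` (or `saccade` +
#'   `image_noise`), `prior`, `response` and a displacement column
#'   (`displacement` or `displacement_deg`).
#' @param window Length-2 displacement-magnitude window, degrees.
#' @param priors Length-2 vector: the low and high prior levels compared.
#' @return Data frame with one row per condition: `prior_use`, `n_low`,
#'   `n_high`. A condition with an empty prior cell in the window gets `NA`
#'   prior use and a warning rather than a silent zero.
#' @export
behavioral_prior_use <- function(trials, window = c(0, 2),
                                 priors = c(0.2, 0.8)) {
  disp <- if ("displacement" %in% names(trials)) trials$displacement
          else trials$displacement_deg
  cond <- if ("condition" %in% names(trials)) as.character(trials$condition)
          else condition_label(trials$saccade, trials$image_noise)
  keep <- abs(disp) >= window[1] & abs(disp) <= window[2]
  out <- data.frame(condition = condition_levels(), prior_use = NA_real_,
                    n_low = 0L, n_high = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    lo <- keep & cond == out$condition[i] & trials$prior == priors[1]
    hi <- keep & cond == out$condition[i] & trials$prior == priors[2]
    out$n_low[i] <- sum(lo)
    out$n_high[i] <- sum(hi)
    if (out$n_low[i] > 0 && out$n_high[i] > 0) {
      out$prior_use[i] <- mean(trials$response[hi]) - mean(trials$response[lo])
    }
  }
  if (anyNA(out$prior_use)) {
    warning("prior use undefined for condition(s) with an empty prior cell: ",
            paste(out$condition[is.na(out$prior_use)], collapse = ", "))
  }
  out
}

#' Compare per-session prior use across noise conditions
#'
#' Runs the standard condition contrasts on a sessions-by-conditions table of
#' prior-use values: a paired t-test of the no-saccade against the common
#' (with-saccade, low-image-noise) condition, a one-way repeated-measures
#' ANOVA across the three image-noise levels, and pairwise paired follow-ups.
#'
#' @param values Data frame or matrix, one row per session, columns named as
#'   in [condition_levels()].
#' @return List with elements `saccade` (paired t), `image` (RM-ANOVA F, df,
#'   p) and `pairwise` (paired t-tests between image-noise levels).
#' @export
compare_prior_use <- function(values) {
  values <- as.data.frame(values)
  stopifnot(all(condition_levels() %in% names(values)))
  if (nrow(values) < 2) stop("need at least 2 sessions")

  paired_t <- function(a, b) {
    d <- a - b
    if (stats::sd(d) == 0) {
      return(list(t = 0, df = length(d) - 1,
                  p = if (mean(d) == 0) 1 else 0))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
  }

  img_levels <- c("saccade_low", "saccade_medium", "saccade_high")
  Y <- as.matrix(values[, img_levels])
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_err <- ss_err / df2
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / ms_err
  p_f <- if (ss_cond == 0) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(img_levels, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    ht <- paired_t(values[[pr[1]]], values[[pr[2]]])
    data.frame(a = pr[1], b = pr[2], t = ht$t, p = ht$p,
               stringsAsFactors = FALSE)
  }))

  list(saccade = paired_t(values[["saccade_low"]], values[["no_saccade"]]),
       image = list(F = f, df1 = df1, df2 = df2, p = p_f),
       pairwise = pairwise)
}
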