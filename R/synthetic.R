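#' Ground truth for synthetic behavioral sessions and model neurons
#'
#' Bundles the generating combined model with the neural rate program of a
#' synthetic neuron population. Each neuron follows one of four prior-
#' modulation patterns at the reafferent event: `bayesian` (modulation grows
#' with saccade-driven noise, unchanged by image noise), `anti_bayesian`
#' (unchanged by saccade-driven noise, collapses with image noise),
#' `prior_only` (constant), or `output_mirroring` (tracks the behavioral
#' prior use per condition).
#'
#' @param combined A [combined_params()] object (the behavioral generator).
#' @param pattern Neural pattern label(s); recycled over neurons in a cohort.
#' @param behavioral_model `"combined"` draws responses from the combined
#'   Bayesian + perceptron observer; `"logistic"` draws them from a logistic
#'   model with the injected interaction strengths below, the generative
#'   route used for mixed-model recovery experiments.
#' @param behavioral_coefs Named logistic coefficients on the predictors
#'   `intercept`, `prior_high` (0/1), `saccade` (0/1), `image` (level
#'   1/2/3), `displacement` (degrees, magnitude), `prior_image` and
#'   `prior_saccade`. Defaults echo the scale of a combined-model cohort's
#'   fitted coefficients, with a positive prior-by-saccade strength (the
#'   Bayesian effect) and a negative prior-by-image strength (the
#'   anti-Bayesian effect).
#' @param base_rate Baseline firing rate, spikes/s.
#' @param modulation Peak high-minus-low-prior rate difference, spikes/s.
#' @param displacement_gain Rate increase per degree of displacement during
#'   the reafferent window, spikes/s per degree (FEF rates grow with the
#'   magnitude of the image displacement).
#' @param response_median_ms Median of the lognormal response-saccade
#'   latency; used only to place the response event.
#' @return Object of class `ssd_ground_truth`.
#' @export
ground_truth <- function(combined = combined_params(),
                         pattern = "anti_bayesian",
                         behavioral_model = c("combined", "logistic"),
                         behavioral_coefs = c(intercept = -3.4,
                                              prior_high = 2.2,
                                              saccade = 0.4, image = 0.9,
                                              displacement = 0.6,
                                              prior_image = -1.2,
                                              prior_saccade = 1.4),
                         base_rate = 20, modulation = 5,
                         displacement_gain = 1,
                         response_median_ms = 611) {
  behavioral_model <- match.arg(behavioral_model)
  stopifnot(inherits(combined, "combined_params"),
            all(pattern %in% c("bayesian", "anti_bayesian", "prior_only",
                               "output_mirroring")),
            base_rate > 0, modulation >= 0,
            all(c("intercept", "prior_high", "saccade", "image",
                  "displacement", "prior_image", "prior_saccade") %in%
                  names(behavioral_coefs)))
  structure(list(combined = combined, pattern = pattern,
                 behavioral_model = behavioral_model,
                 behavioral_coefs = behavioral_coefs,
                 base_rate = base_rate, modulation = modulation,
                 displacement_gain = displacement_gain,
                 response_median_ms = response_median_ms),
            class = "ssd_ground_truth")
}

#' Per-condition prior-modulation gains of the four neural patterns
#'
#' The gain multiplies the modulation depth in each noise condition. The
#' common condition always has gain 1; the anti-Bayesian pattern collapses
#' under medium/high image noise, the Bayesian pattern is reduced without a
#' saccade, the prior-only pattern never changes, and output-mirroring uses
#' the behavioral prior use normalized to the common condition.
#'
#' @param pattern Pattern label.
#' @param behavioral_prior_use Optional named per-condition behavioral prior
#'   use (required for `output_mirroring`).
#' @return Named gain vector over [condition_levels()].
#' @export
pattern_gains <- function(pattern, behavioral_prior_use = NULL) {
  lv <- condition_levels()
  # the anti-Bayesian collapse is linear in the image-noise level so that
  # the decline is fully carried by the prior-by-image term of a regression
  # with numeric level coding; a convex profile would leak curvature into
  # the prior-by-saccade term through the no-saccade anchor cell
  gains <- switch(pattern,
    bayesian       = c(0.3, 1, 1, 1),
    anti_bayesian  = c(1, 1, 0.6, 0.2),
    prior_only     = c(1, 1, 1, 1),
    output_mirroring = {
      if (is.null(behavioral_prior_use)) {
        stop("output_mirroring needs the behavioral prior use per condition")
      }
      pu <- behavioral_prior_use[lv]
      as.numeric(pu / pu[["saccade_low"]])
    },
    stop("unknown pattern: ", pattern))
  stats::setNames(as.numeric(gains), lv)
}

#' Generate a synthetic behavioral session
#'
#' Trains the perceptron of the ground-truth combined model in the common
#' condition (unless a trained network is supplied), then draws an
#' interleaved session over the four noise conditions and cued priors with
#' binary responses sampled from the combined output. Deterministic given
#' the seed.
#'
#' @param truth A [ground_truth()] object.
#' @param n_trials Number of trials (at least 8 times the per-cell minimum
#'   you intend to analyze).
#' @param seed Integer seed.
#' @param session_id Session label.
#' @param net Optional pre-trained [perceptron_net()] (saves retraining when
#'   generating many sessions from one truth).
#' @param include_half_prior Also draw 0.5-prior trials in the low-image-
#'   noise conditions.
#' @return Trial table (columns as in [read_trial_table()], plus
#'   `condition`, `displacement`, `o_combined`, `trial_id`).
#' @export
gen_behavior <- function(truth, n_trials = 800, seed = 1,
                         session_id = "s01", net = NULL,
                         include_half_prior = FALSE) {
  stopifnot(inherits(truth, "ssd_ground_truth"))
  params <- truth$combined
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net) && truth$behavioral_model == "combined") {
    pr_train <- if (include_half_prior) sort(unique(c(params$priors, 0.5)))
                else params$priors
    net <- perceptron_net(priors = pr_train,
                          learning_rate = params$learning_rate)
    train_cells <- data.frame(condition = "saccade_low", prior = pr_train)
    net <- net_train(net, draw_trials(params$n_train, train_cells, params),
                     params$perceptron_noise[["low"]])
  }
  grid <- standard_condition_grid(include_half_prior = include_half_prior)
  idx <- sample.int(nrow(grid), n_trials, replace = TRUE)
  cells <- grid[idx, ]
  jump <- stats::runif(n_trials) < cells$prior
  x <- abs(stats::rnorm(n_trials, 0,
                        ifelse(jump, params$jump_draw_sd, params$nojump_draw_sd)))
  oc <- numeric(n_trials)
  if (truth$behavioral_model == "logistic") {
    b <- truth$behavioral_coefs
    # graded prior coding: 0 at the low cue, 1 at the high cue, so a 0.5
    # cue sits halfway; the extremes match a plain 0/1 indicator
    prs <- range(cells$prior)
    prior_high <- if (diff(prs) > 0) (cells$prior - prs[1]) / diff(prs)
                  else rep(0, nrow(cells))
    image <- match(cells$image_noise, c("low", "medium", "high"))
    eta <- b[["intercept"]] + b[["prior_high"]] * prior_high +
      b[["saccade"]] * cells$saccade + b[["image"]] * image +
      b[["displacement"]] * x +
      b[["prior_image"]] * prior_high * image +
      b[["prior_saccade"]] * prior_high * cells$saccade
    oc <- stats::plogis(eta)
  } else {
    for (cond in unique(cells$condition)) {
      for (pr in unique(cells$prior)) {
        m <- cells$condition == cond & cells$prior == pr
        if (!any(m)) next
        bp <- condition_bayes_params(params, cond, pr)
        ob <- jump_probability(x[m], bp)
        noise <- params$perceptron_noise[[condition_image_level(cond)]]
        op <- pmin(pmax(net_jump_output(net, x[m], noise, pr), 0), 1)
        oc[m] <- combined_output(ob, op, params$w_bayes)
      }
    }
  }
  data.frame(session_id = session_id,
             trial_id = paste0(session_id, "_t", seq_len(n_trials)),
             condition = cells$condition, prior = cells$prior,
             saccade = cells$saccade, image_noise = cells$image_noise,
             probe_sigma = cells$probe_sigma,
             displacement_deg = x, displacement = x,
             jumped = as.integer(jump),
             o_combined = oc,
             response = as.integer(stats::runif(n_trials) < oc),
             valid = 1L, stringsAsFactors = FALSE)
}

#' Generate a synthetic model neuron for a behavioral session
#'
#' Produces per-trial Poisson spike trains aligned to fixation acquisition
#' and to the reafferent event. The baseline rate applies everywhere; in the
#' 0-800 ms reafferent window the rate additionally carries a monotone
#' displacement term and a prior term of magnitude
#' `modulation * gain(condition)`, split symmetrically between the high
#' (+half) and low (-half) prior conditions. The modulation starts at the
#' reafferent event and ends by +800 ms; the fixation period carries no
#' prior information.
#'
#' @param truth A [ground_truth()] object.
#' @param session Trial table from [gen_behavior()].
#' @param seed Integer seed.
#' @param neuron_id Identifier.
#' @param pattern Pattern label (defaults to the truth's first pattern).
#' @return A [neuron_recording()] with the pattern label attached.
#' @export
gen_neuron <- function(truth, session, seed = 1,
                       neuron_id = "n01", pattern = NULL) {
  stopifnot(inherits(truth, "ssd_ground_truth"))
  if (is.null(pattern)) pattern <- truth$pattern[1]
  if (!is.null(seed)) set.seed(seed)
  pu <- NULL
  if (pattern == "output_mirroring") {
    bp <- behavioral_prior_use(session)
    pu <- stats::setNames(bp$prior_use, bp$condition)
  }
  gains <- pattern_gains(pattern, pu)
  windows <- list(fixation = c(-100, 400), reafferent = c(-200, 1000))
  n <- nrow(session)
  cond <- as.character(session$condition)
  half <- truth$modulation * gains[cond] / 2
  # graded prior drive: -1 at the low cue, +1 at the high cue, 0 between
  prs <- range(session$prior)
  scale <- if (diff(prs) > 0) 2 * (session$prior - prs[1]) / diff(prs) - 1
           else rep(1, nrow(session))
  dprior <- half * scale
  dterm <- truth$displacement_gain * pmin(abs(session$displacement), 5)
  rate_mod <- truth$base_rate + dterm + dprior
  if (any(rate_mod < 0)) {
    warning("negative programmed rate clamped at 0")
    rate_mod <- pmax(rate_mod, 0)
  }
  # vectorized Poisson segments: per trial, each alignment window is a set
  # of constant-rate segments; spike times are uniform within each segment
  seg_spikes <- function(rates, start, end, alignment) {
    counts <- stats::rpois(n, rates * (end - start) / 1000)
    data.frame(trial_id = rep(session$trial_id, counts),
               alignment = alignment,
               time_ms = stats::runif(sum(counts), start, end),
               stringsAsFactors = FALSE)
  }
  base <- rep(truth$base_rate, n)
  sp <- rbind(
    seg_spikes(base, windows$fixation[1], windows$fixation[2], "fixation"),
    seg_spikes(base, windows$reafferent[1], 0, "reafferent"),
    seg_spikes(rate_mod, 0, 800, "reafferent"),
    seg_spikes(base, 800, windows$reafferent[2], "reafferent"))
  sp <- sp[order(match(sp$trial_id, session$trial_id), sp$alignment,
                 sp$time_ms), ]
  rownames(sp) <- NULL
  trials <- session[, c("trial_id", "condition", "prior",
                        "displacement", "response")]
  neuron_recording(neuron_id, sp, trials, windows, pattern = pattern)
}

#' Generate a session-linked behavioral and neural cohort
#'
#' Creates `n_sessions` behavioral sessions from the ground-truth combined
#' model (one shared trained network) and one synthetic neuron per session,
#' cycling through the truth's pattern labels. The manifest records all
#' ground truth so recovery can be checked end to end.
#'
#' @param truth A [ground_truth()] object (its `pattern` may be a vector).
#' @param n_sessions Number of sessions.
#' @param n_trials Trials per session.
#' @param seed Integer seed; session and neuron seeds are derived from it.
#' @param include_half_prior Include the 0.5-prior trials of the two
#'   low-image-noise conditions (part of the protocol; required by the
#'   12-parameter model fit).
#' @return List of class `ssd_cohort`: `sessions` (named list of trial
#'   tables), `neurons` (list of recordings), `manifest`.
#' @export
gen_cohort <- function(truth, n_sessions = 12, n_trials = 800, seed = 1,
                       include_half_prior = TRUE) {
  stopifnot(inherits(truth, "ssd_ground_truth"), n_sessions >= 1)
  params <- truth$combined
  set.seed(seed)
  net <- NULL
  if (truth$behavioral_model == "combined") {
    pr_train <- if (include_half_prior) {
      sort(unique(c(params$priors, 0.5)))
    } else {
      params$priors
    }
    net <- perceptron_net(priors = pr_train,
                          learning_rate = params$learning_rate)
    train_cells <- data.frame(condition = "saccade_low", prior = pr_train)
    net <- net_train(net, draw_trials(params$n_train, train_cells, params),
                     params$perceptron_noise[["low"]])
  }
  patterns <- rep_len(truth$pattern, n_sessions)
  sessions <- list()
  neurons <- list()
  # one RNG stream per cohort: sessions and neurons consume it in order, so
  # different cohort seeds give independent cohorts
  for (s in seq_len(n_sessions)) {
    sid <- sprintf("s%02d", s)
    tab <- gen_behavior(truth, n_trials = n_trials, seed = NULL,
                        session_id = sid, net = net,
                        include_half_prior = include_half_prior)
    rec <- gen_neuron(truth, tab, seed = NULL,
                      neuron_id = sprintf("n%02d", s),
                      pattern = patterns[s])
    sessions[[sid]] <- tab
    neurons[[rec$neuron_id]] <- rec
  }
  manifest <- list(
    seed = seed, n_sessions = n_sessions, n_trials = n_trials,
    patterns = patterns,
    behavioral_model = truth$behavioral_model,
    behavioral_coefs = as.list(truth$behavioral_coefs),
    base_rate = truth$base_rate, modulation = truth$modulation,
    displacement_gain = truth$displacement_gain,
    combined = unclass(params)
  )
  structure(list(sessions = sessions, neurons = neurons, manifest = manifest),
            class = "ssd_cohort")
}

#' Write or read a cohort manifest
#'
#' @param manifest Manifest list from [gen_cohort()].
#' @param path File path (JSON).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
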