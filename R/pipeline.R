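#' Default pipeline configuration
#'
#' A single nested configuration drives the full simulate / fit / analyze /
#' report pipeline. Every stochastic stage consumes a seed derived
#' deterministically from the global seed.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = "ssdprior-run") {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, fit = FALSE, analyze = TRUE,
                  report = TRUE),
    cohort = list(n_sessions = 12, n_trials = 800,
                  pattern = "anti_bayesian",
                  base_rate = 20, modulation = 5, displacement_gain = 1),
    combined = list(w_bayes = 0.1, sigma_jump = 2.5,
                    sigma_nojump_no_saccade = 0.5, sigma_nojump_saccade = 1.0,
                    sigma_t_bayes = 0.1,
                    perceptron_noise = c(low = 0.1, medium = 1, high = 2),
                    learning_rate = 0.5, n_train = 1000),
    fit = list(session = 1, n_restarts = 4, maxit = 200)
  )
}

validate_config <- function(config) {
  need <- c("seed", "out_dir", "stages", "cohort", "combined")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  }
  cneed <- c("w_bayes", "sigma_jump", "sigma_nojump_no_saccade",
             "sigma_nojump_saccade", "sigma_t_bayes", "perceptron_noise",
             "learning_rate")
  cmissing <- setdiff(cneed, names(config$combined))
  if (length(cmissing)) {
    stop("config$combined is missing field(s): ",
         paste(cmissing, collapse = ", "))
  }
  invisible(TRUE)
}

config_params <- function(config) {
  cc <- config$combined
  combined_params(
    w_bayes = cc$w_bayes, sigma_jump = cc$sigma_jump,
    sigma_nojump = c(no_saccade = cc$sigma_nojump_no_saccade,
                     saccade = cc$sigma_nojump_saccade),
    sigma_t_bayes = cc$sigma_t_bayes,
    perceptron_noise = unlist(cc$perceptron_noise),
    learning_rate = cc$learning_rate,
    n_train = if (is.null(cc$n_train)) 1000 else cc$n_train)
}

# Small deterministic rolling hash of the serialized config, so every
# output table can be traced back to the configuration that produced it
# (provenance stamp, not cryptographic).
config_hash <- function(config) {
  config$out_dir <- NULL  # the output location is not part of the science
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_table <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' One call runs simulate (cohort generation), optionally fit (12-parameter
#' MLE on one session), analyze (behavioral prior use and condition
#' contrasts, epoch screens, sliding bins, common-normalized effect sizes,
#' neuron-behavior correlations, mixed-effects models) and report (tabular
#' text and JSON outputs, each carrying the configuration hash). All numeric
#' outputs are reproducible from (config, seed).
#'
#' @param config Configuration list (see [default_config()]).
#' @return Invisible list with the in-memory results bundle.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  hash <- config_hash(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list(config_hash = hash)

  cohort <- stage("simulate", {
    truth <- ground_truth(config_params(config),
                          pattern = config$cohort$pattern,
                          base_rate = config$cohort$base_rate,
                          modulation = config$cohort$modulation,
                          displacement_gain = config$cohort$displacement_gain)
    gen_cohort(truth, n_sessions = config$cohort$n_sessions,
               n_trials = config$cohort$n_trials, seed = config$seed)
  })
  results$cohort_sizes <- data.frame(
    session = names(cohort$sessions),
    n_trials = vapply(cohort$sessions, nrow, integer(1)))

  if (isTRUE(config$stages$fit)) {
    results$fit <- stage("fit", {
      tab <- cohort$sessions[[config$fit$session]]
      fit <- fit_combined(tab, n_restarts = config$fit$n_restarts,
                          seed = config$seed + 3000,
                          maxit = config$fit$maxit)
      jsonlite::write_json(
        list(config_hash = hash, estimates = as.list(fit$estimates),
             nll = fit$nll, converged = fit$converged,
             restarts = fit$restarts),
        file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      fit
    })
  }

  analysis <- stage("analyze", {
    pu <- do.call(rbind, lapply(names(cohort$sessions), function(sid) {
      b <- behavioral_prior_use(cohort$sessions[[sid]])
      cbind(session = sid, b)
    }))
    pu_wide <- stats::reshape(
      pu[, c("session", "condition", "prior_use")],
      idvar = "session", timevar = "condition", direction = "wide")
    names(pu_wide) <- sub("^prior_use\\.", "", names(pu_wide))
    contrasts <- compare_prior_use(pu_wide)

    screen <- epoch_prior_screen(cohort$neurons)
    effects <- do.call(rbind, lapply(cohort$neurons, function(rec) {
      es <- vapply(condition_levels(), function(cond) {
        rr <- prior_epoch_rates(rec, "reafferent", 0, 800, cond)
        wilcoxon_effect(rr$high, rr$low)$effect
      }, numeric(1))
      data.frame(neuron_id = rec$neuron_id, t(es),
                 pattern = classify_pattern(es), stringsAsFactors = FALSE)
    }))
    rownames(effects) <- NULL

    slide <- do.call(rbind, lapply(cohort$neurons, function(rec) {
      sb <- sliding_bins(rec)
      data.frame(neuron_id = rec$neuron_id,
                 n_significant = sum(sb$bins$significant),
                 earliest = sb$earliest_significant)
    }))
    rownames(slide) <- NULL

    norm_neuronal <- t(apply(as.matrix(effects[, condition_levels()]), 1,
                             function(v) normalize_to_common(
                               v, v[["saccade_low"]])))
    norm_behavioral <- t(apply(as.matrix(pu_wide[, condition_levels()]), 1,
                               function(v) normalize_to_common(
                                 v, v[["saccade_low"]])))
    cors <- do.call(rbind, lapply(
      c("no_saccade", "saccade_medium", "saccade_high"), function(cond) {
        ct <- neuron_behavior_correlation(norm_neuronal[, cond],
                                          norm_behavioral[, cond])
        data.frame(condition = cond, r = ct$r, p = ct$p, n = ct$n)
      }))

    joined <- do.call(rbind, lapply(seq_along(cohort$neurons), function(i) {
      rec <- cohort$neurons[[i]]
      rates <- epoch_rate(rec, "reafferent", 0, 800)
      tab <- cohort$sessions[[i]]
      merged <- merge(tab, rates, by = "trial_id")
      merged$neuron_id <- rec$neuron_id
      merged
    }))
    designs <- build_mixed_designs(joined)
    mixed <- fit_mixed_models(designs)

    list(prior_use = pu, prior_use_wide = pu_wide, contrasts = contrasts,
         screen = screen, effects = effects, sliding = slide,
         correlations = cors, mixed = mixed)
  })
  results <- c(results, analysis)

  if (isTRUE(config$stages$report)) {
    stage("report", {
      write_table(analysis$prior_use, file.path(out, "prior_use.csv"), hash)
      write_table(analysis$screen, file.path(out, "epoch_screen.csv"), hash)
      write_table(analysis$effects, file.path(out, "effect_sizes.csv"), hash)
      write_table(analysis$sliding, file.path(out, "sliding_bins.csv"), hash)
      write_table(analysis$correlations,
                  file.path(out, "correlations.csv"), hash)
      write_table(analysis$mixed$behavioral,
                  file.path(out, "mixed_behavioral.csv"), hash)
      write_table(analysis$mixed$neural,
                  file.path(out, "mixed_neural.csv"), hash)
      jsonlite::write_json(
        list(config_hash = hash,
             saccade_t = analysis$contrasts$saccade,
             image_F = analysis$contrasts$image,
             pairwise = analysis$contrasts$pairwise),
        file.path(out, "contrasts.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    })
  }
  invisible(results)
}
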