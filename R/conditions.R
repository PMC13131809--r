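#' Condition labels used throughout the package
#'
#' The SSD protocol crosses two uncertainty manipulations into four noise
#' conditions: a no-saccade condition (only at low image noise) and three
#' with-saccade conditions at low, medium and high image noise. The
#' with-saccade, low-image-noise condition is shared by the saccade-noise and
#' image-noise experiments and is designated the "common" condition.
#'
#' @format Character vector of the four canonical condition labels, in the
#'   order used for all per-condition outputs.
#' @export
condition_levels <- function() {
  c("no_saccade", "saccade_low", "saccade_medium", "saccade_high")
}

#' Build the standard prior-by-noise condition grid
#'
#' Returns one row per trial type of the standard protocol: the four noise
#' conditions at cued priors 0.2 and 0.8, plus a 0.5-prior variant of the two
#' low-image-noise conditions (used for model fitting). Probe widths are
#' 0.5 deg (low), 1.25 deg (medium) and 2 deg (high) by default; 1.75 deg is
#' the alternative high-noise width used for one subject.
#'
#' @param high_noise_sigma Probe width in degrees for the high-image-noise
#'   condition; must be 2.0 or 1.75.
#' @param include_half_prior Include the 0.5-prior rows for the two
#'   low-image-noise conditions (default `TRUE`).
#' @return A data frame with columns `condition`, `prior`, `saccade` (0/1),
#'   `image_noise` (`"low"`/`"medium"`/`"high"`), `probe_sigma` (degrees) and
#'   `common` (logical; `TRUE` exactly once per prior level, for the
#'   with-saccade low-image-noise condition).
#' @export
standard_condition_grid <- function(high_noise_sigma = 2.0,
                                    include_half_prior = TRUE) {
  if (!is.numeric(high_noise_sigma) || length(high_noise_sigma) != 1L ||
      !high_noise_sigma %in% c(2.0, 1.75)) {
    stop("`high_noise_sigma` must be 2.0 or 1.75 degrees")
  }
  base <- data.frame(
    condition   = condition_levels(),
    saccade     = c(0L, 1L, 1L, 1L),
    image_noise = c("low", "low", "medium", "high"),
    probe_sigma = c(0.5, 0.5, 1.25, high_noise_sigma),
    stringsAsFactors = FALSE
  )
  priors <- c(0.2, 0.8)
  grid <- merge(data.frame(prior = priors), base, by = NULL)
  if (include_half_prior) {
    half <- base[base$image_noise == "low", , drop = FALSE]
    half <- cbind(prior = 0.5, half)
    grid <- rbind(grid, half)
  }
  grid$common <- grid$saccade == 1L & grid$image_noise == "low"
  grid <- grid[order(match(grid$condition, condition_levels()), grid$prior), ]
  rownames(grid) <- NULL
  grid[, c("condition", "prior", "saccade", "image_noise", "probe_sigma", "common")]
}

#' Derive the condition label from saccade and image-noise columns
#'
#' @param saccade 0/1 (or logical) saccade-present flag.
#' @param image_noise Character, one of `"low"`, `"medium"`, `"high"`.
#' @return Character vector of condition labels.
#' @export
condition_label <- function(saccade, image_noise) {
  saccade <- as.integer(saccade)
  out <- ifelse(saccade == 0L, "no_saccade",
         ifelse(image_noise == "low", "saccade_low",
         ifelse(image_noise == "medium", "saccade_medium", "saccade_high")))
  bad <- saccade == 0L & image_noise != "low"
  if (any(bad)) stop("the no-saccade condition exists only at low image noise")
  out
}

#' Count valid trials per condition cell of a session
#'
#' @param trials A session trial table (see [read_trial_table()]).
#' @param zero_only Count only trials with displacement exactly 0.
#' @return Data frame with one row per condition-by-prior cell and column `n`.
#' @export
count_per_condition <- function(trials, zero_only = FALSE) {
  stopifnot(is.data.frame(trials))
  keep <- if ("valid" %in% names(trials)) as.logical(trials$valid) else TRUE
  t2 <- trials[keep, , drop = FALSE]
  if (zero_only) t2 <- t2[t2$displacement_deg == 0, , drop = FALSE]
  cond <- condition_label(t2$saccade, t2$image_noise)
  agg <- as.data.frame(table(condition = cond, prior = t2$prior),
                       stringsAsFactors = FALSE)
  names(agg)[3] <- "n"
  agg$prior <- as.numeric(agg$prior)
  agg
}

#' Filter sessions by a minimum per-condition valid-trial count
#'
#' A session is analysis-eligible only if every condition-by-prior cell of the
#' standard protocol (priors 0.2 and 0.8 in all four noise conditions) has at
#' least `min_per_condition` valid trials; the zero-displacement control uses
#' the same rule restricted to displacement-zero trials.
#'
#' @param tables Named list of session trial tables.
#' @param min_per_condition Minimum valid trials per cell (default 10; the
#'   displacement-zero control uses 5).
#' @param zero_only Apply the count to displacement-zero trials only.
#' @return The eligible subset of `tables` (possibly empty), names preserved.
#' @export
filter_sessions <- function(tables, min_per_condition = 10, zero_only = FALSE) {
  stopifnot(is.list(tables), min_per_condition >= 1)
  required <- standard_condition_grid(include_half_prior = FALSE)
  ok <- vapply(tables, function(tab) {
    counts <- count_per_condition(tab, zero_only = zero_only)
    all(vapply(seq_len(nrow(required)), function(i) {
      m <- counts$condition == required$condition[i] &
        counts$prior == required$prior[i]
      any(m) && counts$n[m] >= min_per_condition
    }, logical(1)))
  }, logical(1))
  tables[ok]
}

trial_table_columns <- c("session_id", "prior", "saccade", "image_noise",
                         "probe_sigma", "displacement_deg", "response", "valid")

#' Read or write a behavioral trial table
#'
#' Trial tables are comma-separated text with a header row and columns
#' `session_id, prior, saccade, image_noise, probe_sigma, displacement_deg,
#' response, valid`. Displacements keep their sign in storage; model
#' computation uses magnitudes (both displacement distributions are centered
#' on zero).
#'
#' @param path File path.
#' @return `read_trial_table()` returns the validated data frame.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(df))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  validate_trials(df)
  df
}

#' @rdname read_trial_table
#' @param trials Trial table to write.
#' @export
write_trial_table <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, trial_table_columns], path, row.names = FALSE)
  invisible(path)
}

validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (!all(trials$response %in% c(0L, 1L))) {
    stop("`response` must be binary 0/1")
  }
  if (!all(trials$image_noise %in% c("low", "medium", "high"))) {
    stop("`image_noise` must be low/medium/high")
  }
  invisible(condition_label(trials$saccade, trials$image_noise))
}
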