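#' Event-aligned spike recording for one neuron
#'
#' Bundles per-trial spike event times (milliseconds relative to one or more
#' alignment events) with the behavioral labels of the same trials. Spike
#' tables are long format: `trial_id`, `alignment`, `time_ms`.
#'
#' @param neuron_id Identifier.
#' @param spikes Data frame with columns `trial_id`, `alignment`, `time_ms`.
#' @param trials Data frame with columns `trial_id`, `condition`, `prior`,
#'   `displacement`, `response` (one row per trial; joins 1:1 to the
#'   behavioral session).
#' @param windows Named list of the recorded window (ms, length 2) per
#'   alignment event.
#' @param pattern Optional ground-truth pattern label for synthetic neurons.
#' @return Object of class `neuron_recording`.
#' @export
neuron_recording <- function(neuron_id, spikes, trials, windows,
                             pattern = NULL) {
  stopifnot(all(c("trial_id", "alignment", "time_ms") %in% names(spikes)),
            all(c("trial_id", "condition", "prior") %in% names(trials)),
            !anyDuplicated(trials$trial_id))
  if (!all(unique(spikes$alignment) %in% names(windows))) {
    stop("every spike alignment needs a recorded window")
  }
  structure(list(neuron_id = neuron_id, spikes = spikes, trials = trials,
                 windows = windows, pattern = pattern),
            class = "neuron_recording")
}

# Per-trial spike counts on a uniform bin grid for one alignment.
spike_count_matrix <- function(rec, alignment, window = NULL, bin_ms = 20) {
  stopifnot(inherits(rec, "neuron_recording"))
  if (!alignment %in% names(rec$windows)) {
    stop("alignment '", alignment, "' not recorded for neuron ", rec$neuron_id)
  }
  if (is.null(window)) window <- rec$windows[[alignment]]
  edges <- seq(window[1], window[2], by = bin_ms)
  if (length(edges) < 2) stop("window shorter than one bin")
  sp <- rec$spikes[rec$spikes$alignment == alignment, ]
  ids <- rec$trials$trial_id
  counts <- matrix(0L, nrow = length(ids), ncol = length(edges) - 1,
                   dimnames = list(ids, NULL))
  if (nrow(sp) > 0) {
    keep <- sp$time_ms >= window[1] & sp$time_ms < window[2]
    sp <- sp[keep, ]
    if (nrow(sp) > 0) {
      bi <- findInterval(sp$time_ms, edges, rightmost.closed = FALSE)
      ti <- match(sp$trial_id, ids)
      ok <- !is.na(ti) & bi >= 1 & bi <= ncol(counts)
      tab <- table(factor(ti[ok], levels = seq_along(ids)),
                   factor(bi[ok], levels = seq_len(ncol(counts))))
      counts <- matrix(as.integer(tab), nrow = length(ids),
                       dimnames = list(ids, NULL))
    }
  }
  list(counts = counts, edges = edges, bin_ms = bin_ms)
}

#' Z-score normalized firing-rate series
#'
#' Bins spikes across all task conditions into non-overlapping bins (20 ms by
#' default), subtracts the pooled mean of the bins and divides by their
#' pooled standard deviation, so that the normalized bins have mean 0 and SD
#' 1 across all trials and conditions. A silent neuron (pooled SD of 0) is
#' flagged and excluded from normalization-dependent analyses.
#'
#' @param rec A [neuron_recording()].
#' @param alignment Alignment event to bin against.
#' @param window Window in ms (defaults to the recorded window).
#' @param bin_ms Bin width, ms.
#' @return List with `z` (trials-by-bins matrix), `edges`, `mean`, `sd` and
#'   `flagged` (`TRUE` for a silent neuron; `z` is then `NULL`).
#' @export
zscore_rates <- function(rec, alignment, window = NULL, bin_ms = 20) {
  cm <- spike_count_matrix(rec, alignment, window, bin_ms)
  m <- mean(cm$counts)
  s <- stats::sd(as.vector(cm$counts))
  if (is.na(s) || s == 0) {
    return(list(z = NULL, edges = cm$edges, mean = m, sd = s, flagged = TRUE))
  }
  list(z = (cm$counts - m) / s, edges = cm$edges, mean = m, sd = s,
       flagged = FALSE)
}

#' Gaussian smoothing of a rate series
#'
#' Linear convolution with a unit-area Gaussian kernel (SD 20 ms by default,
#' truncated at three SDs), applied along time. The interior of a constant
#' series is unchanged and the series sum is preserved up to edge effects.
#'
#' @param series Numeric vector, or matrix with time along columns.
#' @param kernel_sigma_ms Kernel SD in ms.
#' @param bin_ms Bin width of the series, ms.
#' @return Smoothed series of the same shape.
#' @export
smooth_rates <- function(series, kernel_sigma_ms = 20, bin_ms = 20) {
  sigma_bins <- kernel_sigma_ms / bin_ms
  half <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    padded <- c(rep(0, half), v, rep(0, half))
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  if (is.matrix(series)) t(apply(series, 1, smooth_vec)) else smooth_vec(series)
}

#' Mean firing rate in a task epoch
#'
#' Spike count inside the window divided by the window duration, in
#' spikes/s, per trial. The two canonical epochs are fixation (0-250 ms from
#' fixation acquisition) and reafferent (0-800 ms from the offset of the
#' intervening saccade).
#'
#' @param rec A [neuron_recording()].
#' @param alignment Alignment event.
#' @param start,end Epoch bounds in ms relative to the alignment.
#' @return Data frame with `trial_id` and `rate` (spikes/s).
#' @export
epoch_rate <- function(rec, alignment, start, end) {
  stopifnot(start < end)
  if (!alignment %in% names(rec$windows)) {
    stop("alignment '", alignment, "' not recorded for neuron ", rec$neuron_id)
  }
  sp <- rec$spikes[rec$spikes$alignment == alignment, ]
  inwin <- sp[sp$time_ms >= start & sp$time_ms < end, ]
  n <- table(factor(inwin$trial_id, levels = rec$trials$trial_id))
  data.frame(trial_id = rec$trials$trial_id,
             rate = as.numeric(n) / ((end - start) / 1000))
}

#' Signed Wilcoxon rank-sum effect size
#'
#' Rank-sum z statistic (tie-corrected normal approximation, no continuity
#' correction) divided by the square root of the total sample size. The sign
#' is positive when the high-prior sample tends to exceed the low-prior
#' sample. Two completely identical samples give effect 0 with p = 1.
#'
#' @param high,low Numeric samples (e.g. high- and low-prior epoch rates).
#' @return List of class `effect_size`: `effect`, `z`, `p`, `n_high`,
#'   `n_low`.
#' @export
wilcoxon_effect <- function(high, low) {
  n1 <- length(high); n2 <- length(low)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  pooled <- c(high, low)
  N <- n1 + n2
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(pooled)
  v <- n1 * n2 * (N + 1) / 12 -
    n1 * n2 * sum(ties^3 - ties) / (12 * N * (N - 1))
  if (v <= 0) {
    res <- list(effect = 0, z = 0, p = 1, n_high = n1, n_low = n2)
    return(structure(res, class = "effect_size"))
  }
  z <- (R1 - mu) / sqrt(v)
  structure(list(effect = z / sqrt(N), z = z,
                 p = 2 * stats::pnorm(-abs(z)), n_high = n1, n_low = n2),
            class = "effect_size")
}

# High- and low-prior epoch rates of one neuron in one condition.
prior_epoch_rates <- function(rec, alignment, start, end,
                              condition = "saccade_low",
                              priors = c(0.2, 0.8)) {
  rates <- epoch_rate(rec, alignment, start, end)
  lab <- as.character(rec$trials$condition)
  hi <- rates$rate[lab == condition & rec$trials$prior == priors[2]]
  lo <- rates$rate[lab == condition & rec$trials$prior == priors[1]]
  list(high = hi, low = lo)
}

#' Per-neuron prior-selectivity screen in the canonical epochs
#'
#' For each neuron, contrasts high- against low-prior firing rates in the
#' fixation (0-250 ms) and reafferent (0-800 ms) epochs of the common
#' condition with the rank-sum effect size, at alpha = 0.025 (two-epoch
#' correction of 0.05).
#'
#' @param neurons List of [neuron_recording()] objects.
#' @param epochs Named list of `list(alignment=, start=, end=)` epochs.
#' @param alpha Significance level per epoch.
#' @param condition Condition screened (the common condition).
#' @return Data frame: `neuron_id`, `epoch`, `effect`, `p`, `significant`.
#' @export
epoch_prior_screen <- function(neurons,
                               epochs = list(
                                 fixation = list(alignment = "fixation",
                                                 start = 0, end = 250),
                                 reafferent = list(alignment = "reafferent",
                                                   start = 0, end = 800)),
                               alpha = 0.025,
                               condition = "saccade_low") {
  rows <- lapply(neurons, function(rec) {
    do.call(rbind, lapply(names(epochs), function(en) {
      ep <- epochs[[en]]
      rr <- prior_epoch_rates(rec, ep$alignment, ep$start, ep$end, condition)
      es <- wilcoxon_effect(rr$high, rr$low)
      data.frame(neuron_id = rec$neuron_id, epoch = en,
                 effect = es$effect, p = es$p,
                 significant = es$p < alpha, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-bin prior-effect time course in the reafferent epoch
#'
#' Contrasts high- against low-prior spike counts in successive 100 ms bins
#' stepped by 50 ms across the 0-800 ms reafferent span (15 bins), each at
#' the further-corrected alpha of 0.025/15.
#'
#' @param rec A [neuron_recording()].
#' @param window_ms,step_ms Bin width and step, ms.
#' @param span Length-2 span in ms relative to the reafferent event.
#' @param alpha Per-bin significance level.
#' @param condition Condition analyzed.
#' @param alignment Alignment event.
#' @return List with `bins` (data frame: `start`, `end`, `effect`, `p`,
#'   `significant`) and `earliest_significant` (bin index or `NA`).
#' @export
sliding_bins <- function(rec, window_ms = 100, step_ms = 50,
                         span = c(0, 800), alpha = 0.025 / 15,
                         condition = "saccade_low",
                         alignment = "reafferent") {
  starts <- seq(span[1], span[2] - window_ms, by = step_ms)
  bins <- do.call(rbind, lapply(starts, function(s) {
    rr <- prior_epoch_rates(rec, alignment, s, s + window_ms, condition)
    es <- wilcoxon_effect(rr$high, rr$low)
    data.frame(start = s, end = s + window_ms, effect = es$effect,
               p = es$p, significant = es$p < alpha)
  }))
  rownames(bins) <- NULL
  first <- which(bins$significant)
  list(bins = bins,
       earliest_significant = if (length(first)) first[1] else NA_integer_)
}

#' Normalize per-condition values to the common condition
#'
#' Divides each condition's value by the common-condition value of the same
#' session, so the common condition maps to exactly 1. A common value whose
#' magnitude is below the floor makes the normalization unreliable; the
#' session is flagged with `NA` values instead.
#'
#' @param values Named numeric vector of per-condition values.
#' @param common The common-condition value.
#' @param floor Minimum `|common|` accepted.
#' @return Normalized vector (or all-`NA` when flagged).
#' @export
normalize_to_common <- function(values, common, floor = 0.01) {
  if (!is.finite(common) || abs(common) < floor) {
    out <- rep(NA_real_, length(values))
    names(out) <- names(values)
    return(out)
  }
  values / common
}

#' Session-wise correlation between neuronal and behavioral prior use
#'
#' Pearson correlation across sessions between the common-normalized
#' neuronal effect sizes and the common-normalized behavioral prior use for
#' one noise condition.
#'
#' @param neuronal,behavioral Paired per-session normalized values.
#' @return List `r`, `p`, `n` (pairs used). Pairs with missing values are
#'   dropped; fewer than 3 complete pairs or zero variance gives `NA` with a
#'   warning.
#' @export
neuron_behavior_correlation <- function(neuronal, behavioral) {
  stopifnot(length(neuronal) == length(behavioral))
  ok <- is.finite(neuronal) & is.finite(behavioral)
  x <- neuronal[ok]; y <- behavioral[ok]
  if (length(x) < 3) {
    warning("fewer than 3 complete session pairs")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one of the vectors")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Classify a neuron's prior-modulation pattern across noise conditions
#'
#' Compares the prior effect in each noise condition with the common
#' condition and assigns the qualitative signature: `bayesian` (effect grows
#' with saccade-driven noise, unchanged by image noise), `anti_bayesian`
#' (unchanged by saccade-driven noise, shrinks with image noise),
#' `prior_only` (unchanged everywhere) or `output_mirroring` (tracks the
#' behavioral pattern: both changes). Profiles matching none of the four
#' signatures are `unclassified`.
#'
#' @param effects Named numeric vector of prior effect sizes for the four
#'   conditions (names as in [condition_levels()]).
#' @param threshold Relative change in the common-normalized effect treated
#'   as a real departure from the common condition.
#' @param floor Minimum `|common effect|` for classification.
#' @return Character scalar pattern label.
#' @export
classify_pattern <- function(effects, threshold = 0.3, floor = 0.01) {
  stopifnot(all(condition_levels() %in% names(effects)))
  common <- effects[["saccade_low"]]
  ratios <- normalize_to_common(effects[condition_levels()], common,
                                floor = floor)
  if (anyNA(ratios)) return("unclassified")
  # a ratio far outside the range any signature predicts marks a profile
  # none of the four cartoons generates
  if (any(ratios > 1.75 | ratios < -0.75)) return("unclassified")
  r_ns <- ratios[["no_saccade"]]
  r_img <- mean(c(ratios[["saccade_medium"]], ratios[["saccade_high"]]))
  saccade_change <- (1 - r_ns) > threshold
  image_change <- (1 - r_img) > threshold
  if (saccade_change && image_change) return("output_mirroring")
  if (saccade_change) return("bayesian")
  if (image_change) return("anti_bayesian")
  "prior_only"
}

#' Read or write a long-format spike table
#'
#' Spike tables are comma-separated text with header `neuron_id, trial_id,
#' alignment_event, spike_time_ms`.
#'
#' @param path File path.
#' @return `read_spike_table()` returns the data frame.
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "trial_id", "alignment_event", "spike_time_ms")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("spike table missing: ",
                            paste(missing, collapse = ", "))
  df
}

#' @rdname read_spike_table
#' @param neurons List of [neuron_recording()] objects to serialize.
#' @export
write_spike_table <- function(neurons, path) {
  rows <- do.call(rbind, lapply(neurons, function(rec) {
    data.frame(neuron_id = rec$neuron_id,
               trial_id = rec$spikes$trial_id,
               alignment_event = rec$spikes$alignment,
               spike_time_ms = rec$spikes$time_ms)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
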