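# Shared fixtures, all built in code.

# A tiny valid session table covering the full standard grid.
make_session <- function(n_per_cell = 12, seed = 1, session_id = "s1") {
  set.seed(seed)
  grid <- standard_condition_grid(include_half_prior = FALSE)
  cells <- grid[rep(seq_len(nrow(grid)), each = n_per_cell), ]
  n <- nrow(cells)
  data.frame(session_id = session_id,
             prior = cells$prior, saccade = cells$saccade,
             image_noise = cells$image_noise,
             probe_sigma = cells$probe_sigma,
             displacement_deg = round(abs(rnorm(n, 0, 1.5)), 2),
             response = rbinom(n, 1, 0.5),
             valid = 1L,
             condition = cells$condition,
             stringsAsFactors = FALSE)
}

# A neuron recording with hand-placed spikes: `spike_times` is a named list
# alignment -> list(trial_id -> numeric times).
make_neuron <- function(spike_times, trials,
                        windows = list(fixation = c(-100, 400),
                                       reafferent = c(-200, 1000)),
                        neuron_id = "n1") {
  rows <- list()
  for (al in names(spike_times)) {
    for (tid in names(spike_times[[al]])) {
      tms <- spike_times[[al]][[tid]]
      if (length(tms)) {
        rows[[length(rows) + 1]] <- data.frame(
          trial_id = tid, alignment = al, time_ms = tms)
      }
    }
  }
  sp <- if (length(rows)) do.call(rbind, rows)
        else data.frame(trial_id = character(), alignment = character(),
                        time_ms = numeric())
  neuron_recording(neuron_id, sp, trials, windows)
}

# Exhaustive rank-sum two-sided p-value by enumerating all group
# assignments (independent oracle for the normal approximation).
exact_ranksum_p <- function(high, low) {
  pooled <- c(high, low)
  n1 <- length(high)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (length(pooled) + 1) / 2)
  sets <- utils::combn(length(pooled), n1)
  stats <- apply(sets, 2, function(ix) {
    abs(sum(r[ix]) - n1 * (length(pooled) + 1) / 2)
  })
  mean(stats >= obs - 1e-12)
}
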