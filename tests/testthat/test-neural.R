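trials4 <- data.frame(trial_id = c("t1", "t2", "t3", "t4"),
                      condition = "saccade_low",
                      prior = c(0.2, 0.2, 0.8, 0.8),
                      displacement = 1, response = c(0, 0, 1, 1),
                      stringsAsFactors = FALSE)

test_that("z-scored rates pool to mean 0 and SD 1; silent neurons flagged", {
  set.seed(61)
  spikes <- list(reafferent = lapply(setNames(trials4$trial_id,
                                              trials4$trial_id), function(t) {
    sort(runif(rpois(1, 30), -200, 1000))
  }))
  rec <- make_neuron(spikes, trials4)
  z <- zscore_rates(rec, "reafferent")
  expect_false(z$flagged)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(z$z)), 1, tolerance = 1e-9)
  # brute-force oracle: two-pass (count - mean) / sd on hand-binned counts
  counts <- t(sapply(trials4$trial_id, function(t) {
    hist(spikes$reafferent[[t]], breaks = seq(-200, 1000, by = 20),
         plot = FALSE, right = FALSE)$counts
  }))
  expect_equal(unname(z$z), unname((counts - mean(counts)) / sd(counts)),
               tolerance = 1e-9)

  # a perfectly regular neuron (one spike per bin) has zero pooled SD
  reg <- list(reafferent = lapply(setNames(trials4$trial_id,
                                           trials4$trial_id), function(t) {
    seq(-195, 995, by = 20)
  }))
  zr <- zscore_rates(make_neuron(reg, trials4), "reafferent")
  expect_true(zr$flagged)
  expect_null(zr$z)
})

test_that("Gaussian smoothing preserves area and leaves constants alone", {
  v <- numeric(101); v[51] <- 1
  sm <- smooth_rates(v)
  expect_equal(sum(sm), 1, tolerance = 1e-9)  # unit-area bump
  expect_equal(which.max(sm), 51)
  const <- rep(2.5, 80)
  smc <- smooth_rates(const)
  expect_equal(smc[10:70], const[10:70], tolerance = 1e-9)  # interior
  # direct O(n k) convolution oracle
  set.seed(62)
  x <- rnorm(60)
  half <- 3
  k <- dnorm(-half:half); k <- k / sum(k)
  oracle <- vapply(seq_along(x), function(i) {
    acc <- 0
    for (j in -half:half) {
      xi <- i + j
      if (xi >= 1 && xi <= length(x)) acc <- acc + x[xi] * k[j + half + 1]
    }
    acc
  }, numeric(1))
  expect_equal(smooth_rates(x, kernel_sigma_ms = 20, bin_ms = 20), oracle,
               tolerance = 1e-9)
})

test_that("epoch rates are counts over duration in spikes per second", {
  spikes <- list(reafferent = list(
    t1 = c(100, 200, 300, 350, 400, 500, 600, 700),  # 8 spikes in 800 ms
    t2 = numeric(0),
    t3 = c(-50, 900),                                # outside the epoch
    t4 = c(0, 799.9)))
  rec <- make_neuron(spikes, trials4)
  r <- epoch_rate(rec, "reafferent", 0, 800)
  expect_equal(r$rate, c(10, 0, 0, 2.5))
  expect_error(epoch_rate(rec, "fixation2", 0, 100), "not recorded")
  expect_error(epoch_rate(rec, "reafferent", 500, 100))
})

test_that("Wilcoxon effect size carries the stated sign and bounds", {
  # identical samples: effect 0, p 1
  same <- wilcoxon_effect(c(1, 1, 2), c(2, 1, 1))
  expect_equal(same$effect, 0)
  expect_equal(same$p, 1)
  # complete separation reaches the maximal effect for those n, positive
  # when the high sample is larger
  hi <- c(11, 12, 13, 14); lo <- c(1, 2, 3, 4)
  es <- wilcoxon_effect(hi, lo)
  n1 <- 4; n2 <- 4; N <- 8
  zmax <- (sum(5:8) - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(es$effect, zmax / sqrt(N))
  expect_equal(wilcoxon_effect(lo, hi)$effect, -es$effect)
  expect_error(wilcoxon_effect(numeric(0), lo), "nonempty")
})

test_that("normal-approximation p agrees with exhaustive enumeration", {
  set.seed(63)
  for (i in 1:6) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    hi <- round(rnorm(n1, 1), 1)
    lo <- round(rnorm(n2, 0), 1)
    es <- wilcoxon_effect(hi, lo)
    pex <- exact_ranksum_p(hi, lo)
    expect_lt(abs(es$p - pex), 0.06)
    # and the approximation never flips a clear decision at alpha = 0.025
    if (pex < 0.005) expect_lt(es$p, 0.025)
    if (pex > 0.2) expect_gt(es$p, 0.025)
  }
})

test_that("sliding bins cover the reafferent span with 15 windows", {
  truth <- ground_truth(behavioral_model = "logistic")
  tab <- gen_behavior(truth, n_trials = 400, seed = 64)
  rec <- gen_neuron(truth, tab, seed = 65)
  sb <- sliding_bins(rec)
  expect_equal(nrow(sb$bins), 15)
  expect_equal(sb$bins$start, seq(0, 700, by = 50))
  expect_equal(unique(sb$bins$end - sb$bins$start), 100)
})

test_that("modulation injected in a known window is found at its onset", {
  # rate difference only between 150 and 400 ms -> earliest significant
  # bin is the first window inside the modulated interval
  set.seed(66)
  n <- 120
  tid <- sprintf("t%03d", seq_len(n))
  trials <- data.frame(trial_id = tid, condition = "saccade_low",
                       prior = rep(c(0.2, 0.8), each = n / 2),
                       displacement = 0, response = 0,
                       stringsAsFactors = FALSE)
  mk_times <- function(high) {
    base <- runif(rpois(1, 24), -200, 1000)
    if (high) c(base, runif(rpois(1, 15), 150, 400)) else base
  }
  spikes <- list(reafferent = lapply(setNames(seq_len(n), tid), function(i) {
    sort(mk_times(trials$prior[i] == 0.8))
  }))
  rec <- make_neuron(spikes, trials)
  sb <- sliding_bins(rec)
  expect_true(sb$earliest_significant %in% c(3, 4))
  expect_true(all(!sb$bins$significant[10:15]))
})

test_that("common-condition normalization is an exact ratio with a floor", {
  v <- c(no_saccade = 0.2, saccade_low = 0.4, saccade_medium = 0.1,
         saccade_high = 0.05)
  nv <- normalize_to_common(v, v[["saccade_low"]])
  expect_equal(unname(nv), c(0.5, 1, 0.25, 0.125))
  expect_equal(nv[["saccade_low"]], 1)
  expect_true(all(is.na(normalize_to_common(v, 0.005))))
})

test_that("neuron-behavior correlation behaves at the extremes", {
  x <- c(0.2, 0.5, 0.9, 1.2, 0.4)
  expect_equal(neuron_behavior_correlation(x, x)$r, 1)
  expect_warning(r2 <- neuron_behavior_correlation(x[1:2], x[1:2]), "3")
  expect_true(is.na(r2$r))
  expect_warning(r3 <- neuron_behavior_correlation(rep(1, 5), x), "variance")
  expect_true(is.na(r3$r))
  set.seed(67)
  hits <- replicate(300, {
    neuron_behavior_correlation(rnorm(12), rnorm(12))$p < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("pattern signatures map to the four qualitative outcomes", {
  base <- c(no_saccade = 0.5, saccade_low = 0.5, saccade_medium = 0.5,
            saccade_high = 0.5)
  expect_equal(classify_pattern(base), "prior_only")
  anti <- base; anti[c("saccade_medium", "saccade_high")] <- c(0.25, 0.1)
  expect_equal(classify_pattern(anti), "anti_bayesian")
  bay <- base; bay["no_saccade"] <- 0.15
  expect_equal(classify_pattern(bay), "bayesian")
  mirror <- c(no_saccade = 0.15, saccade_low = 0.5, saccade_medium = 0.25,
              saccade_high = 0.1)
  expect_equal(classify_pattern(mirror), "output_mirroring")
  weird <- base; weird["no_saccade"] <- 1.5   # effect grows off-common
  expect_equal(classify_pattern(weird), "unclassified")
  expect_equal(classify_pattern(base * 0.001), "unclassified")
})

test_that("spike tables round-trip through CSV", {
  truth <- ground_truth(behavioral_model = "logistic")
  tab <- gen_behavior(truth, n_trials = 100, seed = 68)
  rec <- gen_neuron(truth, tab, seed = 69)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(list(rec), path)
  back <- read_spike_table(path)
  expect_equal(nrow(back), nrow(rec$spikes))
  expect_setequal(unique(back$alignment_event), c("fixation", "reafferent"))
})
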