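test_that("the smoothing recurrence matches its scalar roll-out exactly", {
  # fixed point
  expect_equal(as.numeric(tune_index(rep(50, 4), 50)), 50)
  # defining weights
  expect_equal(as.numeric(tune_index(rep(40, 4), 90)), 0.8 * 40 + 0.2 * 90)
  # empty history passes through, flagged
  t0 <- tune_index(numeric(0), 73)
  expect_equal(as.numeric(t0), 73)
  expect_true(attr(t0, "no_history"))
  # step response 0 -> 100: monotone approach, increments bounded by 0.2*100
  raw <- c(rep(0, 5), rep(100, 40))
  got <- numeric(length(raw))
  recent <- numeric(0)
  for (i in seq_along(raw)) {
    got[i] <- as.numeric(tune_index(recent, raw[i]))
    recent <- tail(c(recent, raw[i]), 4)
  }
  expect_equal(got, oracle_tuned_rollout(raw))
  after <- got[6:length(got)]
  expect_true(all(diff(after) >= -1e-12))
  expect_true(all(diff(got) <= 20 + 1e-12))
  expect_lt(abs(tail(got, 1) - 100), 1e-6)
  # bounded raw input keeps the tuned trace inside its range
  set.seed(13)
  raw2 <- runif(200, 20, 80)
  roll <- oracle_tuned_rollout(raw2)
  expect_true(all(roll >= 20 & roll <= 80))
})

test_that("streaming enforces the start-up delay and the sample contract", {
  qm <- ndoa_quick_model()
  st <- stream_init(qm$model)
  expect_error(stream_step(st, rnorm(100)), "128 samples")
  log <- qm$log
  n_sec <- 20
  rows <- lapply(seq_len(n_sec), function(t) {
    stream_step(st, log$samples[((t - 1) * 128 + 1):(t * 128)])
  })
  tr <- dplyr::bind_rows(rows)
  expect_equal(nrow(tr), 20)
  expect_false(any(tr$valid[1:4]))
  expect_true(all(is.na(tr$tuned[1:4])))
  expect_true(all(tr$valid[5:20]))
  expect_true(all(tr$tuned[5:20] >= 0 & tr$tuned[5:20] <= 100))
})

test_that("stream, whole-record, and feature-table paths agree exactly", {
  qm <- ndoa_quick_model()
  short <- new_datalog(qm$log$samples[1:(30 * 128)], qm$log$annotations[1:30, ],
                       subject_id = qm$log$subject_id)
  tr_batch <- run_record(short, qm$model)
  st <- stream_init(qm$model)
  tr_stream <- dplyr::bind_rows(lapply(seq_len(30), function(t) {
    stream_step(st, short$samples[((t - 1) * 128 + 1):(t * 128)])
  }))
  expect_equal(tr_batch[, c("t_s", "raw", "tuned", "valid")],
               tr_stream[, c("t_s", "raw", "tuned", "valid")],
               ignore_attr = TRUE)
  feats <- extract_feature_table(short, qm$model$denoise, qm$model$features)
  tr_feats <- trace_from_features(feats, qm$model)
  expect_equal(tr_batch$raw, tr_feats$raw)
  expect_equal(tr_batch$tuned, tr_feats$tuned)
})

test_that("a stationary record converges to a constant index", {
  qm <- ndoa_quick_model()
  sched <- state_schedule(c("deep"), 60)
  log <- generate_record(sched, noise_spec(spike_rate_per_min = 0,
                                           low_amp_rate_per_min = 0), seed = 77)
  tr <- run_record(log, qm$model)
  last10 <- tail(tr$tuned[tr$valid], 10)
  expect_lt(sd(last10), 3)
  expect_lt(max(abs(diff(last10))), 5)
})

test_that("the index tracks induction: lower in deep than awake spans", {
  qm <- ndoa_quick_model()
  sched <- state_schedule(c("awake", "deep"), c(40, 40))
  log <- generate_record(sched, noise_spec(), seed = 5)
  tr <- run_record(log, qm$model)
  truth <- attr(log, "truth")
  mean_awake <- mean(tr$tuned[tr$valid & truth$state == "awake"], na.rm = TRUE)
  mean_deep <- mean(tr$tuned[tr$valid & truth$state == "deep"], na.rm = TRUE)
  expect_gt(mean_awake, mean_deep)
})

test_that("EMG bursts move the index less than a naive spectral-power index", {
  qm <- ndoa_quick_model()
  n_seeds <- 10
  wins <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    bursts <- tibble::tibble(start_s = c(30, 80), duration_s = c(20, 20))
    log <- generate_record(
      state_schedule("deep", 120),
      noise_spec(spike_rate_per_min = 0, low_amp_rate_per_min = 0,
                 emg_bursts = bursts, emg_mult = 1.5),
      seed = 3000 + s
    )
    tr <- run_record(log, qm$model)
    burst_sec <- c(30:49, 80:99)
    base_sec <- setdiff(which(tr$valid) - 1L, c(burst_sec, 25:29, 75:79, 50:54, 100:104))
    # naive comparator: relative 30-60 Hz power per second, on a 0-100 scale
    naive <- sapply(0:119, function(t) {
      seg <- log$samples[(t * 128 + 1):((t + 1) * 128)]
      100 * oracle_band_power(seg, 128, c(30, 60)) /
        oracle_band_power(seg, 128, c(0.5, 60))
    })
    exc <- function(idx_trace, idx_base, series) {
      max(abs(series[idx_trace + 1] - median(series[idx_base + 1], na.rm = TRUE)),
          na.rm = TRUE)
    }
    wins[s] <- exc(burst_sec, base_sec, tr$tuned) < exc(burst_sec, base_sec, naive)
  }
  expect_gte(sum(wins), 8)
})
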