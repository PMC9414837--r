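# Shared fixtures, computed lazily once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# A deep-anaesthesia-like clean window (high-voltage slow oscillation) with
# isolated spikes of 10x the oscillation amplitude, as seen on monitor logs
# contaminated by electrode artifacts.
make_spike_fixture <- function(seed, amplitude = 60, n_spikes = 4,
                               spike_mult = 10) {
  set.seed(seed)
  t <- (0:1279) / 128
  f0 <- runif(1, 1.5, 3)
  clean <- amplitude * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
  noisy <- clean
  pos <- sample(1280, n_spikes)
  noisy[pos] <- noisy[pos] +
    sample(c(-1, 1), n_spikes, TRUE) * spike_mult * amplitude
  list(clean = clean, noisy = noisy, spike_at = pos)
}

# Single awake-like / deep-like windows (band-limited noise), for feature
# direction checks.
make_state_window <- function(state, seed, n = 1280, fs = 128) {
  set.seed(seed)
  bands <- if (state == "awake") {
    list(c(0.5, 4, 0.10), c(4, 8, 0.15), c(8, 30, 0.60), c(30, 47, 0.15))
  } else {
    list(c(0.5, 4, 0.75), c(4, 8, 0.15), c(8, 30, 0.09), c(30, 47, 0.01))
  }
  rms <- if (state == "awake") 5 else 20
  x <- numeric(n)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  for (b in bands) {
    spec <- fft(rnorm(n))
    spec[!(f >= b[1] & f <= b[2])] <- 0
    xb <- Re(fft(spec, inverse = TRUE)) / n
    x <- x + sqrt(b[3]) * rms * xb / sd(xb)
  }
  x
}

# The 10-record synthetic benchmark with per-record feature tables and
# record-wise held-out traces (each pair of records scored by a model trained
# on the other eight).
ndoa_benchmark <- function() {
  .cached("benchmark", {
    bm <- make_benchmark(10, seed = 7)
    feats <- lapply(bm$logs, function(l) {
      extract_feature_table(l)
    })
    train_tbls <- lapply(seq_along(bm$logs), function(i) {
      build_training_set(feats[[i]], bm$logs[[i]]$annotations,
                         subject_id = bm$logs[[i]]$subject_id)
    })
    folds <- split(seq_along(bm$logs), rep(1:5, each = 2))
    traces <- vector("list", length(bm$logs))
    models <- vector("list", length(folds))
    for (k in seq_along(folds)) {
      hold <- folds[[k]]
      m <- ndoa_fit(dplyr::bind_rows(train_tbls[-hold]), "sq_exp_gp", seed = 7)
      models[[k]] <- m
      for (i in hold) {
        traces[[i]] <- trace_from_features(feats[[i]], m,
                                           subject_id = bm$logs[[i]]$subject_id)
      }
    }
    list(bm = bm, feats = feats, train_tbls = train_tbls,
         heldout_traces = traces, fold_models = models,
         model = models[[5]])  # trained on records 1-8
  })
}

# A quick single-record GP model for streaming and CLI tests.
ndoa_quick_model <- function() {
  .cached("quick_model", {
    sched <- state_schedule(c("awake", "moderate", "deep"), c(30, 20, 30))
    log <- generate_record(sched, noise_spec(), seed = 42)
    feats <- extract_feature_table(log)
    train <- build_training_set(feats, log$annotations, log$subject_id)
    list(log = log, feats = feats,
         model = ndoa_fit(train, "sq_exp_gp", seed = 42))
  })
}
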