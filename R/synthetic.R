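# Synthetic data-log generator. Emulates the statistical structure the
# pipeline assumes: low-voltage high-frequency EEG awake, high-voltage
# low-frequency EEG in deep anaesthesia, smooth state transitions, spike and
# low-amplitude noise episodes, EMG bursts, SQI dropouts with the invalid
# reference sentinel, and a smooth 0-100 reference trace.

# Per-state generator settings: total rms amplitude (microvolts) and relative
# power in the four nominal EEG bands (delta 0.5-4, theta 4-8, alpha/beta
# 8-30, gamma 30-47 Hz). Amplitudes follow the classic awake (+/-15 uV,
# broadband fast) vs deep (+/-60 uV, slow dominant) contrast; intermediate
# states interpolate. Reference targets follow the conventional clinical
# bands (general anaesthesia around 40-60).
.ndoa_states <- list(
  awake    = list(rms = 5,  bands = c(delta = 0.10, theta = 0.15, alphabeta = 0.60, gamma = 0.15), target = 90),
  light    = list(rms = 8,  bands = c(delta = 0.25, theta = 0.30, alphabeta = 0.40, gamma = 0.05), target = 65),
  moderate = list(rms = 12, bands = c(delta = 0.45, theta = 0.30, alphabeta = 0.22, gamma = 0.03), target = 50),
  deep     = list(rms = 20, bands = c(delta = 0.75, theta = 0.15, alphabeta = 0.09, gamma = 0.01), target = 30)
)

.ndoa_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alphabeta = c(8, 30), gamma = c(30, 47))

#' Anaesthetic-state schedule
#'
#' An ordered sequence of (state, duration) segments describing a simulated
#' case. States are `awake`, `light`, `moderate`, `deep`, mapped to reference
#' index targets 90/65/50/30.
#'
#' @param states Character vector of states.
#' @param durations_s Integer vector of segment durations in seconds
#'   (each at least 10; total at least 60).
#' @return A tibble of class `ndoa_schedule` with columns `state`,
#'   `duration_s`, `target`.
#' @export
state_schedule <- function(states = c("awake", "light", "moderate", "deep"),
                           durations_s = c(40, 30, 30, 60)) {
  stopifnot(length(states) == length(durations_s))
  if (!all(states %in% names(.ndoa_states))) {
    stop("states must be in {", paste(names(.ndoa_states), collapse = ", "), "}",
         call. = FALSE)
  }
  if (any(durations_s < 10)) stop("each segment must last >= 10 s", call. = FALSE)
  if (sum(durations_s) < 60) stop("total duration must be >= 60 s", call. = FALSE)
  out <- tibble::tibble(
    state = states,
    duration_s = as.integer(durations_s),
    target = vapply(states, function(s) .ndoa_states[[s]]$target, numeric(1))
  )
  class(out) <- c("ndoa_schedule", class(out))
  out
}

#' Noise specification for the generator
#'
#' @param spike_rate_per_min Expected isolated spikes per minute.
#' @param spike_mult Spike amplitude as a multiple of the local rms (default
#'   10; the denoiser's spike tests assume > 5).
#' @param low_amp_rate_per_min Expected low-amplitude episodes per minute
#'   (2 s spans where the signal collapses to a fraction of its amplitude).
#' @param low_amp_frac Amplitude fraction during such episodes.
#' @param emg_bursts Tibble with `start_s`, `duration_s` of EMG bursts
#'   (30-60 Hz contamination), or NULL.
#' @param emg_mult EMG burst rms as a multiple of the local signal rms.
#' @param sqi_dropouts Tibble with `start_s`, `duration_s` of low-SQI spans
#'   (SQI 10, reference = sentinel), or NULL.
#' @return A list of class `ndoa_noise_spec`.
#' @export
noise_spec <- function(spike_rate_per_min = 2, spike_mult = 10,
                       low_amp_rate_per_min = 0.5, low_amp_frac = 0.1,
                       emg_bursts = NULL, emg_mult = 1.5,
                       sqi_dropouts = NULL) {
  stopifnot(spike_rate_per_min >= 0, low_amp_rate_per_min >= 0)
  structure(
    list(spike_rate_per_min = spike_rate_per_min, spike_mult = spike_mult,
         low_amp_rate_per_min = low_amp_rate_per_min, low_amp_frac = low_amp_frac,
         emg_bursts = emg_bursts, emg_mult = emg_mult,
         sqi_dropouts = sqi_dropouts),
    class = "ndoa_noise_spec"
  )
}

# Band-limited unit-rms noise of length n via FFT masking of white noise.
.band_noise <- function(n, fs, band, rng_noise) {
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  mask <- f >= band[1] & f <= band[2]
  spec <- stats::fft(rng_noise)
  spec[!mask] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Per-sample state weights with raised-cosine crossfades of `fade_s` seconds
# centred on each segment boundary.
.state_weights <- function(schedule, fs, fade_s = 5) {
  n <- sum(schedule$duration_s) * fs
  starts <- cumsum(c(0, head(schedule$duration_s, -1))) * fs
  w <- matrix(0, nrow = n, ncol = nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    seg <- rep(0, n)
    seg[(starts[i] + 1):(starts[i] + schedule$duration_s[i] * fs)] <- 1
    w[, i] <- seg
  }
  half <- (fade_s * fs) %/% 2
  if (half > 0 && nrow(schedule) > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(2 * half) / (2 * half + 1)))
    for (i in seq_len(nrow(schedule) - 1)) {
      b <- starts[i + 1]  # boundary sample (0-based)
      idx <- (b - half + 1):(b + half)
      idx <- idx[idx >= 1 & idx <= n]
      r <- ramp[seq_along(idx)]
      w[idx, i] <- 1 - r
      w[idx, i + 1] <- r
      if (i + 2 <= nrow(schedule)) w[idx, seq.int(i + 2, nrow(schedule))] <- 0
    }
  }
  w
}

#' Generate a synthetic data log
#'
#' Produces 128 Hz EEG as a sum of band-limited noises whose band gains and
#' total amplitude follow the state schedule (raised-cosine crossfades of
#' `fade_s` seconds at segment boundaries), injects spike/low-amplitude/EMG
#' artifacts per the noise spec, and builds the per-second annotation stream:
#' a smoothed reference trace tracking the per-state targets plus seeded
#' jitter (sd 3), SQI 95 except scheduled dropout spans (SQI 10 and the
#' -3276.8 sentinel), and an EMG index elevated during bursts. Deterministic
#' for a given seed.
#'
#' @param schedule A [state_schedule()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param subject_id Label for the recording.
#' @param fade_s Crossfade length in seconds.
#' @return An `ndoa_datalog` with attribute `"truth"`: a tibble with the
#'   per-second `state` and noise-free reference `ref_clean`.
#' @export
generate_record <- function(schedule, noise = noise_spec(), seed = 1,
                            subject_id = sprintf("SYN%03d", seed %% 1000),
                            fade_s = 5) {
  stopifnot(inherits(schedule, "ndoa_schedule"), inherits(noise, "ndoa_noise_spec"))
  fs <- NDOA_FS
  dur <- sum(schedule$duration_s)
  n <- dur * fs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  base <- lapply(.ndoa_bands, function(b) .band_noise(n, fs, b, stats::rnorm(n)))
  w <- .state_weights(schedule, fs, fade_s)
  x <- numeric(n)
  for (b in names(.ndoa_bands)) {
    # per-sample gain: sqrt of the weighted band power times state rms^2
    g2 <- numeric(n)
    for (i in seq_len(nrow(schedule))) {
      st <- .ndoa_states[[schedule$state[i]]]
      g2 <- g2 + w[, i] * st$rms^2 * st$bands[[b]]
    }
    x <- x + sqrt(g2) * base[[b]]
  }

  # local rms per second, for artifact scaling
  sec_rms <- sqrt(colMeans(matrix(x^2, nrow = fs)))

  # low-amplitude episodes: 2 s spans where the signal collapses
  n_low <- stats::rpois(1, noise$low_amp_rate_per_min * dur / 60)
  if (n_low > 0) {
    starts <- sort(sample.int(max(dur - 2L, 1L), min(n_low, max(dur - 2L, 1L))))
    for (s0 in starts) {
      idx <- (s0 * fs + 1):((s0 + 2) * fs)
      x[idx] <- x[idx] * noise$low_amp_frac
    }
  }

  # isolated spikes
  n_spk <- stats::rpois(1, noise$spike_rate_per_min * dur / 60)
  spike_at <- integer(0)
  if (n_spk > 0) {
    spike_at <- sample.int(n, n_spk)
    sec_of <- (spike_at - 1L) %/% fs + 1L
    x[spike_at] <- x[spike_at] +
      sample(c(-1, 1), n_spk, replace = TRUE) * noise$spike_mult * sec_rms[sec_of]
  }

  # EMG bursts: 30-60 Hz contamination with raised-cosine onsets
  emg_level <- rep(0, dur)
  if (!is.null(noise$emg_bursts) && nrow(noise$emg_bursts) > 0) {
    emg_noise <- .band_noise(n, fs, c(30, 60), stats::rnorm(n))
    gain <- numeric(n)
    for (i in seq_len(nrow(noise$emg_bursts))) {
      s0 <- noise$emg_bursts$start_s[i]
      d <- noise$emg_bursts$duration_s[i]
      idx <- (s0 * fs + 1):min((s0 + d) * fs, n)
      ramp <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
      loc <- sec_rms[pmin((idx - 1L) %/% fs + 1L, dur)]
      gain[idx] <- pmax(gain[idx], noise$emg_mult * loc * ramp)
      secs <- s0:min(s0 + d - 1L, dur - 1L)
      emg_level[secs + 1L] <- pmax(emg_level[secs + 1L], 30)
    }
    x <- x + gain * emg_noise
  }

  # reference trace: crossfaded target + jitter (sd 3), clamped to [0, 100]
  target_s <- colMeans(matrix(
    as.vector(w %*% schedule$target), nrow = fs))
  ref <- clamp01_100(target_s + stats::rnorm(dur, sd = 3))

  sqi <- rep(95, dur)
  bis <- ref
  if (!is.null(noise$sqi_dropouts) && nrow(noise$sqi_dropouts) > 0) {
    for (i in seq_len(nrow(noise$sqi_dropouts))) {
      s0 <- noise$sqi_dropouts$start_s[i]
      d <- noise$sqi_dropouts$duration_s[i]
      secs <- (s0:min(s0 + d - 1L, dur - 1L)) + 1L
      sqi[secs] <- 10
      bis[secs] <- BIS_SENTINEL
    }
  }

  ann <- tibble::tibble(
    t_s = seq_len(dur) - 1L, bis = bis, sqi = sqi,
    emg = 25 + emg_level + abs(stats::rnorm(dur, sd = 1))
  )
  log <- new_datalog(x, ann, fs = fs, subject_id = subject_id)
  state_of_sec <- rep(schedule$state, schedule$duration_s)
  attr(log, "truth") <- tibble::tibble(
    t_s = seq_len(dur) - 1L, state = state_of_sec, ref_clean = target_s
  )
  attr(log, "spike_samples") <- spike_at
  log
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a benchmark set of synthetic records
#'
#' Builds `n_records` records with varied (seeded) schedules and a
#' train/test assignment in 60:73 / 13:73 proportions (proportional
#' rounding, at least one test record). Every record contains an awake and a
#' deep span so state discrimination can be scored per record.
#'
#' @param n_records Number of records (>= 2).
#' @param seed Integer seed; record `i` is generated with seed
#'   `seed * 1000 + i`.
#' @param noise A [noise_spec()] applied to every record.
#' @return A list with `logs` (list of `ndoa_datalog`) and `manifest` (tibble
#'   with `subject_id`, `seed`, `role` in train/test, `duration_s`).
#' @export
make_benchmark <- function(n_records = 10, seed = 7, noise = noise_spec()) {
  stopifnot(n_records >= 2)
  n_train <- max(1L, min(n_records - 1L, round(n_records * 60 / 73)))
  logs <- vector("list", n_records)
  rows <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    rec_seed <- seed * 1000 + i
    old <- .Random.seed_save()
    set.seed(rec_seed %% .Machine$integer.max)
    d_awake <- sample(30:45, 1)
    d_light <- sample(20:35, 1)
    d_mod <- sample(20:35, 1)
    d_deep <- sample(50:70, 1)
    recover <- stats::runif(1) < 0.5
    .Random.seed_restore(old)
    states <- c("awake", "light", "moderate", "deep")
    durs <- c(d_awake, d_light, d_mod, d_deep)
    if (recover) {
      states <- c(states, "light")
      durs <- c(durs, 20L)
    }
    sched <- state_schedule(states, durs)
    logs[[i]] <- generate_record(sched, noise, seed = rec_seed,
                                 subject_id = sprintf("SYN%03d", i))
    rows[[i]] <- tibble::tibble(
      subject_id = sprintf("SYN%03d", i), seed = rec_seed,
      role = if (i <= n_train) "train" else "test",
      duration_s = sum(durs)
    )
  }
  list(logs = logs, manifest = dplyr::bind_rows(rows))
}
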