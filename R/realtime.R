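# Per-second streaming execution: denoise -> features -> predict on the
# trailing window, then temporal smoothing of the raw prediction.

#' Smooth the current raw index against recent history
#'
#' `tuned = 0.8 * mean(recent_raw) + 0.2 * current_raw`, clamped to
#' `[0, 100]`. With an empty history the current value passes through (the
#' result carries attribute `"no_history" = TRUE` in that case).
#'
#' @param recent_raw Raw index values of up to the last four seconds (most
#'   recent last); `NA` entries are dropped.
#' @param current_raw Current raw index value.
#' @param w_history Weight of the history mean (default 0.8; the current
#'   value gets `1 - w_history`).
#' @return The tuned index value.
#' @export
tune_index <- function(recent_raw, current_raw, w_history = 0.8) {
  recent_raw <- recent_raw[!is.na(recent_raw)]
  if (length(recent_raw) == 0) {
    out <- clamp01_100(current_raw)
    attr(out, "no_history") <- TRUE
    return(out)
  }
  clamp01_100(w_history * mean(recent_raw) + (1 - w_history) * current_raw)
}

#' Initialize a streaming state
#'
#' @param model A fitted `ndoa_model`; its frozen denoising/feature
#'   configuration is used for every window.
#' @param history `"raw"` (default): the smoothing history holds the last
#'   four raw predictions; `"tuned"`: it holds the last four tuned values
#'   (recursive smoothing).
#' @return An object of class `ndoa_stream` (an environment).
#' @export
stream_init <- function(model, history = c("raw", "tuned")) {
  stopifnot(inherits(model, "ndoa_model"))
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$history <- match.arg(history)
  st$buffer <- numeric(0)
  st$recent <- numeric(0)
  st$t <- -1L
  class(st) <- "ndoa_stream"
  st
}

#' Advance the stream by one second
#'
#' Appends 128 samples to the buffer (trimmed to the trailing 10 s) and
#' emits one trace row. The first four seconds are invalid (start-up delay);
#' from the fifth second on, the trailing buffer (5 s growing to 10 s) is
#' denoised, featurized and scored. Degenerate windows yield an invalid row
#' rather than an error.
#'
#' @param state An `ndoa_stream` from [stream_init()] (mutated in place).
#' @param samples Exactly `fs` = 128 new samples.
#' @return One-row tibble `t_s`, `raw`, `tuned`, `valid`.
#' @export
stream_step <- function(state, samples) {
  stopifnot(inherits(state, "ndoa_stream"))
  if (length(samples) != NDOA_FS) {
    stop("stream_step needs exactly ", NDOA_FS, " samples, got ", length(samples),
         call. = FALSE)
  }
  state$t <- state$t + 1L
  state$buffer <- tail(c(state$buffer, samples), NDOA_WINDOW_S * NDOA_FS)
  t <- state$t
  raw <- NA_real_
  tuned <- NA_real_
  valid <- FALSE
  if (t >= NDOA_DELAY_S) {
    win <- tryCatch(denoise_window(state$buffer, state$model$denoise),
                    error = function(e) NULL)
    if (!is.null(win)) {
      fv <- extract_features(win, state$model$features)
      if (!fv$degenerate) {
        raw <- predict(state$model, fv)
        if (!is.na(raw)) {
          tuned <- as.numeric(tune_index(state$recent, raw))
          valid <- TRUE
          state$recent <- tail(c(state$recent,
                                 if (state$history == "raw") raw else tuned), 4L)
        }
      }
    }
  }
  tibble::tibble(t_s = t, raw = raw, tuned = tuned, valid = valid)
}

#' Score a whole data log
#'
#' Runs the record through the identical per-second path as [stream_step()]
#' (so batch and incremental execution produce the same trace) and returns
#' the full index trace. The index is emitted for every second with usable
#' EEG, including spans where the reference carries the invalid sentinel or
#' SQI is low - the reference stream never gates the index.
#'
#' @param log An `ndoa_datalog`.
#' @param model A fitted `ndoa_model`.
#' @param history See [stream_init()].
#' @return A tibble of class `ndoa_trace`: `t_s`, `raw`, `tuned`, `valid`,
#'   plus the record's `subject_id` as an attribute.
#' @export
run_record <- function(log, model, history = "raw") {
  stopifnot(inherits(log, "ndoa_datalog"))
  st <- stream_init(model, history = history)
  n_sec <- length(log$samples) %/% log$fs
  rows <- vector("list", n_sec)
  for (t in seq_len(n_sec)) {
    idx <- ((t - 1L) * log$fs + 1L):(t * log$fs)
    rows[[t]] <- stream_step(st, log$samples[idx])
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "subject_id") <- log$subject_id
  class(out) <- c("ndoa_trace", class(out))
  out
}

#' Index trace from a precomputed feature table
#'
#' Batch counterpart of [run_record()]: applies the model and the smoothing
#' recurrence to a per-second feature table (from [extract_feature_table()]
#' with the model's frozen configuration). Produces the identical trace to
#' the sample-by-sample stream, without re-extracting features.
#'
#' @param features Feature table with `t_s`, the five features, `degenerate`.
#' @param model A fitted `ndoa_model`.
#' @param history See [stream_init()].
#' @param subject_id Label attached to the trace.
#' @return An `ndoa_trace` tibble.
#' @export
trace_from_features <- function(features, model, history = c("raw", "tuned"),
                                subject_id = "S1") {
  history <- match.arg(history)
  raw_all <- predict(model, features)
  raw_all[features$degenerate] <- NA_real_
  raw_all[features$t_s < NDOA_DELAY_S] <- NA_real_
  recent <- numeric(0)
  n <- nrow(features)
  tuned <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    raw <- raw_all[i]
    if (!is.na(raw)) {
      tuned[i] <- as.numeric(tune_index(recent, raw))
      valid[i] <- TRUE
      recent <- tail(c(recent, if (history == "raw") raw else tuned[i]), 4L)
    }
  }
  out <- tibble::tibble(t_s = features$t_s, raw = raw_all, tuned = tuned,
                        valid = valid)
  attr(out, "subject_id") <- subject_id
  class(out) <- c("ndoa_trace", class(out))
  out
}

#' Plot an index trace
#'
#' Raw and tuned index against time, optionally overlaid with the reference
#' stream of the originating record (invalid-reference seconds are dropped
#' from the overlay).
#'
#' @param object An `ndoa_trace`.
#' @param log Optional `ndoa_datalog` supplying the reference overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ndoa_trace <- function(object, log = NULL, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t_s", "raw", "tuned"),
    c("raw", "tuned"), names_to = "series", values_to = "index"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$index,
                                        colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "index (0-100)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100))
  if (!is.null(log)) {
    ref <- log$annotations[valid_bis_mask(log$annotations), c("t_s", "bis")]
    p <- p + ggplot2::geom_line(
      data = ref, ggplot2::aes(x = .data$t_s, y = .data$bis),
      inherit.aes = FALSE, linetype = "dashed", colour = "grey40", na.rm = TRUE
    )
  }
  p
}
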