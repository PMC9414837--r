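# Window-level pre-processing: outlier clipping and wavelet-shrinkage
# denoising with either the universal (Donoho) threshold or the adaptive
# permutation-entropy threshold.

#' Clip amplitude outliers in an EEG window
#'
#' Samples further than `k` standard deviations from the window mean are
#' clipped to `mean +/- k*sd` (clipping, not deletion, preserves the 128 Hz
#' alignment with the per-second annotation stream). A constant window is
#' returned unchanged.
#'
#' @param x Numeric vector of amplitudes (microvolts).
#' @param k Positive multiplier of the window standard deviation. Default 5.
#' @return Numeric vector, same length as `x`.
#' @export
remove_outliers <- function(x, k = 5) {
  if (length(x) == 0) stop("empty window", call. = FALSE)
  stopifnot(k > 0)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, m - k * s), m + k * s)
}

#' Universal wavelet-shrinkage threshold
#'
#' Donoho's threshold `Th = sigma * sqrt(2 log N)` with the noise scale
#' estimated from the median absolute detail coefficient,
#' `sigma = median(|d|) / 0.6745`.
#'
#' @param detail Numeric vector of detail coefficients (one level).
#' @return A list with `sigma`, `th` and `n` (the coefficient count).
#' @export
universal_threshold <- function(detail) {
  if (length(detail) == 0) stop("empty detail coefficient vector", call. = FALSE)
  sigma <- stats::median(abs(detail)) / 0.6745
  n <- length(detail)
  list(sigma = sigma, th = sigma * sqrt(2 * log(n)), n = n)
}

#' Permutation-entropy energy of a window
#'
#' Splits the window into `k_segments` equal pieces, computes the ordinal
#' (permutation) entropy of each in nats, and returns the total entropy
#' energy `pe_total` (sum over segments) together with the relative energy
#' `rpe` = entropy of the whole window divided by `pe_total`. `rpe` drives
#' the adaptive denoising threshold: regular, low-entropy windows yield small
#' `rpe` terms and the threshold collapses towards its empirical plateau.
#'
#' @param x Numeric vector (one window).
#' @param m Embedding dimension for the ordinal patterns (default 3).
#' @param k_segments Number of equal segments (default 10; one per second of
#'   the 10 s window).
#' @return A list with `pe_total` (nats), `rpe` (dimensionless), `h_whole`
#'   (entropy of the whole window) and `degenerate` (TRUE when every segment
#'   shows a single ordinal pattern so `rpe` is undefined).
#' @export
permutation_entropy_energy <- function(x, m = 3L, k_segments = 10L) {
  stopifnot(m >= 2, k_segments >= 1)
  n <- length(x)
  seg_len <- n %/% k_segments
  if (seg_len < m) {
    stop("segments of length ", seg_len, " are shorter than the embedding ",
         "dimension ", m, call. = FALSE)
  }
  h_seg <- vapply(seq_len(k_segments), function(k) {
    seg <- x[((k - 1L) * seg_len + 1L):(k * seg_len)]
    .ordinal_entropy(seg, m, tau = 1L)
  }, numeric(1))
  pe_total <- sum(h_seg)
  h_whole <- .ordinal_entropy(x, m, tau = 1L)
  degenerate <- pe_total <= 0
  list(
    pe_total = pe_total,
    rpe = if (degenerate) NA_real_ else h_whole / pe_total,
    h_whole = h_whole,
    degenerate = degenerate
  )
}

# Shannon entropy (nats) of the ordinal-pattern distribution of x; ties broken
# by order of occurrence (stable sort).
.ordinal_entropy <- function(x, m, tau = 1L) {
  codes <- .ordinal_codes(x, m, tau)
  p <- tabulate(codes + 1L)
  p <- p[p > 0] / length(codes)
  -sum(p * log(p))
}

# Lehmer-code each embedded m-tuple; stable tie-break: a later equal value
# counts as larger, matching a stable argsort.
.ordinal_codes <- function(x, m, tau = 1L) {
  n_pat <- length(x) - (m - 1L) * tau
  if (n_pat < 1) stop("series too short for embedding", call. = FALSE)
  cols <- lapply(seq_len(m), function(i) x[seq.int(1L + (i - 1L) * tau, by = 1L, length.out = n_pat)])
  codes <- integer(n_pat)
  radix <- 1L
  # digit_i = #{j > i : x_j < x_i} (strict; ties keep occurrence order)
  for (i in seq_len(m - 1L)) {
    d <- integer(n_pat)
    for (j in seq.int(i + 1L, m)) d <- d + (cols[[j]] < cols[[i]])
    codes <- codes * (m - i + 1L) + d
  }
  codes
}

#' Adaptive permutation-entropy denoising threshold
#'
#' Maps the relative permutation-entropy energy of a window to a shrinkage
#' threshold: `th = |log(rpe) / log(n * log(n))^2 - a| * b` (natural logs),
#' where `n` is the window length in samples and `a`, `b` are empirical
#' constants (defaults 9 and 6). The absolute value keeps the threshold
#' non-negative; since `log(rpe) <= 0` the entropy term raises the threshold
#' above the `a*b` plateau for irregular windows.
#'
#' @param rpe Relative permutation-entropy energy in (0, 1].
#' @param n Window length in samples (>= 3).
#' @param a,b Empirical offset and gain constants.
#' @return Non-negative threshold (same scale as the wavelet coefficients).
#' @export
adaptive_threshold <- function(rpe, n, a = 9, b = 6) {
  if (!is.finite(rpe) || rpe <= 0) stop("rpe must be positive", call. = FALSE)
  stopifnot(n >= 3)
  abs(log(rpe) / log(n * log(n))^2 - a) * b
}

#' Denoising configuration
#'
#' Collects the tunable parameters of [denoise_window()] so the exact
#' configuration used at training time can be frozen into a fitted model.
#'
#' @param wavelet Mother wavelet (default `"db16"`).
#' @param levels Decomposition levels (default 6).
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @param threshold `"adaptive"` (default) or `"universal"`.
#' @param a,b Constants of the adaptive threshold.
#' @param k_segments Segment count of the entropy-energy computation.
#' @param outlier_k Outlier-clipping multiplier applied before the transform.
#' @return A list of class `ndoa_denoise_config`.
#' @export
denoise_config <- function(wavelet = "db16", levels = 6L, mode = c("soft", "hard"),
                           threshold = c("adaptive", "universal"),
                           a = 9, b = 6, k_segments = 10L, outlier_k = 5) {
  structure(
    list(wavelet = wavelet, levels = as.integer(levels),
         mode = match.arg(mode), threshold = match.arg(threshold),
         a = a, b = b, k_segments = as.integer(k_segments),
         outlier_k = outlier_k),
    class = "ndoa_denoise_config"
  )
}

#' Denoise one EEG window by wavelet shrinkage
#'
#' Decomposes the window, thresholds every detail level, and reconstructs.
#' With `threshold = "universal"` each level gets its own Donoho threshold
#' estimated from that level's coefficients; with `"adaptive"` (the default)
#' a single threshold from [adaptive_threshold()] is computed on the
#' time-domain window and applied to all detail levels. If the window's
#' ordinal structure is fully degenerate (single pattern in every segment),
#' the adaptive threshold falls back to its `rpe = 1` plateau `a * b`.
#'
#' @param x Numeric vector (one window; length divisible by `2^levels`).
#' @param config A [denoise_config()].
#' @param clip_outliers Clip amplitude outliers first (default TRUE).
#' @return Numeric vector, same length as `x` (the denoised window), with
#'   attribute `"th"` giving the threshold(s) applied.
#' @export
denoise_window <- function(x, config = denoise_config(), clip_outliers = TRUE) {
  stopifnot(inherits(config, "ndoa_denoise_config"))
  if (clip_outliers) x <- remove_outliers(x, k = config$outlier_k)
  w <- eeg_dwt(x, wavelet = config$wavelet, levels = config$levels)
  shrink <- if (config$mode == "soft") soft_threshold else hard_threshold
  if (config$threshold == "adaptive") {
    pe <- permutation_entropy_energy(x, m = 3L, k_segments = config$k_segments)
    rpe <- if (pe$degenerate) 1 else pe$rpe
    th <- adaptive_threshold(rpe, n = length(x), a = config$a, b = config$b)
    w$details <- lapply(w$details, shrink, th = th)
    ths <- rep(th, config$levels)
  } else {
    ths <- vapply(w$details, function(d) universal_threshold(d)$th, numeric(1))
    w$details <- Map(shrink, w$details, ths)
  }
  out <- eeg_idwt(w)
  attr(out, "th") <- ths
  out
}
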