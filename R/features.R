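# The five per-window features feeding the regression model: sample entropy,
# fuzzy entropy, normalized permutation entropy, Hurst range response, and the
# eigenvector-pseudospectrum summary of the wavelet sub-bands.

#' Sample entropy
#'
#' `SE = -ln(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev distance `r` and `A` the pairs still matching at length `m + 1`;
#' self-matches are excluded and the tolerance is `r_factor * sd(x)`, so the statistic is
#' invariant under positive affine maps of the signal.
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Sample entropy in nats. `Inf` (with a warning) when no template
#'   pair matches at length `m + 1`.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.2) {
  stopifnot(length(x) >= m + 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant signal: sample entropy undefined", call. = FALSE)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), r_factor * s)
  if (cnt[["B"]] == 0) stop("no length-m template matches: sample entropy undefined", call. = FALSE)
  if (cnt[["A"]] == 0) {
    warning("no length-(m+1) template matches: sample entropy infinite")
    return(Inf)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

#' Fuzzy entropy
#'
#' `FE = ln(phi_m) - ln(phi_{m+1})` where `phi_m` is the mean fuzzy membership
#' `exp(-(d/r)^n_fuzzy)` over all pairs of de-meaned length-`m` templates
#' (Chebyshev distance `d`, self-pairs excluded). The tolerance is
#' `r_factor * sd(x)`, making FE invariant under positive affine maps.
#'
#' @param x Numeric vector, length >= m + 2.
#' @param m Embedding dimension (default 2).
#' @param n_fuzzy Membership exponent (default 2).
#' @param r_factor Tolerance multiplier (default 0.15).
#' @return Fuzzy entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2L, n_fuzzy = 2, r_factor = 0.15) {
  stopifnot(length(x) >= m + 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant signal: fuzzy entropy undefined", call. = FALSE)
  r <- r_factor * s
  p_m <- fuzzy_phi(as.numeric(x), as.integer(m), n_fuzzy, r)
  p_m1 <- fuzzy_phi(as.numeric(x), as.integer(m) + 1L, n_fuzzy, r)
  if (!is.finite(p_m) || !is.finite(p_m1) || p_m <= 0 || p_m1 <= 0) {
    stop("degenerate fuzzy membership", call. = FALSE)
  }
  log(p_m) - log(p_m1)
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution divided by `log(m!)`,
#' so the value lies in `[0, 1]`: 0 for a single recurring pattern (monotone
#' signal), 1 when all `m!` patterns are equally frequent. Ties are broken by
#' order of occurrence.
#'
#' @param x Numeric vector, length >= (m - 1) * tau + 1.
#' @param m Embedding dimension (default 4).
#' @param tau Time delay in samples (default 1).
#' @return Normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, m = 4L, tau = 1L) {
  m <- as.integer(m)
  stopifnot(m >= 2, tau >= 1)
  if (length(x) < (m - 1L) * tau + 1L) stop("series too short for embedding", call. = FALSE)
  .ordinal_entropy(x, m, tau) / log(factorial(m))
}

#' Hurst range response
#'
#' Rescaled-range style statistic: for each dyadic scale `m` in
#' `{N, N/2, N/4, ...}` (down to `min_scale`), the signal is cut into
#' non-overlapping segments of length `m`; per segment the cumulative sum of
#' mean-adjusted values is formed and its range `R` (max minus min) and the
#' segment standard deviation `S` (population, divisor `m`) are computed. The
#' feature is the minimum over scales of the mean segment range,
#' `Rr = min_m mean(R)`. Scales where every segment is constant are skipped.
#'
#' @param x Numeric vector, length >= 8.
#' @param min_scale Smallest segment length considered (default 8).
#' @return A list with `rr` (the feature, microvolt scale), and a tibble
#'   `scales` with per-scale `m`, `mean_r` and `mean_rs` (the classic mean
#'   rescaled range `R/S`, exposed for diagnostics).
#' @export
hurst_range_response <- function(x, min_scale = 8L) {
  n <- length(x)
  stopifnot(n >= min_scale)
  scales <- n %/% 2^(0:floor(log2(n / min_scale)))
  scales <- scales[scales >= min_scale]
  rows <- lapply(scales, function(m) {
    k <- n %/% m
    seg <- matrix(x[seq_len(k * m)], nrow = m)
    mu <- colMeans(seg)
    xm <- sweep(seg, 2, mu)
    z <- apply(xm, 2, cumsum)
    if (k == 1) z <- matrix(z, ncol = 1)
    r <- apply(z, 2, function(col) max(col) - min(col))
    s <- sqrt(colMeans(xm^2))
    ok <- s > 0
    if (!any(ok)) return(NULL)
    tibble::tibble(m = m, mean_r = mean(r[ok]), mean_rs = mean(r[ok] / s[ok]))
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) stop("constant signal: range response undefined", call. = FALSE)
  list(rr = min(rows$mean_r), scales = rows)
}

#' Parameters of the eigenvector-pseudospectrum feature
#'
#' @param k1,k2,k3 Combination constants (defaults 28, 90, 3).
#' @param levels Wavelet decomposition levels (default 6).
#' @param wavelet Mother wavelet (default `"db16"`).
#' @param order Autocorrelation-matrix order of the eigenvector estimator
#'   (default 12).
#' @param eig_order Number of principal (signal) eigenvectors (default 6);
#'   the remaining `order - eig_order` eigenvectors span the noise subspace.
#' @param n_grid Pseudospectrum grid size over `[0, fs/2]` Hz (default 128).
#' @param fs Nominal sampling rate (Hz).
#' @return A list of class `ndoa_psd_params`.
#' @export
psd_feature_params <- function(k1 = 28, k2 = 90, k3 = 3, levels = 6L,
                               wavelet = "db16", order = 12L, eig_order = 6L,
                               n_grid = 128L, fs = 128) {
  stopifnot(k3 != 0, levels >= 1, order > eig_order)
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, levels = as.integer(levels),
         wavelet = wavelet, order = as.integer(order),
         eig_order = as.integer(eig_order), n_grid = as.integer(n_grid), fs = fs),
    class = "ndoa_psd_params"
  )
}

# Eigenvector (EV) pseudospectrum of a real sequence on a fixed frequency
# grid: P(f) = 1 / sum_i |e(f)^H v_i|^2 / lambda_i over the noise-subspace
# eigenvectors of the order-p autocorrelation matrix. For sequences shorter
# than order + 1 (coarse wavelet levels of partial start-up windows) the
# order shrinks to n - 1, keeping at least one noise eigenvector.
ev_pseudospectrum <- function(x, order = 12L, eig_order = 6L, n_grid = 128L, fs = 128) {
  n <- length(x)
  if (n <= order) {
    order <- n - 1L
    eig_order <- min(eig_order, order - 1L)
  }
  if (order < 2L) stop("sequence too short for the eigenvector estimator", call. = FALSE)
  xc <- x - mean(x)
  # biased autocorrelation estimates, lags 0..order-1
  acov <- vapply(0:(order - 1L), function(l) {
    sum(xc[seq_len(n - l)] * xc[seq_len(n - l) + l]) / n
  }, numeric(1))
  R <- stats::toeplitz(acov)
  e <- eigen(R, symmetric = TRUE)
  idx <- seq.int(eig_order + 1L, order)  # noise subspace
  lam <- pmax(e$values[idx], .Machine$double.eps)
  V <- e$vectors[, idx, drop = FALSE]
  f <- seq(0, fs / 2, length.out = n_grid)
  E <- exp(-2i * pi * outer(0:(order - 1L), f / fs))  # order x n_grid steering
  num <- Mod(crossprod(V, E))^2 / lam                  # |v_i^H e(f)|^2 / lambda_i
  1 / colSums(num)
}

#' Eigenvector wavelet-pseudospectrum feature
#'
#' Decomposes the window to `levels` levels, computes the eigenvector (EV)
#' pseudospectrum of the approximation `A_j` and detail `D_j` coefficients at
#' every level, then summarizes: per sequence the grid mean and grid standard
#' deviation of the pseudospectrum; `M = 0.5 * (log(mean over levels of the
#' detail means) + log(mean over levels of the approximation means))`, `S`
#' the analogue with standard deviations; the feature is
#' `(k1 * M + k2 * S) / k3`.
#'
#' @param x Numeric vector (one window).
#' @param params A [psd_feature_params()].
#' @return The scalar feature (dimensionless).
#' @export
psd_eigenvector_feature <- function(x, params = psd_feature_params()) {
  stopifnot(inherits(params, "ndoa_psd_params"))
  w <- eeg_dwt(x, wavelet = params$wavelet, levels = params$levels)
  approx <- eeg_dwt_all_approx(x, wavelet = params$wavelet, levels = params$levels)
  ps <- function(seq) ev_pseudospectrum(seq, params$order, params$eig_order,
                                        params$n_grid, params$fs)
  d_spec <- lapply(w$details, ps)
  a_spec <- lapply(approx, ps)
  md <- mean(vapply(d_spec, mean, numeric(1)))
  ma <- mean(vapply(a_spec, mean, numeric(1)))
  sd_d <- mean(vapply(d_spec, stats::sd, numeric(1)))
  sd_a <- mean(vapply(a_spec, stats::sd, numeric(1)))
  if (md <= 0 || ma <= 0 || sd_d <= 0 || sd_a <= 0) {
    stop("non-positive pseudospectrum summary: feature undefined", call. = FALSE)
  }
  M <- 0.5 * (log(md) + log(ma))
  S <- 0.5 * (log(sd_d) + log(sd_a))
  (params$k1 * M + params$k2 * S) / params$k3
}

#' Feature-extraction configuration
#'
#' @param se_m,se_r Sample-entropy dimension and tolerance multiplier.
#' @param fe_m,fe_n,fe_r Fuzzy-entropy dimension, exponent, tolerance multiplier.
#' @param pe_m,pe_tau Permutation-entropy dimension and delay.
#' @param hurst_min_scale Smallest Hurst segment length.
#' @param psd A [psd_feature_params()].
#' @return A list of class `ndoa_feature_config`.
#' @export
feature_config <- function(se_m = 2L, se_r = 0.2, fe_m = 2L, fe_n = 2, fe_r = 0.15,
                           pe_m = 4L, pe_tau = 1L, hurst_min_scale = 8L,
                           psd = psd_feature_params()) {
  structure(
    list(se_m = se_m, se_r = se_r, fe_m = fe_m, fe_n = fe_n, fe_r = fe_r,
         pe_m = pe_m, pe_tau = pe_tau, hurst_min_scale = hurst_min_scale,
         psd = psd),
    class = "ndoa_feature_config"
  )
}

#' Extract the five features from one (denoised) window
#'
#' Computes sample entropy, fuzzy entropy, normalized permutation entropy,
#' Hurst range response and the eigenvector-pseudospectrum feature with the
#' default parameterization. Degenerate windows (e.g. constant signal) do not
#' raise: the affected features are `NA` and the row is flagged.
#'
#' @param x Numeric vector (one denoised window).
#' @param config A [feature_config()].
#' @return A one-row tibble with columns `se`, `fe`, `pe`, `hurst_rr`,
#'   `psd_fea`, `degenerate`.
#' @export
extract_features <- function(x, config = feature_config()) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_,
                                  warning = function(w) NA_real_)
  se <- safe(sample_entropy(x, config$se_m, config$se_r))
  fe <- safe(fuzzy_entropy(x, config$fe_m, config$fe_n, config$fe_r))
  pe <- safe(permutation_entropy(x, config$pe_m, config$pe_tau))
  rr <- safe(hurst_range_response(x, config$hurst_min_scale)$rr)
  fea <- safe(psd_eigenvector_feature(x, config$psd))
  vals <- c(se, fe, pe, rr, fea)
  tibble::tibble(
    se = se, fe = fe, pe = pe, hurst_rr = rr, psd_fea = fea,
    degenerate = anyNA(vals) || !all(is.finite(vals))
  )
}

#' Per-second feature table of a data log
#'
#' Runs the sliding-window pipeline over a [read_datalog()] object: for every
#' second `t >= 4` (0-based; the monitor's four-second start-up delay) the
#' trailing window of up to 10 s is denoised and the five features are
#' extracted. Seconds 0-3 are emitted with `NA` features and
#' `degenerate = TRUE`.
#'
#' @param log An `ndoa_datalog`.
#' @param denoise A [denoise_config()] (set to `NULL` to skip denoising).
#' @param features A [feature_config()].
#' @return A tibble with one row per second: `t_s`, the five features, and
#'   `degenerate`.
#' @export
extract_feature_table <- function(log, denoise = denoise_config(),
                                  features = feature_config()) {
  stopifnot(inherits(log, "ndoa_datalog"))
  fs <- log$fs
  n_sec <- length(log$samples) %/% fs
  rows <- lapply(seq_len(n_sec) - 1L, function(t) {
    if (t < NDOA_DELAY_S) {  # seconds 0..3: start-up delay
      return(tibble::tibble(t_s = t, se = NA_real_, fe = NA_real_, pe = NA_real_,
                            hurst_rr = NA_real_, psd_fea = NA_real_,
                            degenerate = TRUE))
    }
    hi <- (t + 1L) * fs
    lo <- max(0L, hi - NDOA_WINDOW_S * fs) + 1L
    win <- log$samples[lo:hi]
    if (!is.null(denoise)) win <- denoise_window(win, denoise)
    dplyr::bind_cols(tibble::tibble(t_s = t), extract_features(win, features))
  })
  dplyr::bind_rows(rows)
}
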