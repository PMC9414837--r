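# Periodized orthogonal discrete wavelet transform.
#
# Filters are the standard Daubechies orthonormal scaling filters (sum = sqrt(2),
# unit energy). Analysis correlates the signal with even circular shifts of the
# scaling/wavelet filters; synthesis is the adjoint, so perfect reconstruction
# follows from orthonormality of the filter bank.

.db_filters <- list(
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705, 0.0006754494064505693,
          -0.00011747678412476953),
  db16 = c(0.003189220925347738, 0.034907714323673344, 0.16506428348885313,
           0.4303127228460038, 0.637356332083789, 0.4402902568863569,
           -0.08975108940248964, -0.3270633105279177, -0.027918208133028276,
           0.2111906939471043, 0.027340263752716042, -0.1323883055638104,
           -0.006239722752474872, 0.07592423604427631, -0.007588974368857738,
           -0.03688839769173014, 0.01029765964095597, 0.013993768859828731,
           -0.006990014563413916, -0.00364427962149839, 0.003128023381206269,
           0.00040789698084971285, -0.0009410217493595676, 0.00011424152003872239,
           0.00017478724522533817, -6.103596621410936e-05, -1.3945668988208893e-05,
           1.1336608661276258e-05, -1.0435713423116066e-06, -7.363656785451205e-07,
           2.3087840868575457e-07, -2.109339630100743e-08)
)

wavelet_filters <- function(wavelet = "db16") {
  lo <- .db_filters[[wavelet]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "), call. = FALSE)
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(lo = lo, hi = hi, length = L)
}

# One analysis step: x (even length n) -> list(a, d) of length n/2.
.dwt_step <- function(x, f) {
  n <- length(x)
  half <- n %/% 2L
  idx <- (outer(2L * (seq_len(half) - 1L), seq_len(f$length) - 1L, `+`) %% n) + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% f$lo), d = drop(xm %*% f$hi))
}

# Adjoint of .dwt_step: coefficients back to length-n signal.
.idwt_step <- function(a, d, f) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  pos <- (outer(2L * (seq_len(half) - 1L), seq_len(f$length) - 1L, `+`) %% n) + 1L
  for (k in seq_len(half)) {
    p <- pos[k, ]
    x[p] <- x[p] + a[k] * f$lo + d[k] * f$hi
  }
  x
}

#' Multilevel wavelet decomposition of an EEG window
#'
#' Decomposes a signal with a periodized orthogonal discrete wavelet transform
#' into one approximation band and `levels` detail bands. With the default
#' Daubechies-16 filter at six levels on 128 Hz data, the detail bands cover
#' (nominally) 32-64, 16-32, 8-16, 4-8, 2-4 and 1-2 Hz and the approximation
#' 0-1 Hz.
#'
#' @param x Numeric vector; length must be divisible by `2^levels`.
#' @param wavelet Filter name: one of `"db4"`, `"db8"`, `"db16"`.
#' @param levels Number of decomposition levels.
#' @return An object of class `ndoa_dwt`: a list with `approx` (coarsest
#'   approximation coefficients), `details` (list `D1`..`D<levels>`, fine to
#'   coarse), `wavelet`, `levels`, `n`.
#' @examples
#' w <- eeg_dwt(sin(2 * pi * 2 * (0:1279) / 128))
#' x <- eeg_idwt(w)
#' @export
eeg_dwt <- function(x, wavelet = "db16", levels = 6L) {
  stopifnot(is.numeric(x), length(x) >= 2)
  if (anyNA(x)) stop("signal contains NA", call. = FALSE)
  levels <- as.integer(levels)
  if (length(x) %% (2^levels) != 0) {
    stop("signal length ", length(x), " is not divisible by 2^", levels,
         "; cannot run a ", levels, "-level periodized transform", call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, f)
    details[[j]] <- s$d
    a <- s$a
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(
    list(approx = a, details = details, wavelet = wavelet,
         levels = levels, n = length(x)),
    class = "ndoa_dwt"
  )
}

#' Inverse wavelet transform
#'
#' Reconstructs the signal from an [eeg_dwt()] decomposition. With unmodified
#' coefficients the reconstruction matches the input to floating-point
#' accuracy (the transform is orthonormal).
#'
#' @param w An `ndoa_dwt` object.
#' @return Numeric vector of length `w$n`.
#' @export
eeg_idwt <- function(w) {
  stopifnot(inherits(w, "ndoa_dwt"))
  f <- wavelet_filters(w$wavelet)
  a <- w$approx
  for (j in rev(seq_len(w$levels))) {
    a <- .idwt_step(a, w$details[[j]], f)
  }
  a
}

# Approximation coefficients at every level (A1..Alevels), used by the
# pseudospectrum feature which needs A_j and D_j per level.
eeg_dwt_all_approx <- function(x, wavelet = "db16", levels = 6L) {
  f <- wavelet_filters(wavelet)
  out <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwt_step(a, f)
    out[[j]] <- s$a
    a <- s$a
  }
  names(out) <- paste0("A", seq_len(levels))
  out
}

#' Soft-threshold wavelet coefficients
#'
#' Shrinks each coefficient towards zero by `th`: coefficients with
#' `|c| <= th` become 0, larger ones keep their sign and lose `th` in
#' magnitude.
#'
#' @param coefs Numeric vector of coefficients.
#' @param th Non-negative threshold.
#' @return Numeric vector, same length.
#' @export
soft_threshold <- function(coefs, th) {
  stopifnot(th >= 0)
  sign(coefs) * pmax(abs(coefs) - th, 0)
}

#' Hard-threshold wavelet coefficients
#'
#' Zeroes coefficients with `|c| <= th`; others pass unchanged.
#'
#' @inheritParams soft_threshold
#' @return Numeric vector, same length.
#' @export
hard_threshold <- function(coefs, th) {
  stopifnot(th >= 0)
  ifelse(abs(coefs) > th, coefs, 0)
}
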