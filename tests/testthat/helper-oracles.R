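# Independent brute-force oracles. These follow the defining formulas with
# plain scalar loops and share no code with the package internals.

# Sample entropy: O(N^2) template-pair counting, Chebyshev distance,
# self-matches excluded, common template range for lengths m and m+1.
oracle_sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  r <- r_factor * sd(x)
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm < r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) < r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# Fuzzy entropy: mean exp(-(d/r)^nf) membership over de-meaned template pairs.
oracle_fuzzy_phi <- function(x, m, nf, r) {
  n <- length(x)
  nt <- n - m + 1
  tpl <- lapply(1:nt, function(i) {
    v <- x[i:(i + m - 1)]
    v - mean(v)
  })
  acc <- 0; cnt <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(tpl[[i]] - tpl[[j]]))
      acc <- acc + exp(-(d / r)^nf)
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

oracle_fuzzy_entropy <- function(x, m = 2, nf = 2, r_factor = 0.15) {
  r <- r_factor * sd(x)
  log(oracle_fuzzy_phi(x, m, nf, r)) - log(oracle_fuzzy_phi(x, m + 1, nf, r))
}

# Normalized permutation entropy by explicit pattern enumeration; ties keep
# occurrence order (stable ranking).
oracle_perm_entropy <- function(x, m = 4, tau = 1, normalize = TRUE) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- character(n_pat)
  for (i in 1:n_pat) {
    v <- x[seq(i, by = tau, length.out = m)]
    pats[i] <- paste(order(v), collapse = "-")  # order() is stable
  }
  p <- table(pats) / n_pat
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

# Hurst range response: literal step-by-step loop over dyadic scales.
oracle_hurst_rr <- function(x, min_scale = 8) {
  n <- length(x)
  scales <- c()
  m <- n
  while (m >= min_scale) { scales <- c(scales, m); m <- m %/% 2 }
  mean_r <- c()
  for (m in scales) {
    k <- n %/% m
    rs <- c()
    for (seg in 1:k) {
      y <- x[((seg - 1) * m + 1):(seg * m)]
      mu <- mean(y)
      xadj <- y - mu
      z <- cumsum(xadj)
      R <- max(z) - min(z)
      S <- sqrt(mean(xadj^2))
      if (S > 0) rs <- c(rs, R)
    }
    if (length(rs)) mean_r <- c(mean_r, mean(rs))
  }
  min(mean_r)
}

# Scalar roll-out of the index smoothing recurrence.
oracle_tuned_rollout <- function(raw, w = 0.8) {
  recent <- c()
  tuned <- numeric(length(raw))
  for (i in seq_along(raw)) {
    if (length(recent) == 0) {
      tuned[i] <- min(100, max(0, raw[i]))
    } else {
      tuned[i] <- min(100, max(0, w * mean(recent) + (1 - w) * raw[i]))
    }
    recent <- tail(c(recent, raw[i]), 4)
  }
  tuned
}

# Eigenvector pseudospectrum written independently (explicit loops).
oracle_ev_pseudospectrum <- function(x, order = 12, eig_order = 6,
                                     n_grid = 128, fs = 128) {
  n <- length(x)
  if (n <= order) {
    order <- n - 1
    eig_order <- min(eig_order, order - 1)
  }
  xc <- x - mean(x)
  ac <- sapply(0:(order - 1), function(l) sum(xc[1:(n - l)] * xc[(1 + l):n]) / n)
  R <- outer(1:order, 1:order, function(i, j) ac[abs(i - j) + 1])
  e <- eigen(R, symmetric = TRUE)
  f <- seq(0, fs / 2, length.out = n_grid)
  sapply(f, function(fi) {
    s <- 0
    for (q in (eig_order + 1):order) {
      v <- e$vectors[, q]
      proj <- sum(v * exp(-2i * pi * fi / fs * (0:(order - 1))))
      s <- s + Mod(proj)^2 / max(e$values[q], .Machine$double.eps)
    }
    1 / s
  })
}

# Mean band power of a signal via the raw periodogram (for the generator's
# spectral contract).
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  f <- (0:(n - 1)) / n * fs
  keep <- f <= fs / 2 & f >= band[1] & f <= band[2]
  sum(sp[keep])
}
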