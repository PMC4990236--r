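# Independent oracles, coded from first principles and kept separate from the
# implementation paths they check.

# Term-by-term DFT: X_k = sum_n x_n exp(-2*pi*i*k*n/N), no FFT involved.
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% as.complex(x))
}

# Tapered-cosine window written as one closed-form expression (distinct from
# the implementation's piecewise assignment).
oracle_tukey <- function(n, alpha) {
  if (n == 1) return(1)
  x <- (0:(n - 1)) / (n - 1)
  if (alpha == 0) return(rep(1, n))
  vapply(x, function(xi) {
    d <- min(xi, 1 - xi)              # distance to nearer edge
    if (d >= alpha / 2) 1 else 0.5 * (1 - cos(2 * pi * d / alpha))
  }, numeric(1))
}

# Full one-sided amplitude spectrum via the brute-force DFT.
oracle_amplitude_spectrum <- function(segment, fs, tukey_alpha = 0.5,
                                      detrend = TRUE) {
  x <- as.numeric(segment)
  if (detrend) x <- x - sum(x) / length(x)
  w <- oracle_tukey(length(x), tukey_alpha)
  X <- brute_dft(x * w)
  n <- length(x)
  nyq <- floor(n / 2)
  amp <- 2 * Mod(X[1:(nyq + 1)]) / sum(w)
  amp[1] <- amp[1] / 2
  if (n %% 2 == 0) amp[nyq + 1] <- amp[nyq + 1] / 2
  list(freqs = (0:nyq) * fs / n, amplitudes = amp)
}

oracle_amsa <- function(freqs, amplitudes, lo = 2, hi = 48) {
  sel <- freqs >= lo & freqs <= hi
  sum(amplitudes[sel] * freqs[sel])
}

# Textbook one-way within-subject sum-of-squares decomposition.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  col_means <- colMeans(m)
  row_means <- rowMeans(m)
  ss_time <- n * sum((col_means - grand)^2)
  ss_within <- sum(sweep(m, 1, row_means)^2)
  ss_err <- ss_within - ss_time
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_time / df1) / (ss_err / df2)
  list(F = F, df_effect = df1, df_error = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}

# Normal-equations least squares for y = a + b x.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  a <- (sy - b * sx) / n
  list(slope = b, intercept = a)
}

# Definitional Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Convenience: short stationary synthetic VF record for spectral tests.
make_vf_record <- function(fs = 250, duration_s = 10, seed = 1, amsa = 10,
                           subject_id = "s1") {
  generate_vf(vf_profile(stats::setNames(amsa, "1")),
              generator_spec(fs = fs, duration_s = duration_s, seed = seed,
                             subject_sigma = 0),
              subject_id = subject_id)
}
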