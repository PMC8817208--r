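# Independent closed-form oracles used to cross-check the package's
# statistics, plus small fixture builders.

# Pearson r and two-sided p from the definitional formulas only.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# Naive Benjamini-Hochberg step-up: sort, scale, enforce monotonicity by
# explicit cumulative minimum from the largest rank down.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# ICC(A,1) from explicit sums of squares (no aov).
oracle_icc_a1 <- function(w1, w2) {
  n <- length(w1)
  k <- 2
  mat <- cbind(w1, w2)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Minimal OpenFace-dialect AU data frame with constant intensities.
make_au_df <- function(intensity = 0.5, n = 3, confidence = 0.95,
                       success = 1, t0 = 0, fps = 30) {
  vals <- matrix(intensity, nrow = n, ncol = length(AU_SET),
                 byrow = length(intensity) > 1)
  colnames(vals) <- paste0("AU", AU_SET, "_r")
  cbind(data.frame(frame = seq_len(n),
                   timestamp = t0 + (seq_len(n) - 1) / fps,
                   confidence = confidence, success = success),
        as.data.frame(vals))
}

# A PANSS item vector with the given subscale item scores.
make_items <- function(p = 1, n = 1, g = 1) {
  stats::setNames(c(rep(p, 7), rep(n, 7), rep(g, 16)),
                  c(paste0("P", 1:7), paste0("N", 1:7), paste0("G", 1:16)))
}

pure_tone <- function(freq, duration = 3, fs = 16000, amp = 0.8) {
  audio_signal(amp * sin(2 * pi * freq * (0:(duration * fs - 1)) / fs), fs)
}
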