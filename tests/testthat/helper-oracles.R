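# Independent oracles used to cross-check the package implementations.

# mean of the k fastest values, by repeated extraction of the maximum
topk_mean_oracle <- function(pool, k) {
  picked <- numeric(0)
  for (i in seq_len(min(k, length(pool)))) {
    j <- which.max(pool)
    picked <- c(picked, pool[j])
    pool <- pool[-j]
  }
  mean(picked)
}

# closed-form simple linear regression via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# exhaustive all-pairs burst scan: a burst is the suffix, from the first
# seeding ISI, of a maximal block (i..j) whose internal gaps are all
# <= quiet_s and which is bounded by > quiet_s silence (or the train edge)
burst_scan_oracle <- function(t, isi_join_s = 0.05, quiet_s = 0.1, min_spikes = 3) {
  n <- length(t)
  out <- NULL
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      internal_ok <- all(diff(t[i:j]) <= quiet_s)
      left_max <- i == 1 || (t[i] - t[i - 1]) > quiet_s
      right_max <- j == n || (t[j + 1] - t[j]) > quiet_s
      if (!(internal_ok && left_max && right_max)) next
      gaps <- diff(t[i:j])
      seed <- which(gaps <= isi_join_s)[1]
      if (is.na(seed)) next
      k <- i + seed - 1                       # first spike of the burst
      if (j - k + 1 >= min_spikes) {
        out <- rbind(out, c(t_start = t[k], t_end = t[j], n_spikes = j - k + 1))
      }
    }
  }
  if (is.null(out)) NULL else as.data.frame(out)
}

# hand-computed Pearson chi-square
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - e)^2 / e),
       df = (nrow(m) - 1) * (ncol(m) - 1))
}
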