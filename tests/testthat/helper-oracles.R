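# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force or direct formula, separately from the package
# code paths they check.

# O(n^2) tie-corrected Kendall tau-b from the concordant/discordant pair
# definition.
brute_force_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Hann-windowed magnitude spectrum in dB (relative to its own maximum).
spectrum_db <- function(audio) {
  x <- audio$samples
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  s <- Mod(stats::fft(x * w))[1:floor(n / 2)]
  list(freq = (seq_len(floor(n / 2)) - 1) * audio$sample_rate / n,
       db = 20 * log10(pmax(s, 1e-12) / max(s)))
}

# Level (dB rel. spectrum max) of the strongest bin within +-tol Hz of f.
level_at <- function(spec, f, tol = 15) {
  idx <- which(abs(spec$freq - f) <= tol)
  max(spec$db[idx])
}

# Count distinct spectral peaks above `floor_db` at frequencies > fmin_hz:
# local maxima of the dB spectrum separated by at least `min_sep` Hz.
count_peaks_above <- function(spec, fmin_hz, floor_db = -35,
                              min_sep = 50) {
  db <- spec$db; f <- spec$freq
  cand <- which(db > floor_db & f > fmin_hz)
  cand <- cand[cand > 1 & cand < length(db)]
  cand <- cand[db[cand] >= db[cand - 1] & db[cand] >= db[cand + 1]]
  if (!length(cand)) return(0L)
  keep <- c()
  for (i in cand) {
    if (!length(keep) || f[i] - f[keep[length(keep)]] >= min_sep)
      keep <- c(keep, i)
  }
  length(keep)
}

# Minimal independent replay of the 2-down-1-up rule for a fixed response
# sequence (used as the hand-trace oracle for run_staircase).
replay_staircase <- function(responses, start = 6, steps = c(1, 0.1, 0.02),
                             after = c(4, 8), total_rev = 14,
                             floor_exc = 0.02) {
  exc <- start; cc <- 0; last <- 0; nrev <- 0
  out_exc <- c(); out_rev <- c()
  for (t in seq_along(responses)) {
    if (nrev >= total_rev) break
    step <- steps[findInterval(nrev, after) + 1]
    ch <- 0
    if (responses[t]) { cc <- cc + 1; if (cc == 2) { ch <- -step; cc <- 0 } }
    else { ch <- step; cc <- 0 }
    rev <- FALSE
    if (ch != 0) {
      if (last != 0 && sign(ch) != last) { rev <- TRUE; nrev <- nrev + 1 }
      last <- sign(ch)
    }
    out_exc <- c(out_exc, exc); out_rev <- c(out_rev, rev)
    exc <- max(floor_exc, exc + ch)
  }
  list(excursion = out_exc, is_reversal = out_rev)
}
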