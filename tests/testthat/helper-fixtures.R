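# shared fixtures and independent oracles

# brute-force all-pairs AUC oracle (ties = 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small scored synthetic cohort at the default study design
make_scored <- function(seed = 1, ...) {
  p <- cohort_params(seed = seed)
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  score_cohort(generate_cohort(p)$cohort)
}

# a minimal waveform: sum of gaussian bumps on a time grid
bump_waveform <- function(centers, amps, widths = 0.3, fs = 24000,
                          dur = 10.66) {
  n <- round(fs * dur / 1000)
  t <- (seq_len(n) - 1) / fs * 1000
  y <- rep(0, n)
  widths <- rep_len(widths, length(centers))
  for (i in seq_along(centers)) {
    y <- y + amps[i] * exp(-(t - centers[i])^2 / (2 * widths[i]^2))
  }
  abr_waveform(y, fs)
}
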