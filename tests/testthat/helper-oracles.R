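## naive reference implementations used as independent oracles

brute_tdauc <- function(risk, time, event, Gfun, t, strict = FALSE) {
  num <- 0; wsum <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t) {
      wi <- 1 / Gfun(time[i])
      wsum <- wsum + wi
      for (j in seq_len(n)) {
        if (time[j] > t) {
          cmp <- if (risk[i] > risk[j]) 1
                 else if (!strict && risk[i] == risk[j]) 0.5 else 0
          num <- num + wi * cmp
        }
      }
    }
  }
  num / (sum(time > t) * wsum)
}

brute_brier <- function(risk, time, event, Gfun, Gt, t) {
  n <- length(risk)
  tot <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t) tot <- tot + (1 - risk[i])^2 / Gfun(time[i])
    else if (time[i] > t) tot <- tot + risk[i]^2 / Gt
  }
  tot / n
}
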