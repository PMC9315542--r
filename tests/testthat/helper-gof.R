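# Brute-force goodness-of-fit oracles, deliberately naive loops kept
# independent of the package's vectorized formulas
ad_brute <- function(u) {
  u <- sort(u)
  n <- length(u)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + (2 * i - 1) * (log(u[i]) + log(1 - u[n + 1 - i]))
  }
  -n - total / n
}

ks_brute <- function(u) {
  u <- sort(u)
  n <- length(u)
  worst <- 0
  for (i in seq_len(n)) {
    worst <- max(worst, i / n - u[i], u[i] - (i - 1) / n)
  }
  worst
}
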