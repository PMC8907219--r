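# Independent two-pass loop oracles for the three metrics.
nmad_oracle <- function(x, y, keep) {
  s <- 0; n <- 0
  for (i in seq_along(x)) if (keep[i]) { s <- s + abs(x[i] - y[i]) / 2; n <- n + 1 }
  s / n
}
nrse_oracle <- function(x, y, keep) {
  mx <- 0
  for (i in seq_along(x)) if (keep[i]) mx <- max(mx, sqrt((x[i] - y[i])^2))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) if (keep[i])
    out[i] <- if (mx == 0) 0 else sqrt((x[i] - y[i])^2) / mx
  out
}
amd_oracle <- function(x, y, keep) {
  s <- 0; n <- 0
  for (i in seq_along(x)) if (keep[i]) { s <- s + log(x[i] + 2) - log(y[i] + 2); n <- n + 1 }
  abs(s / n)
}
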