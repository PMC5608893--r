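# Independent brute-force oracles shared by the unit and acceptance suites.

# Rosendaal oracle: evaluate the interpolated INR on a fine grid and
# classify each step by its midpoint; excludes over-long gaps and clips to
# the window, like the implementation but through a different route.
grid_ttr <- function(day, inr, lo = 2, hi = 3, window = 183, max_gap = 56,
                     step = 0.01) {
  tin <- tbelow <- tabove <- ttot <- 0
  for (k in seq_len(length(day) - 1)) {
    if (day[k + 1] - day[k] > max_gap || day[k] >= window) next
    d2 <- min(day[k + 1], window)
    g <- seq(day[k], d2, by = step)
    v <- inr[k] + (inr[k + 1] - inr[k]) * (g - day[k]) / (day[k + 1] - day[k])
    mid <- (v[-1] + v[-length(v)]) / 2   # midpoint classification per step
    ttot <- ttot + (d2 - day[k])
    tin <- tin + step * sum(mid >= lo & mid <= hi)
    tbelow <- tbelow + step * sum(mid < lo)
    tabove <- tabove + step * sum(mid > hi)
  }
  100 * c(in_ = tin, below = tbelow, above = tabove) / ttot
}

# exhaustive event/non-event pair enumeration for the c-index
c_index_pair_oracle <- function(s, y) {
  se <- s[y]; sn <- s[!y]
  mean(outer(se, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}
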