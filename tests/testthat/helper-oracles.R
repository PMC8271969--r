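# Brute-force oracle implementations of the printed feature formulas,
# written as plain loops so they stay independent of the package's
# vectorised implementations.

o_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

o_std <- function(x) {
  m <- o_mav_signed(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
o_mav_signed <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }

o_wl <- function(x, squared = TRUE) {
  s <- 0
  for (k in 2:length(x)) {
    d <- x[k] - x[k - 1]
    s <- s + if (squared) d^2 else abs(d)
  }
  s
}

o_ssc <- function(x, eps = 0.001) {
  cnt <- 0
  for (k in 2:(length(x) - 1)) {
    d1 <- x[k] - x[k - 1]
    d2 <- x[k + 1] - x[k]
    if (sign(d1) * sign(d2) < 0 && abs(d1) >= eps && abs(d2) >= eps)
      cnt <- cnt + 1
  }
  cnt
}

o_wamp <- function(x, eps = 0.5) {
  cnt <- 0
  for (k in 2:length(x))
    if (abs(x[k] - x[k - 1]) >= eps) cnt <- cnt + 1
  cnt
}

# first grid line at which cumulative power reaches half the total
o_fmd <- function(freqs, power) {
  tot <- sum(power)
  cum <- 0
  for (k in seq_along(power)) {
    cum <- cum + power[k]
    if (cum >= tot / 2) return(freqs[k])
  }
  freqs[length(freqs)]
}

o_fmn <- function(freqs, power) {
  num <- 0; den <- 0
  for (k in seq_along(power)) {
    num <- num + freqs[k] * power[k]
    den <- den + power[k]
  }
  num / den
}

o_hlr <- function(freqs, power, low, high) {
  lo <- 0; hi <- 0
  for (k in seq_along(power)) {
    if (freqs[k] >= low[1] && freqs[k] < low[2]) lo <- lo + power[k]
    if (freqs[k] >= high[1] && freqs[k] < high[2]) hi <- hi + power[k]
  }
  hi / lo
}

o_nn_count <- function(ibis, thresh) {
  cnt <- 0
  for (k in 2:length(ibis))
    if (abs(ibis[k] - ibis[k - 1]) >= thresh) cnt <- cnt + 1
  cnt
}

o_hrv_std <- function(ibis) {
  h <- length(ibis)
  d <- numeric(h - 1)
  for (k in 2:h) d[k - 1] <- ibis[k] - ibis[k - 1]
  m <- sum(d) / (h - 1)
  s <- 0
  for (v in d) s <- s + (v - m)^2
  sqrt(s / (h - 2))
}
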