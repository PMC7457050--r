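# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# count records per half-open bin [edges[i], edges[i+1]) by explicit loop
brute_force_bin_freq <- function(x, edges) {
  counts <- integer(length(edges) - 1L)
  for (v in x) {
    for (i in seq_along(counts)) {
      if (v >= edges[i] && v < edges[i + 1L]) {
        counts[i] <- counts[i] + 1L
        break
      }
    }
  }
  100 * counts / length(x)
}

# strict below/above percentages by explicit scan
brute_force_outside <- function(x, low, high) {
  nb <- 0L; na <- 0L
  for (v in x) {
    if (v < low) nb <- nb + 1L
    if (v > high) na <- na + 1L
  }
  c(100 * nb / length(x), 100 * na / length(x))
}

# carbon balance by explicit accumulation over contributions
brute_force_balance <- function(contrib) {
  pos <- 0; neg <- 0
  for (v in contrib) {
    if (v > 0) pos <- pos + v
    if (v < 0) neg <- neg - v
  }
  c(100 * pos / (pos + neg), 100 * neg / (pos + neg))
}

# quick valid trace from bare temperatures
make_trace <- function(temps, start = "2003-01-16 00:00") {
  temperature_trace(as.POSIXct(start, tz = "UTC") + 3600 * seq_along(temps),
                    temps)
}
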