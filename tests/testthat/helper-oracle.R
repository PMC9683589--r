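# Plain-loop reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_median_profile <- function(values) {
  out <- numeric(nrow(values))
  for (b in seq_len(nrow(values))) out[b] <- oracle_median(values[b, ])
  out
}

# exhaustive scan for the landmark pair: last bin attaining the window
# minimum, then first bin after it attaining the maximum over the rest
oracle_landmarks <- function(zt, med, window_start, transition, bin = 30) {
  cand <- which(zt >= window_start & zt <= transition - bin & !is.na(med))
  mn <- Inf; i_min <- NA
  for (i in cand) if (med[i] <= mn) { mn <- med[i]; i_min <- i }
  mx <- -Inf; i_max <- NA
  for (i in cand) {
    if (i > i_min && med[i] > mx) { mx <- med[i]; i_max <- i }
  }
  list(zt_min = zt[i_min], zt_max = zt[i_max])
}

oracle_fly_slopes <- function(values, zt, zt_min, zt_max) {
  i <- which(zt == zt_min); j <- which(zt == zt_max)
  out <- numeric(ncol(values))
  for (f in seq_len(ncol(values))) {
    out[f] <- (values[j, f] - values[i, f]) / (zt_max - zt_min)
  }
  out
}

# textbook Kruskal-Wallis H with tie correction, computed with loops
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  pos <- 0
  h <- 0
  for (g in groups) {
    rg <- r[(pos + 1):(pos + length(g))]
    h <- h + length(g) * (mean(rg) - (n + 1) / 2)^2
    pos <- pos + length(g)
  }
  h <- 12 * h / (n * (n + 1))
  tie <- 0
  for (v in unique(x)) {
    tv <- sum(x == v)
    tie <- tie + (tv^3 - tv)
  }
  h / (1 - tie / (n^3 - n))
}

# sort-based interpolated quartile (type-7), written out longhand
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
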