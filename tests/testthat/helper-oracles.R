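# Independent brute-force oracles the implementation is checked against.

# Grid search over acrophase with mesor/amplitude profiled by least squares
# at each candidate phase; independent of the linearized cosinor solution.
grid_cosinor_acrophase <- function(y, step = 0.01) {
  t <- 0:23
  phis <- seq(0, 24 - step, by = step)
  sse <- vapply(phis, function(phi) {
    x <- cos(2 * pi * (t - phi) / 24)
    # profile mesor and amplitude, constraining amplitude >= 0 (an
    # unconstrained slope would make phi and phi + 12 indistinguishable)
    a <- max(0, sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
    sum((y - mean(y) - a * (x - mean(x)))^2)
  }, numeric(1))
  phis[which.min(sse)]
}

# Circular distance between two dial positions, in hours.
circ_dist_h <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# Circular mean by exhaustive minimization of summed squared circular
# distance over a fine grid of candidate means.
grid_circular_mean <- function(phases, step = 0.001) {
  cand <- seq(0, 24 - step, by = step)
  circ_dist <- function(a, b) {
    d <- abs(a - b) %% 24
    pmin(d, 24 - d)
  }
  cost <- vapply(cand, function(m) sum(circ_dist(m, phases)^2), numeric(1))
  cand[which.min(cost)]
}

# Least-squares ratio oracle for the overlap coefficient: the c minimizing
# sum((ref - c * inc)^2).
ls_ratio <- function(ref, inc) sum(ref * inc) / sum(inc^2)

# Hand-coded classic equal-variance two-sample t-test p-value.
student_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tt), n1 + n2 - 2)
}

# Random valid RSV segment (integers, max = 100) for round-trip tests.
random_segment <- function(term = "word", start = as.POSIXct("2018-03-10 00:00:00", tz = "UTC")) {
  v <- sample(0:100, 168, replace = TRUE)
  v[sample(168, 1)] <- 100L
  rsv_segment(term, start, v)
}

# Quick low-noise config used across pipeline tests.
quiet_config <- function(...) {
  sim_config(noise_sd = 0.5, segment_scale_jitter = 0.05, ...)
}
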