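# Independent oracles used to freeze expected values. These deliberately use
# brute force / closed forms, never the package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(n, m)
  u_all <- apply(combos, 2L, u_of)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Exact two-sided signed-rank p by enumeration of all sign patterns.
sr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# Direct summation of squared samples over inclusive 0-based ranges.
direct_sq_sum <- function(signal, from0, to0) {
  tot <- 0
  for (k in seq_along(from0)) {
    tot <- tot + sum(signal[(from0[k] + 1):(to0[k] + 1)]^2)
  }
  tot
}

# Argmax of the analytic two-bump template on a dense grid (fraction of
# beat), evaluated with the same circularly wrapped distance the template
# defines but computed independently here.
dense_template_argmax <- function(tpl, n_grid = 100000) {
  fr <- (0:(n_grid - 1)) / n_grid
  wrap <- function(d) d - round(d)
  ds <- wrap(fr - tpl$systolic_center)
  ws <- tpl$systolic_width * ifelse(ds < 0, 1 + tpl$systolic_skew, 1 - tpl$systolic_skew)
  v <- tpl$systolic_amp * exp(-ds^2 / (2 * ws^2)) +
    tpl$diastolic_amp * exp(-wrap(fr - tpl$diastolic_center)^2 / (2 * tpl$diastolic_width^2))
  fr[which.max(v)]
}

# Squared magnitude of a digital filter's frequency response at f (Hz):
# closed form from the designed coefficients, squared again for the
# forward-backward application.
filtfilt_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(h)^2
}
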