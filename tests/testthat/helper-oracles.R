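# Independent oracles used across the suite.  These deliberately use
# brute-force enumeration or direct computation so that they share no code
# with the implementation paths they check.

# Two-sided Fisher exact p by enumerating every 2x2 table with the observed
# margins and summing the probabilities of tables no more probable than the
# observed one.
fisher_oracle <- function(k_a, n_a, k_b, n_b) {
  k_tot <- k_a + k_b
  lo <- max(0, k_tot - n_b)
  hi <- min(n_a, k_tot)
  ks <- lo:hi
  pr <- stats::dhyper(ks, n_a, n_b, k_tot)
  obs <- stats::dhyper(k_a, n_a, n_b, k_tot)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by full enumeration of group assignments
# (midranks, deviation of the rank sum from its mean).
mw_oracle <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  n <- length(r)
  mu <- n1 * sum(r) / n
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  sets <- utils::combn(n, n1)
  w <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(w - mu) >= obs - 1e-9)
}

# Best single least-squares breakpoint of a numeric series (exhaustive).
single_break_oracle <- function(x) {
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  gains <- vapply(1:(n - 1), function(k)
    ss(x) - ss(x[1:k]) - ss(x[(k + 1):n]), numeric(1))
  which.max(gains)
}

# Exhaustive least-squares state fit for one segment (enumeration oracle).
state_oracle <- function(mean_t, mean_strong, rho, c_tilde,
                         max_copies = 12) {
  best <- NULL; best_r <- Inf
  for (a in 0:max_copies) for (b in 0:a) {
    ex <- expected_signals(a, b, rho, c_tilde)
    r <- (mean_t - ex$t)^2 + (mean_strong - ex$mirrored)^2
    if (r < best_r - 1e-12) { best_r <- r; best <- c(a, b) }
  }
  best
}
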