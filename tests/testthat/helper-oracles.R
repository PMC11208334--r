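# Independent oracles used across test files.

# Brute-force one-sided signed-rank p-value: enumerate all 2^n assignments of
# signs to the observed absolute differences (zero differences removed, ties
# mid-ranked) and count rank sums at least as large as the observed one.
brute_force_signed_rank_p <- function(x, y, shift = 0) {
  d <- x - (y + shift)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  mean(w_all >= w_obs)
}

# A random valid transition matrix with the chain's structure (absorbing
# quit state, no direct leave-to-quit transition).
random_transition_matrix <- function() {
  p12 <- runif(1, 0, 0.4)
  p13 <- runif(1, 0, 0.3)
  p21 <- runif(1, 0, 1)
  h <- hazard_parameters(
    q_hie = 1, p_dayoff_high = p12, p_dayoff_low = 0,
    p_quit_high = p13, p_quit_low = 0, recovery_prob = p21
  )
  build_transition_matrix(h)
}
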