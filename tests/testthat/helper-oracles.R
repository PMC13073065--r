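# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the hypergeometric tail is summed from log
# binomial coefficients, and the BH step-up rule is applied literally.

# P(X >= a) for X ~ Hypergeom(m term genes, N - m others, k draws)
hyper_tail_oracle <- function(a, m, N, k) {
  hi <- min(m, k)
  if (a > hi) return(0)
  lo <- max(a, 0, k - (N - m))
  terms <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(N - m, k - x) - lchoose(N, k))
  }, 0)
  sum(terms)
}

# literal BH step-up: q_(i) = min(1, min_{j >= i} (m/j) p_(j)), computed
# with an explicit suffix minimum per rank
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    qs[i] <- min(m / j * po[j], 1)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# small screen used by several suites; sized for speed, defaults otherwise
small_screen <- function(seed, n_genes = 120, ...) {
  simulate_screen(screen_sim_config(n_genes = n_genes, seed = seed, ...))
}

score_sim <- function(sim, threshold = 2.0) {
  fits <- fit_screen(sim$series)
  qc <- qc_arrays(fits)
  score_screen(fits, sim$design, qc = qc, threshold = threshold)
}
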