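# Independent oracles the implementation is checked against.

# Step-up FDR adjustment written directly from the procedure: sort, scale
# by m/i, enforce monotonicity from the largest p down, cap at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Multinomial bootstrap SD of the Perkins estimator.
bootstrapPerkinsSE <- function(pd, npd, tt, B = 1e5) {
  n <- pd + npd + tt
  draws <- stats::rmultinom(B, n, c(pd, npd, tt) / n)
  est <- 100 * (draws[3, ] / 2 + 3 * draws[2, ]) / n
  stats::sd(est)
}

# Transition-matrix oracle for the no-interference tetrad-class chain:
# one crossover moves PD -> TT; TT -> PD/NPD/TT w.p. 1/4, 1/4, 1/2;
# NPD -> TT. Class probabilities are the Poisson(d/50) mixture of chain
# states starting from PD.
chainClassFreqs <- function(d, kmax = max(20, ceiling(d / 50) * 10)) {
  M <- rbind(PD  = c(0, 0, 1),
             NPD = c(0, 0, 1),
             TT  = c(1 / 4, 1 / 4, 1 / 2))
  colnames(M) <- rownames(M)
  state <- c(PD = 1, NPD = 0, TT = 0)
  lam <- d / 50
  acc <- stats::dpois(0, lam) * state
  for (k in seq_len(kmax)) {
    state <- as.vector(state %*% M)
    acc <- acc + stats::dpois(k, lam) * state
  }
  names(acc) <- c("PD", "NPD", "TT")
  acc
}
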