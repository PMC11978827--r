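# Naive loop oracles for the two loss formulas, used by the unit and
# acceptance suites. Deliberately written as literal loops over the printed
# sums, independent of the vectorized implementation paths.

lcon_oracle <- function(P, Q, sigma, normalize = TRUE) {
  if (normalize) {
    P <- P / sqrt(rowSums(P^2)); Q <- Q / sqrt(rowSums(Q^2))
  }
  n <- nrow(P)
  t1 <- t2 <- 0
  for (i in seq_len(n)) {
    num <- exp(sum(P[i, ] * Q[i, ]) / sigma)
    den <- 0
    for (j in seq_len(n)) den <- den + exp(sum(P[i, ] * Q[j, ]) / sigma)
    t1 <- t1 - log(num / den)
    den2 <- 0
    for (j in seq_len(n)) den2 <- den2 + exp(sum(Q[i, ] * P[j, ]) / sigma)
    t2 <- t2 - log(num / den2)
  }
  t1 / n + t2 / n
}

lbfg_oracle <- function(Pl, Qr, normalize = TRUE, batch_norm = FALSE) {
  n <- dim(Pl)[1]; nr <- dim(Pl)[2]
  tot <- 0
  for (i in seq_len(n)) {
    Pi <- matrix(Pl[i, , ], nr); Qi <- matrix(Qr[i, , ], nr)
    if (normalize) {
      Pi <- Pi / sqrt(rowSums(Pi^2)); Qi <- Qi / sqrt(rowSums(Qi^2))
    }
    for (k in seq_len(nr)) {
      den <- 0
      for (g in seq_len(nr)) den <- den + exp(sum(Pi[k, ] * Qi[g, ]))
      tot <- tot - log(exp(sum(Pi[k, ] * Qi[k, ])) / den)
    }
  }
  out <- tot / nr
  if (batch_norm) out / n else out
}
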