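# Independent brute-force oracles used to pin expected values.

# Exhaustive two-sided Wilcoxon rank-sum: enumerate every assignment of the
# pooled observations to group A and count assignments at least as extreme
# (|U - E[U]|) as observed.
enum_wilcoxon <- function(xA, xB) {
  nA <- length(xA); n <- nA + length(xB)
  r <- rank(c(xA, xB))
  mu <- nA * (n - nA) / 2
  U_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(n, nA)
  U_all <- colSums(matrix(r[combos], nrow = nA)) - nA * (nA + 1) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Fisher 2x2 by full table enumeration with fixed margins; probabilities
# from the factorial formula, two-sided by the probability-mass rule.
enum_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1), 0)
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Naive Benjamini-Hochberg step-up.
naive_bh <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  m <- length(q)
  o <- order(q)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, q[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric by direct pmf summation.
enum_hyper_upper <- function(overlap, set_size, universe, list_size) {
  ks <- overlap:min(set_size, list_size)
  sum(vapply(ks, function(k)
    choose(set_size, k) * choose(universe - set_size, list_size - k) /
      choose(universe, list_size), 0))
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  srow <- sum(choose(rowSums(tab), 2))
  scol <- sum(choose(colSums(tab), 2))
  stot <- choose(sum(tab), 2)
  expected <- srow * scol / stot
  (sij - expected) / ((srow + scol) / 2 - expected)
}
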