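# Independent oracles used across the suite. These re-derive expected values
# from first principles and deliberately share no code with the package
# internals they check.

# Brute-force replay of the shock-test schedule rules on a sorted vector of
# active response times: responses 1-3 of a cycle have no outcome, the 4th
# yields a shock, the 5th a shock plus pellet (10-s time-out); a cycle parked
# after its 4th response for more than 60 s restarts.
oracle_shock_replay <- function(times) {
  shocks <- 0L; pellets <- 0L; cyc <- 0L; abandoned <- 0L
  timeout_end <- -Inf; t4 <- -Inf
  for (t in sort(times)) {
    if (t < timeout_end) next
    if (cyc == 4L && t - t4 > 60) { cyc <- 0L; abandoned <- abandoned + 1L }
    cyc <- cyc + 1L
    if (cyc == 4L) {
      shocks <- shocks + 1L; t4 <- t
    } else if (cyc == 5L) {
      shocks <- shocks + 1L; pellets <- pellets + 1L
      timeout_end <- t + 10; cyc <- 0L
    }
  }
  if (cyc == 4L) abandoned <- abandoned + 1L  # parked past its 4th at the end
  list(shocks = shocks, pellets = pellets, abandoned = abandoned)
}

# Literal Benjamini-Hochberg step-up definition with explicit loops
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  q[order(o)]
}

# Exhaustive-enumeration upper-tail hypergeometric probability: draw every
# size-s subset of 1..n_u, with A = 1..m, and count overlaps >= k
oracle_hyper_tail <- function(k, m, s, n_u) {
  if (s == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(n_u, s)
  overlaps <- colSums(subsets <= m)
  mean(overlaps >= k)
}

# Type-7 quantile by its textbook interpolation formula
oracle_quantile7 <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Pearson chi-squared from the textbook formula
oracle_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Active response times that complete exactly the first n_steps PR ladder
# requirements, spaced so every response falls outside the 10-s time-out
build_pr_times <- function(n_steps, gap = 0.2, ladder = pr_ladder()) {
  times <- c()
  t <- 0
  for (k in seq_len(n_steps)) {
    times <- c(times, t + seq_len(ladder[k]) * gap)
    t <- tail(times, 1) + 10 + gap  # clear the post-pellet time-out
  }
  times
}
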