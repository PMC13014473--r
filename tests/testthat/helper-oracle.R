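# Independent brute-force oracle: enumerates every legal align/extend state
# path for small instances, computing the total log score, per-cell
# posteriors and path-weighted expectations directly from the path list.
# Deliberately written without the package's DP primitives.

# All dwell vectors d (length n_seg, each >= min_len, sum = t_len).
enumerate_dwells <- function(t_len, n_seg, min_len = 2) {
  if (n_seg == 1) {
    if (t_len >= min_len) return(list(t_len)) else return(list())
  }
  out <- list()
  for (d1 in min_len:(t_len - min_len * (n_seg - 1))) {
    for (rest in enumerate_dwells(t_len - d1, n_seg - 1, min_len)) {
      out[[length(out) + 1]] <- c(d1, rest)
    }
  }
  out
}

# Full enumeration for one instance. kmers are 1-based model indices.
oracle_enumerate <- function(samples, kmers, model, a1, e1 = 1, e2 = 1 - a1) {
  t_len <- length(samples)
  n <- length(kmers)
  dwells <- enumerate_dwells(t_len, n)
  logw <- vapply(dwells, function(d) {
    lw <- (n - 1) * log(a1) + n * log(e1) + sum(d - 2) * log(e2)
    pos <- 1
    for (j in seq_len(n)) {
      lw <- lw + sum(dnorm(samples[pos:(pos + d[j] - 1)],
                           mean = model$level_mean[kmers[j]],
                           sd = model$level_stdv[kmers[j]], log = TRUE))
      pos <- pos + d[j]
    }
    lw
  }, numeric(1))
  m <- max(logw)
  log_Z <- m + log(sum(exp(logw - m)))

  # Per-cell posteriors: the path with dwells d visits A[j, start_j] and
  # E[j, start_j + 1 .. end_j].
  post_A <- matrix(0, n, t_len)
  post_E <- matrix(0, n, t_len)
  pw <- exp(logw - log_Z)
  for (p in seq_along(dwells)) {
    d <- dwells[[p]]
    starts <- cumsum(c(1, d[-n]))
    for (j in seq_len(n)) {
      post_A[j, starts[j]] <- post_A[j, starts[j]] + pw[p]
      idx <- (starts[j] + 1):(starts[j] + d[j] - 1)
      post_E[j, idx] <- post_E[j, idx] + pw[p]
    }
  }
  list(dwells = dwells, logw = logw, log_Z = log_Z, weights = pw,
       post_A = post_A, post_E = post_E,
       min_seg_len = if (length(dwells)) min(unlist(dwells)) else NA)
}

# Posterior-Viterbi argmax by enumeration: score each path by the sum of
# log posteriors at its cells, pick the best.
oracle_map_dwells <- function(orc) {
  scores <- vapply(seq_along(orc$dwells), function(p) {
    d <- orc$dwells[[p]]
    n <- length(d)
    starts <- cumsum(c(1, d[-n]))
    s <- 0
    for (j in seq_len(n)) {
      s <- s + log(orc$post_A[j, starts[j]]) +
        sum(log(orc$post_E[j, (starts[j] + 1):(starts[j] + d[j] - 1)]))
    }
    s
  }, numeric(1))
  orc$dwells[[which.max(scores)]]
}

# Path-weighted expected transition counts (a1 openings, e2 extensions).
oracle_expected_transitions <- function(orc) {
  n_seg <- length(orc$dwells[[1]])
  e2_uses <- vapply(orc$dwells, function(d) sum(d - 2), numeric(1))
  c(a1 = sum(orc$weights) * (n_seg - 1),
    e2 = sum(orc$weights * e2_uses))
}
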