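# Independent oracles used by the tests. These deliberately take the slow,
# brute-force route (memoized recursion, full enumeration, exhaustive
# summation) and share no code with the package internals they check.

# Number of left/right arrangements with no run longer than max_run,
# counted by memoized recursion over (left remaining, right remaining,
# last side, trailing-run length).
oracle_count_sequences <- function(n_left, n_right, max_run) {
  memo <- new.env(parent = emptyenv())
  rec <- function(l, r, last, run) {
    if (l == 0L && r == 0L) return(1)
    key <- paste(l, r, last, run)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    tot <- 0
    if (l > 0L && !(last == "L" && run == max_run)) {
      tot <- tot + rec(l - 1L, r, "L", if (last == "L") run + 1L else 1L)
    }
    if (r > 0L && !(last == "R" && run == max_run)) {
      tot <- tot + rec(l, r - 1L, "R", if (last == "R") run + 1L else 1L)
    }
    memo[[key]] <- tot
    tot
  }
  rec(n_left, n_right, "", 0L)
}

# Full enumeration of the valid sequence set for small n (as strings of
# "L"/"R"), by filtering every left-position subset.
oracle_enumerate_sequences <- function(n_left, n_right, max_run) {
  n <- n_left + n_right
  if (n_left == 0L || n_right == 0L) {
    s <- paste(rep(if (n_left > 0L) "L" else "R", n), collapse = "")
    return(if (n <= max_run) s else character(0))
  }
  subsets <- utils::combn(n, n_left)
  out <- character(0)
  for (j in seq_len(ncol(subsets))) {
    v <- rep("R", n)
    v[subsets[, j]] <- "L"
    if (max(rle(v)$lengths) <= max_run) {
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Exact Mann-Whitney by brute-force enumeration of every group assignment.
# Returns U (pair-count definition) and the one/two-sided permutation
# p-values under the doubled-tail convention.
oracle_mw_enum <- function(x, y) {
  n_a <- length(x); n_b <- length(y); n <- n_a + n_b
  pooled <- c(x, y)
  u1 <- 0
  for (xi in x) u1 <- u1 + sum(xi > y) + 0.5 * sum(xi == y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  subsets <- utils::combn(n, n_a)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  list(U1 = u1, U = min(u1, n_a * n_b - u1),
       p_two = min(1, 2 * min(p_le, p_ge)), p_le = p_le, p_ge = p_ge)
}

# Exact two-sided binomial p by exhaustive summation of all outcome
# probabilities no larger than the observed one (with the customary
# relative tolerance for floating-point equality).
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Flat re-scan of a trial-log data frame, independent of the scoring code:
# per-session accuracies/trial counts straight from the rows.
oracle_session_table <- function(trials, phase) {
  tr <- trials[trials$phase == phase, ]
  ns <- tapply(tr$trial_index, tr$session_index, length)
  ks <- tapply(as.integer(tr$correct), tr$session_index, sum)
  ord <- order(as.integer(names(ns)))
  data.frame(session_index = as.integer(names(ns))[ord],
             n_trials = as.integer(ns)[ord], n_correct = as.integer(ks)[ord])
}
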