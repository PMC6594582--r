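# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# all permutations of 1..n as rows (n! x n); fine for n <= 8
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  unname(out)
}

# a random consecutive-distinct ordering of a fixed action multiset
valid_order <- function(acts) {
  repeat {
    out <- character(length(acts))
    pool <- table(acts)
    ok <- TRUE
    prev <- ""
    for (t in seq_along(acts)) {
      cand <- names(pool)[pool > 0 & names(pool) != prev]
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = pool[cand])
      out[t] <- pick
      pool[pick] <- pool[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
}

# toy cohort whose flies share one bout composition (same per-action duration
# multisets) in different consecutive-distinct orders; under within-fly
# permutation its Monte-Carlo null expectation equals the pooled analytic
# formula, which is the regime the analytic nulls describe
make_matched_toy <- function(n_flies = 3L, actions = c("f", "h", "wk"),
                             n_each = 10L, n_bins = 2L, seed = 11L) {
  withr::with_seed(seed, {
    acts <- rep(actions, each = n_each)
    durs <- lapply(actions, function(a) stats::rlnorm(n_each, 0.3, 0.5))
    names(durs) <- actions
    cohort <- lapply(seq_len(n_flies), function(i) {
      a <- valid_order(acts)
      d <- numeric(length(a))
      for (act in actions) d[a == act] <- sample(durs[[act]])
      bout_ethogram(a, d, fly_id = i)
    })
  })
  scheme <- fit_binning_scheme(cohort, n_bins)
  list(cohort = lapply(cohort, apply_binning, scheme = scheme),
       scheme = scheme,
       space = build_state_space(actions, n_bins))
}

# exhaustive duration-permutation oracle on a single short binned ethogram:
# average transition counts over ALL joint within-action label permutations,
# then row-normalize
exhaustive_duration_null <- function(etho, space) {
  df <- etho$bouts
  n <- nrow(df)
  v <- space$v
  aidx <- match(df$action, space$actions)
  groups <- lapply(space$actions, function(a) which(df$action == a))
  groups <- groups[lengths(groups) > 0L]
  pergroup <- lapply(groups, function(g) perms(length(g)))
  combos <- expand.grid(lapply(pergroup, function(p) seq_len(nrow(p))))
  acc <- matrix(0, v, v)
  for (r in seq_len(nrow(combos))) {
    cc <- df$category
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      cc[g] <- df$category[g][pergroup[[gi]][combos[r, gi], ]]
    }
    idx <- (aidx - 1L) * space$n_bins + cc + 1L
    acc <- acc + matrix(tabulate(idx[-n] + (idx[-1L] - 1L) * v, nbins = v * v), v, v)
  }
  m <- acc / nrow(combos)
  m / ifelse(rowSums(m) > 0, rowSums(m), 1)
}

# exhaustive order-permutation oracle: average counts over all n! orderings
# (same-action adjacent pairs skipped), zero same-action columns, normalize
exhaustive_order_null <- function(etho, space) {
  df <- etho$bouts
  n <- nrow(df)
  v <- space$v
  idx0 <- (match(df$action, space$actions) - 1L) * space$n_bins + df$category + 1L
  po <- perms(n)
  acc <- matrix(0, v, v)
  for (r in seq_len(nrow(po))) {
    a <- df$action[po[r, ]]
    idx <- idx0[po[r, ]]
    keep <- a[-n] != a[-1L]
    from <- idx[-n][keep]
    to <- idx[-1L][keep]
    acc <- acc + matrix(tabulate(from + (to - 1L) * v, nbins = v * v), v, v)
  }
  m <- acc / nrow(po)
  m[outer(space$states$action, space$states$action, "==")] <- 0
  m / ifelse(rowSums(m) > 0, rowSums(m), 1)
}

# structural invariants every transition matrix in the package must satisfy
expect_valid_matrix <- function(M) {
  expect_true(all(M$probs >= 0 & M$probs <= 1))
  rs <- rowSums(M$probs)
  expect_true(all(abs(rs[M$row_support] - 1) < 1e-9))
  expect_true(all(rs[!M$row_support] == 0))
  same <- outer(M$space$states$action, M$space$states$action, "==")
  expect_true(all(M$probs[same] == 0))
}
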