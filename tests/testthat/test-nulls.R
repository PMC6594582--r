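test_that("marginal statistics match hand counts and independent tallies", {
  sp <- build_state_space(c("f", "h"), 1)
  st <- marginal_statistics(bout_ethogram(c("h", "f", "h"), rep(1, 3)), sp)
  expect_equal(st$action_transition["h", "f"], 1)
  expect_equal(st$action_transition["f", "h"], 1)
  expect_equal(st$state_marginal, c(1 / 3, 2 / 3))

  toy <- make_matched_toy()
  st2 <- marginal_statistics(toy$cohort, toy$space)
  # equal-count binning makes per-action category distributions ~uniform
  for (a in toy$space$actions)
    expect_equal(st2$duration_given_action[[a]], c(0.5, 0.5), tolerance = 0.04)
  # independent tally of the state marginal
  all_b <- do.call(rbind, lapply(toy$cohort, function(e) e$bouts))
  lab <- paste(all_b$action, c("s", "l")[all_b$category + 1], sep = ".")
  expect_equal(st2$state_marginal,
               as.numeric(table(factor(lab, toy$space$states$label))) / nrow(all_b))
})

test_that("duration-permuted null has the closed form and degenerate limits", {
  # two actions, two equal categories, deterministic alternation
  e <- bout_ethogram(rep(c("f", "h"), 4), c(1, 1, 2, 2, 1, 1, 2, 2))
  scheme <- fit_binning_scheme(e, 2)
  binned <- apply_binning(e, scheme)
  sp <- build_state_space(c("f", "h"), 2)
  null <- duration_permuted_null(marginal_statistics(binned, sp), sp)
  expect_equal(null$probs["f.s", "h.s"], 0.5)
  expect_equal(null$probs["f.l", "h.l"], 0.5)
  expect_valid_matrix(null)

  # one category: the null equals the action-level MLE exactly
  sp1 <- build_state_space(c("f", "h", "wk"), 1)
  seq1 <- bout_ethogram(c("h", "f", "h", "wk", "h", "f"), rep(1, 6))
  M <- mle_transition_matrix(count_transitions(seq1, sp1))
  null1 <- duration_permuted_null(marginal_statistics(seq1, sp1), sp1)
  expect_equal(null1$probs, M$probs)
})

test_that("order-permuted null spreads state marginals with self-renormalization", {
  sp <- build_state_space(c("f", "h"), 2)
  st <- structure(list(
    action_transition = matrix(c(0, 1, 1, 0), 2, 2,
                               dimnames = list(c("f", "h"), c("f", "h"))),
    duration_given_action = list(f = c(0.5, 0.5), h = c(0.5, 0.5)),
    state_marginal = rep(0.25, 4), space = sp), class = "marginal_statistics")
  null <- order_permuted_null(st, sp)
  expect_true(all(null$probs[null$probs > 0] == 0.5))

  st$state_marginal <- c(0, 0, 1, 0)  # all mass on h.s
  null2 <- order_permuted_null(st, sp)
  expect_equal(null2$probs["f.s", "h.s"], 1)
  expect_equal(null2$probs["f.l", "h.s"], 1)
  expect_false(null2$row_support[3])  # h rows have no admissible mass

  raw <- order_permuted_null(st, sp, renormalize_self = FALSE)
  expect_true(is.matrix(raw))
  expect_equal(raw["f.s", "h.s"], 1)
})

test_that("analytic nulls equal the exhaustive permutation oracles exactly", {
  withr::with_seed(3, {
    acts <- c("f", "h", "f", "wk", "h", "wk")
    e <- bout_ethogram(acts, stats::rlnorm(6), c(1L, 0L, 0L, 1L, 1L, 0L))
  })
  sp <- build_state_space(c("f", "h", "wk"), 2)
  st <- marginal_statistics(e, sp)
  expect_lt(max(abs(exhaustive_duration_null(e, sp) -
                    duration_permuted_null(st, sp)$probs)), 1e-12)
  expect_lt(max(abs(exhaustive_order_null(e, sp) -
                    order_permuted_null(st, sp)$probs)), 1e-12)
})

test_that("Monte-Carlo nulls are seeded, degenerate correctly, and keep row identity", {
  toy <- make_matched_toy()
  a <- monte_carlo_null(toy$cohort, toy$space, "duration", n_perm = 1, seed = 7)
  b <- monte_carlo_null(toy$cohort, toy$space, "duration", n_perm = 1, seed = 7)
  expect_identical(a$mean$probs, b$mean$probs)

  # one category: duration permutation is a no-op, recovering the MLE exactly
  sp1 <- build_state_space(c("f", "h", "wk"), 1)
  flat <- lapply(toy$cohort, function(e)
    bout_ethogram(e$bouts$action, e$bouts$duration, frame_rate = e$frame_rate))
  M <- mle_transition_matrix(count_transitions(flat, sp1))
  mc <- monte_carlo_null(flat, sp1, "duration", n_perm = 3, seed = 1)
  expect_equal(mc$mean$probs, M$probs)
  expect_lt(max(mc$se), 1e-6)  # identical permutations up to fp noise

  # analytic nulls: identical rows within each action block
  st <- marginal_statistics(toy$cohort, toy$space)
  for (null in list(duration_permuted_null(st), order_permuted_null(st))) {
    for (act in toy$space$actions) {
      rows <- which(toy$space$states$action == act)
      expect_equal(null$probs[rows[1], ], null$probs[rows[2], ])
    }
  }
})

test_that("duration-permuted null preserves the MLE's action-block mass", {
  toy <- make_matched_toy()
  M <- mle_transition_matrix(count_transitions(toy$cohort, toy$space))
  null <- duration_permuted_null(marginal_statistics(toy$cohort, toy$space))
  st <- toy$space$states
  counts <- count_transitions(toy$cohort, toy$space)$counts
  for (ai in toy$space$actions) {
    for (aj in setdiff(toy$space$actions, ai)) {
      rows <- st$action == ai
      cols <- st$action == aj
      # action-level mass of the null equals the duration-collapsed MLE
      null_mass <- unname(rowSums(null$probs[rows, cols, drop = FALSE])[1])
      mle_mass <- sum(counts[rows, cols]) / sum(counts[rows, ])
      expect_equal(null_mass, mle_mass, tolerance = 1e-12)
    }
  }
})
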