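test_that("state spaces have deterministic product structure", {
  expect_equal(build_state_space(grooming_actions(), 3)$v, 18)
  expect_equal(build_state_space(grooming_actions(), 1)$v, 6)
  sp <- build_state_space(c("a1" = "f", "a2" = "h"), 2)
  expect_equal(sp$v, 4)
  expect_equal(sp$states$action, c("f", "f", "h", "h"))
  expect_equal(sp$states$category, c(0L, 1L, 0L, 1L))
  expect_error(build_state_space(c("f", "f"), 1), "duplicate")
})

test_that("transition counting pools flies without crossing boundaries", {
  sp <- build_state_space(c("f", "h", "wk"), 1)
  e1 <- bout_ethogram(c("h", "f", "h", "f", "wk"), rep(1, 5))
  counts <- count_transitions(e1, sp)
  expect_equal(counts$counts["h", "f"], 2L)
  expect_equal(counts$counts["f", "h"], 1L)
  expect_equal(counts$counts["f", "wk"], 1L)
  expect_equal(counts$n_total, 4L)

  e2 <- bout_ethogram(c("h", "f"), c(1, 1))
  e3 <- bout_ethogram(c("f", "h"), c(1, 1))
  pooled <- count_transitions(list(e2, e3), sp)
  expect_equal(pooled$counts["h", "f"], 1L)
  expect_equal(pooled$counts["f", "h"], 1L)
  expect_equal(pooled$n_total, 2L)  # no cross-fly f -> f or h -> f pair
})

test_that("MLE normalizes rows and flags unsupported rows", {
  sp <- build_state_space(c("f", "h", "wk"), 1)
  counts <- count_transitions(bout_ethogram(c("h", "f", "h", "f", "wk"), rep(1, 5)), sp)
  M <- mle_transition_matrix(counts)
  expect_equal(M$probs["f", "h"], 0.5)
  expect_equal(M$probs["f", "wk"], 0.5)
  expect_equal(M$probs["h", "f"], 1)
  expect_false(M$row_support["wk" == sp$states$label][1])
  expect_true(all(M$probs[3, ] == 0))  # zero-count row is all-zero, not NaN
  expect_valid_matrix(M)
})

test_that("log-likelihood sums per-fly log transition probabilities", {
  sp <- build_state_space(c("f", "h"), 1)
  M <- transition_matrix(matrix(c(0, 1, 1, 0), 2, 2), sp)
  expect_equal(log_likelihood(bout_ethogram(c("h", "f", "h"), rep(1, 3)), M), 0)

  counts <- count_transitions(bout_ethogram(c("h", "f", "h", "f", "wk"), rep(1, 5)),
                              build_state_space(c("f", "h", "wk"), 1))
  Mh <- mle_transition_matrix(counts)
  e <- bout_ethogram(c("f", "h"), c(1, 1))
  expect_equal(log_likelihood(e, Mh), log(0.5))

  # additivity: cohort likelihood equals sum of per-fly likelihoods
  toy <- make_matched_toy()$cohort
  sp2 <- make_matched_toy()$space
  Mt <- mle_transition_matrix(count_transitions(toy, sp2))
  expect_equal(log_likelihood(toy, Mt),
               sum(vapply(toy, log_likelihood, 0, M = Mt)))

  # zero-probability observed transition reports -Inf with diagnostics
  Mz <- transition_matrix(matrix(c(0, 1, 1, 0), 2, 2), sp)
  bad <- bout_ethogram(c("h", "wk"), c(1, 1))
  sp3 <- build_state_space(c("f", "h", "wk"), 1)
  Mz3 <- transition_matrix(rbind(c(0, 1, 0), c(1, 0, 0), c(1, 0, 0)), sp3)
  ll <- log_likelihood(bad, Mz3)
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "zero_transitions"), "h -> wk")
})

test_that("free-parameter counts follow both conventions", {
  sp18 <- build_state_space(grooming_actions(), 3)
  allowed <- outer(sp18$states$action, sp18$states$action, "!=")
  M <- transition_matrix(allowed / rowSums(allowed), sp18)
  expect_equal(count_free_parameters(M, "structural"), 18 * (18 - 3) - 18)

  sp6 <- build_state_space(grooming_actions(), 1)
  probs6 <- matrix(1 / 5, 6, 6)
  diag(probs6) <- 0
  M6 <- transition_matrix(probs6, sp6)
  expect_equal(count_free_parameters(M6, "structural"), 6 * 5 - 6)
  expect_equal(count_free_parameters(M6, "observed"), 30 - 6)

  # an unsupported row loses its allowance
  probs6[2, ] <- 0
  M6u <- transition_matrix(probs6, sp6)
  expect_equal(count_free_parameters(M6u, "structural"), 5 * 4)
})

test_that("BIC follows the arithmetic identity and propagates -Inf", {
  toy <- make_matched_toy()
  M <- mle_transition_matrix(count_transitions(toy$cohort, toy$space))
  sc <- bic_score(toy$cohort, M)
  expect_equal(sc$bic, log(sc$n) * sc$k - 2 * sc$log_likelihood)
  # spot-check the formula: n = 100, k = 10, logL = -200
  expect_equal(log(100) * 10 - 2 * (-200), 446.0517019, tolerance = 1e-9)
  sc2 <- bic_score(toy$cohort, M, k = 10)
  expect_equal(sc2$bic, log(sc2$n) * 10 - 2 * sc2$log_likelihood)
})

test_that("phase splitting implements every rule", {
  e <- bout_ethogram(valid_order(rep(c("h", "f"), 5)), rep(1, 10))
  part <- split_phases(e, "half-bouts-average")
  expect_equal(part$boundary * 60, 5)  # ten 1-second bouts: half after 5 s
  expect_equal(sum(vapply(part$early, function(x) x$total_time, 0)) +
               sum(vapply(part$late, function(x) x$total_time, 0)),
               e$total_time)

  big <- bout_ethogram(rep(c("h", "f"), 500), rep(1, 1000))
  part2 <- split_phases(big, "edge-bouts", n_bouts = 200)
  expect_equal(nrow(part2$early[[1]]$bouts), 200)
  expect_equal(nrow(part2$late[[1]]$bouts), 200)
  expect_equal(part2$early[[1]]$bouts$action, big$bouts$action[1:200])
  expect_equal(part2$late[[1]]$bouts$action, big$bouts$action[801:1000])

  part3 <- split_phases(big, "thirds")
  expect_equal(nrow(part3$early[[1]]$bouts), 333)
  expect_equal(nrow(part3$late[[1]]$bouts), 333)

  part4 <- split_phases(big, "fixed-time", boundary = 5)
  expect_equal(nrow(part4$early[[1]]$bouts), 300)  # bouts starting before 300 s
  w <- capture_warnings(split_phases(bout_ethogram(c("h", "f"), c(1, 1)),
                                     "edge-bouts", n_bouts = 200))
  expect_match(w, "fewer", all = FALSE)
})

test_that("matrix comparison counts sub-threshold residuals", {
  toy <- make_matched_toy()
  M <- mle_transition_matrix(count_transitions(toy$cohort, toy$space))
  cmp <- compare_matrices(M, M, thresholds = c(0.01, 0.05))
  expect_true(all(cmp$below$fraction == 1))

  sp <- build_state_space(c("f", "h"), 2)
  p1 <- matrix(0, 4, 4)
  p1[1, 3:4] <- c(0.5, 0.5); p1[2, 3:4] <- c(0.5, 0.5)
  p1[3, 1:2] <- c(0.5, 0.5); p1[4, 1:2] <- c(0.5, 0.5)
  p2 <- p1
  p2[1, 3:4] <- c(0.56, 0.44)
  M1 <- transition_matrix(p1, sp)
  M2 <- transition_matrix(p2, sp)
  cmp2 <- compare_matrices(M1, M2, thresholds = c(0.05, 0.10))
  expect_equal(cmp2$below$count, c(6, 8))
  expect_equal(cmp2$n_nonzero, 8)
})

test_that("MLE recovery error shrinks at the root-n rate", {
  spec <- ground_truth_spec(n_flies = 1, drift = NULL, seed = 31)
  mrp <- make_ground_truth_mrp(spec)
  truth <- mrp$M_late$probs
  errs <- vapply(c(1e3, 1e4, 1e5), function(N) {
    sim <- simulate_ethogram(mrp, total_time = N * 1.5 / 60, seed = 31 + N)
    M <- mle_transition_matrix(count_transitions(sim$ethogram, mrp$space))
    max(abs(M$probs[M$row_support, ] - truth[M$row_support, ]))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[3], 3)  # ~sqrt(100) in expectation, loosely bounded
})
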