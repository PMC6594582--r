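two_state_cycle <- function() {
  sp <- build_state_space(c("f", "h"), 1)
  M <- transition_matrix(matrix(c(0, 1, 1, 0), 2, 2), sp)
  mrp_model(M, M,
            duration_sampler = list(f = ethosyntax:::empirical_sampler(1),
                                    h = ethosyntax:::empirical_sampler(1)),
            initial_distribution = c(1, 0), t_switch = 13)
}

test_that("M(t) interpolates linearly with exact endpoints", {
  spec <- ground_truth_spec(n_flies = 1, seed = 2)
  mrp <- make_ground_truth_mrp(spec)
  expect_equal(interpolate_transition_matrix(mrp, 0)$probs, mrp$M_early$probs)
  expect_equal(interpolate_transition_matrix(mrp, 20)$probs, mrp$M_late$probs)
  mid <- interpolate_transition_matrix(mrp, mrp$t_switch / 2)
  expect_equal(mid$probs, (mrp$M_early$probs + mrp$M_late$probs) / 2)
  expect_error(interpolate_transition_matrix(mrp, -1), "non-negative")

  # convexity and row-stochasticity across the interpolation range
  lo <- pmin(mrp$M_early$probs, mrp$M_late$probs)
  hi <- pmax(mrp$M_early$probs, mrp$M_late$probs)
  for (t in c(1, 4.3, 9, 12.99, 13, 15)) {
    Mt <- interpolate_transition_matrix(mrp, t)
    expect_true(all(Mt$probs >= lo - 1e-12 & Mt$probs <= hi + 1e-12))
    expect_valid_matrix(Mt)
  }
})

test_that("a deterministic cycle simulates exactly", {
  model <- two_state_cycle()
  sim <- simulate_ethogram(model, total_time = 10 / 60, seed = 4)
  expect_equal(nrow(sim$ethogram$bouts), 10)
  expect_equal(sim$ethogram$bouts$action, rep(c("f", "h"), 5))
  expect_equal(sim$ethogram$bouts$duration, rep(1, 10))
  expect_equal(sim$ethogram$total_time, 10)
})

test_that("simulation is reproducible under seed and conserves time", {
  spec <- ground_truth_spec(n_flies = 1, seed = 2)
  mrp <- make_ground_truth_mrp(spec)
  s1 <- simulate_ethogram(mrp, total_time = 3, seed = 99)
  s2 <- simulate_ethogram(mrp, total_time = 3, seed = 99)
  expect_identical(s1$ethogram$bouts, s2$ethogram$bouts)
  expect_equal(s1$ethogram$total_time, 180)
  expect_equal(s1$transition_times[1], 0)
  expect_equal(diff(s1$transition_times),
               s1$ethogram$bouts$duration[-nrow(s1$ethogram$bouts)] / 60)
})

test_that("simulation aborts informatively at an absorbing state", {
  sp <- build_state_space(c("f", "h", "wk"), 1)
  p <- matrix(0, 3, 3)
  p[1, 3] <- 1   # f -> wk
  p[2, 1] <- 1   # h -> f
  # wk row unsupported: absorbing
  M <- transition_matrix(p, sp)
  model <- mrp_model(M, M,
                     duration_sampler = list(f = ethosyntax:::empirical_sampler(1),
                                             h = ethosyntax:::empirical_sampler(1),
                                             wk = ethosyntax:::empirical_sampler(1)),
                     initial_distribution = c(0, 1, 0))
  expect_error(simulate_ethogram(model, total_time = 1, seed = 1),
               "absorbing state 'wk'")
})

test_that("MRP fitting recovers stationary structure and duration pools", {
  spec <- ground_truth_spec(n_flies = 10, drift = NULL, seed = 17)
  cohort <- generate_cohort(spec)
  mrp <- suppressWarnings(
    build_mrp_from_cohort(cohort$bouts, cohort$mrp$space, n_edge_bouts = 600))
  # a stationary cohort's early and late matrices agree within sampling error:
  # compare noise-robust summaries rather than the max over sparse entries
  diff <- abs(mrp$M_early$probs - mrp$M_late$probs)
  allowed <- outer(mrp$space$states$action, mrp$space$states$action, "!=")
  expect_lt(mean(diff[allowed]), 0.03)
  st <- mrp$space$states
  ant <- st$action %in% anterior_actions()
  expect_lt(max(abs(rowSums(mrp$M_early$probs[ant, ant]) -
                    rowSums(mrp$M_late$probs[ant, ant]))), 0.06)

  # resampling a state's sampler reproduces its empirical duration pool
  lab <- "h.l"
  pool <- mrp$duration_sampler[[lab]]$pool
  withr::with_seed(5, draws <- ethosyntax:::draw_duration(mrp$duration_sampler[[lab]], 10000))
  expect_true(all(draws %in% pool))
  qs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(unname(stats::quantile(draws, qs)),
               unname(stats::quantile(pool, qs)), tolerance = 0.05)

  # initial distribution is the empirical first-bout frequency
  first <- vapply(cohort$bouts, function(e)
    paste(e$bouts$action[1], c("s", "m", "l")[e$bouts$category[1] + 1], sep = "."), "")
  emp <- as.numeric(table(factor(first, cohort$mrp$space$states$label))) / length(first)
  expect_equal(mrp$initial_distribution, emp)
})

test_that("MRP JSON serialization round-trips and reproduces simulations", {
  spec <- ground_truth_spec(n_flies = 1, seed = 2)
  mrp <- make_ground_truth_mrp(spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_mrp_model(mrp, path)
  back <- read_mrp_model(path)
  expect_equal(back$M_early$probs, mrp$M_early$probs)
  expect_equal(back$t_switch, mrp$t_switch)
  s1 <- simulate_ethogram(mrp, total_time = 2, seed = 12)
  s2 <- simulate_ethogram(back, total_time = 2, seed = 12)
  expect_equal(s1$ethogram$bouts, s2$ethogram$bouts)
})
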