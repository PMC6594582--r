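# Duration samplers: each state owns a sampler over bout durations (seconds).
# Two kinds: an empirical pool (resampling observed durations, the default
# when fitting from data) and a truncated log-normal (used by the synthetic
# ground-truth generator).

empirical_sampler <- function(pool) {
  pool <- as.numeric(pool)
  stopifnot(length(pool) >= 1L, all(pool > 0))
  list(kind = "empirical", pool = pool)
}

lnorm_sampler <- function(meanlog, sdlog, lower = 0, upper = Inf) {
  meanlog <- unname(as.numeric(meanlog))
  sdlog <- unname(as.numeric(sdlog))
  lower <- unname(as.numeric(lower))
  upper <- unname(as.numeric(upper))
  stopifnot(sdlog > 0, lower >= 0, upper > lower)
  list(kind = "lnorm", meanlog = meanlog, sdlog = sdlog,
       lower = lower, upper = upper)
}

draw_duration <- function(sampler, n = 1L) {
  if (sampler$kind == "empirical") {
    sampler$pool[sample.int(length(sampler$pool), n, replace = TRUE)]
  } else {
    plo <- stats::plnorm(sampler$lower, sampler$meanlog, sampler$sdlog)
    phi <- stats::plnorm(sampler$upper, sampler$meanlog, sampler$sdlog)
    stats::qlnorm(stats::runif(n, plo, phi), sampler$meanlog, sampler$sdlog)
  }
}

sampler_quantile <- function(sampler, p) {
  if (sampler$kind == "empirical") {
    as.numeric(stats::quantile(sampler$pool, p, type = 7))
  } else {
    plo <- stats::plnorm(sampler$lower, sampler$meanlog, sampler$sdlog)
    phi <- stats::plnorm(sampler$upper, sampler$meanlog, sampler$sdlog)
    stats::qlnorm(plo + p * (phi - plo), sampler$meanlog, sampler$sdlog)
  }
}

#' Nonstationary Markov renewal process model
#'
#' The generative model for grooming ethograms: state transitions follow a
#' time-varying Markov matrix M(t), a convex combination of an early and a
#' late transition matrix up to `t_switch` minutes and the late matrix
#' thereafter; bout durations are drawn from per-state duration samplers
#' (renewal process). Duration distributions do not change over time, because
#' early- and late-phase bout durations are statistically indistinguishable
#' in the data this model emulates.
#'
#' @param M_early,M_late [transition_matrix()] objects on one state space.
#' @param duration_sampler Named list (by state label) of duration samplers;
#'   fit one with [build_mrp_from_cohort()].
#' @param initial_distribution Length-v probability vector over states.
#' @param t_switch Interpolation horizon in minutes (default 13).
#' @return An object of class `mrp_model`.
#' @export
mrp_model <- function(M_early, M_late, duration_sampler, initial_distribution,
                      t_switch = 13) {
  stopifnot(inherits(M_early, "transition_matrix"),
            inherits(M_late, "transition_matrix"))
  if (!same_space(M_early$space, M_late$space))
    stop("M_early and M_late must share one state space")
  if (t_switch <= 0) stop("t_switch must be positive (minutes)")
  space <- M_early$space
  p0 <- as.numeric(initial_distribution)
  if (length(p0) != space$v || any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("initial_distribution must be a length-v probability vector")
  reachable <- p0 > 0 | colSums(M_early$probs) > 0 | colSums(M_late$probs) > 0
  lab <- space$states$label
  missing <- lab[reachable][!(lab[reachable] %in% names(duration_sampler))]
  if (length(missing) > 0L)
    stop("reachable states lack duration samplers: ",
         paste(missing, collapse = ", "))
  structure(list(space = space, M_early = M_early, M_late = M_late,
                 t_switch = as.numeric(t_switch),
                 duration_sampler = duration_sampler,
                 initial_distribution = p0),
            class = "mrp_model")
}

#' @export
print.mrp_model <- function(x, ...) {
  cat(sprintf("<mrp_model> %d states, t_switch = %g min\n",
              x$space$v, x$t_switch))
  invisible(x)
}

#' Time-varying transition matrix M(t)
#'
#' For `t <= t_switch`: the convex combination
#' `((t_switch - t)/t_switch) * M_early + (t/t_switch) * M_late`;
#' for `t > t_switch`: `M_late`. `t` is in minutes. Rows supported in only
#' one endpoint matrix take that endpoint's row, so the result stays
#' row-stochastic.
#'
#' @param model An [mrp_model()].
#' @param t Elapsed time in minutes (>= 0).
#' @return A [transition_matrix()].
#' @export
interpolate_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "mrp_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be a single non-negative time in minutes")
  if (t > model$t_switch) return(model$M_late)
  w <- (model$t_switch - t) / model$t_switch
  probs <- w * model$M_early$probs + (1 - w) * model$M_late$probs
  se <- model$M_early$row_support
  sl <- model$M_late$row_support
  only_e <- se & !sl
  only_l <- sl & !se
  probs[only_e, ] <- model$M_early$probs[only_e, , drop = FALSE]
  probs[only_l, ] <- model$M_late$probs[only_l, , drop = FALSE]
  transition_matrix(probs, model$space, row_support = se | sl)
}

#' Fit an MRP model to a cohort
#'
#' Fits the early matrix to the pooled first `n_edge_bouts` bouts of each fly
#' and the late matrix to the pooled last `n_edge_bouts` (flies with fewer
#' bouts contribute what they have, with a warning). Duration samplers pool
#' each state's observed durations across the whole recording; the initial
#' distribution is the empirical first-bout state frequency.
#'
#' @param cohort Binned [bout_ethogram()] or list of them.
#' @param space A [build_state_space()].
#' @param n_edge_bouts Bouts per fly per edge (default 200).
#' @param t_switch Interpolation horizon in minutes (default 13).
#' @return An [mrp_model()].
#' @export
build_mrp_from_cohort <- function(cohort, space, n_edge_bouts = 200L,
                                  t_switch = 13) {
  cohort <- as_cohort(cohort)
  if (length(cohort) == 0L) stop("empty cohort")
  part <- split_phases(cohort, "edge-bouts", n_bouts = n_edge_bouts)
  M_early <- mle_transition_matrix(count_transitions(part$early, space))
  M_late <- mle_transition_matrix(count_transitions(part$late, space))
  all_bouts <- do.call(rbind, lapply(cohort, function(e) e$bouts))
  idx <- state_index(space, all_bouts$action, all_bouts$category)
  lab <- space$states$label
  samplers <- list()
  for (s in seq_len(space$v)) {
    pool <- all_bouts$duration[idx == s]
    if (length(pool) > 0L) samplers[[lab[s]]] <- empirical_sampler(pool)
  }
  first_idx <- vapply(cohort, function(e)
    state_index(space, e$bouts$action[1L], e$bouts$category[1L]), 0L)
  p0 <- tabulate(first_idx, nbins = space$v) / length(first_idx)
  mrp_model(M_early, M_late, samplers, p0, t_switch = t_switch)
}

#' Simulate a synthetic ethogram from an MRP model
#'
#' Draws an initial state from the model's initial distribution, then
#' alternates renewal draws (a bout duration from the current state's
#' sampler) with Markov draws (the next state from the row of M(t) at the
#' elapsed time when the transition is made, i.e. the start of the new bout).
#' The final bout is truncated so the total simulated time equals
#' `total_time` exactly. Fully reproducible given `seed`.
#'
#' @param model An [mrp_model()].
#' @param total_time Simulated recording length in minutes (default 27.8).
#' @param seed Integer seed.
#' @param fly_id Optional identifier for the simulated fly.
#' @return An object of class `simulated_ethogram`: list with `ethogram`
#'   (a binned [bout_ethogram()]), `states` (1-based state indices) and
#'   `transition_times` (bout start times, minutes).
#' @export
simulate_ethogram <- function(model, total_time = 27.8, seed = 1L,
                              fly_id = NULL) {
  stopifnot(inherits(model, "mrp_model"))
  if (total_time <= 0) stop("total_time must be positive (minutes)")
  space <- model$space
  v <- space$v
  lab <- space$states$label
  stationary <- isTRUE(all.equal(model$M_early$probs, model$M_late$probs,
                                 tolerance = 1e-12))
  cum_early <- t(apply(model$M_early$probs, 1L, cumsum))
  cum_late <- t(apply(model$M_late$probs, 1L, cumsum))
  support <- model$M_early$row_support | model$M_late$row_support
  # cache truncation quantiles so the hot loop avoids repeated plnorm calls
  samplers <- lapply(model$duration_sampler, function(sm) {
    if (sm$kind == "lnorm") {
      sm$plo <- stats::plnorm(sm$lower, sm$meanlog, sm$sdlog)
      sm$phi <- stats::plnorm(sm$upper, sm$meanlog, sm$sdlog)
    }
    sm
  })
  draw1 <- function(sm) {
    if (sm$kind == "empirical") sm$pool[sample.int(length(sm$pool), 1L)]
    else stats::qlnorm(stats::runif(1, sm$plo, sm$phi), sm$meanlog, sm$sdlog)
  }
  total_sec <- total_time * 60
  cap <- 1024L
  states <- integer(cap)
  durs <- numeric(cap)
  withr::with_seed(as.integer(seed), {
    s <- sample.int(v, 1L, prob = model$initial_distribution)
    t_sec <- 0
    k <- 0L
    repeat {
      d <- draw1(samplers[[lab[s]]])
      k <- k + 1L
      if (k > cap) {
        cap <- cap * 2L
        length(states) <- cap
        length(durs) <- cap
      }
      states[k] <- s
      if (t_sec + d >= total_sec) {
        durs[k] <- total_sec - t_sec
        break
      }
      durs[k] <- d
      t_sec <- t_sec + d
      if (!support[s])
        stop(sprintf("absorbing state '%s' reached at %.2f min", lab[s], t_sec / 60))
      u <- stats::runif(1)
      if (stationary || t_sec / 60 > model$t_switch) {
        s <- findInterval(u, cum_late[s, ], left.open = TRUE) + 1L
      } else {
        w <- (model$t_switch - t_sec / 60) / model$t_switch
        row <- w * model$M_early$probs[s, ] + (1 - w) * model$M_late$probs[s, ]
        if (model$M_early$row_support[s] && !model$M_late$row_support[s])
          row <- model$M_early$probs[s, ]
        if (!model$M_early$row_support[s] && model$M_late$row_support[s])
          row <- model$M_late$probs[s, ]
        s <- findInterval(u, cumsum(row), left.open = TRUE) + 1L
      }
      if (s > v) s <- v  # cumulative sum fp guard
    }
  })
  states <- states[seq_len(k)]
  durs <- durs[seq_len(k)]
  if (durs[k] <= 0) {  # final bout truncated to nothing
    states <- states[-k]
    durs <- durs[-k]
    k <- k - 1L
  }
  etho <- bout_ethogram(space$states$action[states], durs,
                        space$states$category[states],
                        frame_rate = NA_real_, fly_id = fly_id)
  structure(list(ethogram = etho,
                 states = states,
                 transition_times = cumsum(c(0, durs[-k])) / 60),
            class = "simulated_ethogram")
}

#' Serialize / read an MRP model as JSON
#'
#' @param model An [mrp_model()].
#' @param path File path.
#' @return `read_mrp_model` returns the [mrp_model()].
#' @export
write_mrp_model <- function(model, path) {
  x <- list(
    actions = model$space$actions,
    n_bins = model$space$n_bins,
    t_switch = model$t_switch,
    M_early = as.data.frame(model$M_early$probs),
    M_late = as.data.frame(model$M_late$probs),
    initial_distribution = model$initial_distribution,
    duration_sampler = lapply(model$duration_sampler, function(s) {
      # JSON has no Inf; serialize unbounded uppers as the string "Inf"
      if (s$kind == "lnorm" && is.infinite(s$upper)) s$upper <- "Inf"
      s
    }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mrp_model
#' @export
read_mrp_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- build_state_space(x$actions, x$n_bins)
  Me <- transition_matrix(as.matrix(x$M_early), space)
  Ml <- transition_matrix(as.matrix(x$M_late), space)
  samplers <- lapply(x$duration_sampler, function(s) {
    if (s$kind == "empirical") empirical_sampler(s$pool)
    else lnorm_sampler(s$meanlog, s$sdlog, s$lower, as.numeric(s$upper))
  })
  mrp_model(Me, Ml, samplers, as.numeric(x$initial_distribution),
            t_switch = x$t_switch)
}
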