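#' Marginal statistics of a binned cohort
#'
#' Extracts the three ingredients of the analytic permutation nulls:
#' the duration-marginalized action-level transition matrix P(action_j |
#' action_i), the per-action duration-category distributions P(cat | action),
#' and the state marginal P(state) over bouts.
#'
#' @param cohort Binned [bout_ethogram()] or list of them.
#' @param space A [build_state_space()].
#' @return An object of class `marginal_statistics`: list with
#'   `action_transition` (n_actions x n_actions, rows summing to 1, zero
#'   diagonal), `duration_given_action` (named list of probability vectors),
#'   `state_marginal` (length-v probability vector) and `space`.
#' @export
marginal_statistics <- function(cohort, space) {
  stopifnot(inherits(space, "state_space"))
  cohort <- as_cohort(cohort)
  acts <- space$actions
  na <- length(acts)

  all_bouts <- do.call(rbind, lapply(cohort, function(e) e$bouts))
  missing <- setdiff(acts, unique(all_bouts$action))
  if (length(missing) > 0L)
    warning("actions with zero bouts excluded from marginals: ",
            paste(missing, collapse = ", "))

  # action-level transitions (per fly, pooled)
  at <- matrix(0, na, na, dimnames = list(acts, acts))
  for (e in cohort) {
    aidx <- match(e$bouts$action, acts)
    if (anyNA(aidx)) stop("cohort contains actions outside the state space")
    n <- length(aidx)
    if (n < 2L) next
    at <- at + matrix(tabulate(aidx[-n] + (aidx[-1L] - 1L) * na, nbins = na * na), na, na)
  }
  rs <- rowSums(at)
  at <- at / ifelse(rs > 0, rs, 1)

  # per-action duration-category distributions over bouts
  dga <- lapply(acts, function(a) {
    sel <- all_bouts$action == a
    if (!any(sel)) return(rep(NA_real_, space$n_bins))
    cats <- if (space$n_bins == 1L) rep(0L, sum(sel)) else all_bouts$category[sel]
    if (anyNA(cats)) stop(sprintf("unbinned bouts of action '%s'", a))
    as.numeric(tabulate(cats + 1L, nbins = space$n_bins) / sum(sel))
  })
  names(dga) <- acts

  # state marginal over bouts
  idx <- state_index(space, all_bouts$action, all_bouts$category)
  sm <- tabulate(idx, nbins = space$v) / length(idx)

  structure(list(action_transition = at, duration_given_action = dga,
                 state_marginal = sm, space = space),
            class = "marginal_statistics")
}

#' Analytic duration-permuted null transition matrix
#'
#' Preserves action-order statistics while making duration categories
#' independent of history: the entry from (action i, cat c) to (action j,
#' cat d) is P(action j | action i) * P(cat d | action j). In the limit of
#' infinitely many within-action permutations of duration labels, the
#' Monte-Carlo null converges to this matrix. All rows of a given action are
#' identical, and the action-level block mass equals the MLE's.
#'
#' @param stats A [marginal_statistics()] result.
#' @param space The state space (defaults to the one in `stats`).
#' @return A [transition_matrix()].
#' @export
duration_permuted_null <- function(stats, space = stats$space) {
  stopifnot(inherits(stats, "marginal_statistics"))
  v <- space$v
  st <- space$states
  probs <- matrix(0, v, v)
  ai <- match(st$action, space$actions)
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (st$action[i] == st$action[j]) next
      pa <- stats$action_transition[ai[i], ai[j]]
      pd <- stats$duration_given_action[[st$action[j]]][st$category[j] + 1L]
      probs[i, j] <- pa * pd
    }
  }
  rs <- rowSums(probs)
  support <- rs > 1e-15
  probs <- probs / ifelse(support, rs, 1)  # exact renorm against fp drift
  transition_matrix(probs, space, row_support = support)
}

#' Analytic order-permuted null transition matrix
#'
#' Preserves bout-state marginals while destroying sequential order: every
#' row's entries are proportional to the state marginal P(state j). Because
#' discretization forbids same-action adjacency, same-action columns are
#' zeroed and rows renormalized when `renormalize_self = TRUE` (the default),
#' giving entry m_j / (m - m_{A(i)}) in bout-count terms. With
#' `renormalize_self = FALSE` the same-action columns are zeroed but rows are
#' left unnormalized (their sums fall short of 1 by the own-action marginal
#' mass); this variant is exposed for comparison only and does not satisfy the
#' row-stochastic contract, so it is returned as a plain matrix.
#'
#' @param stats A [marginal_statistics()] result.
#' @param space The state space (defaults to the one in `stats`).
#' @param renormalize_self Renormalize rows after zeroing same-action columns.
#' @return A [transition_matrix()] (or a plain matrix when
#'   `renormalize_self = FALSE`).
#' @export
order_permuted_null <- function(stats, space = stats$space,
                                renormalize_self = TRUE) {
  stopifnot(inherits(stats, "marginal_statistics"))
  v <- space$v
  st <- space$states
  probs <- matrix(rep(stats$state_marginal, each = v), v, v)
  probs[!allowed_mask(space)] <- 0
  if (!renormalize_self) {
    dimnames(probs) <- list(st$label, st$label)
    return(probs)
  }
  rs <- rowSums(probs)
  support <- rs > 1e-15
  probs <- probs / ifelse(support, rs, 1)
  transition_matrix(probs, space, row_support = support)
}

# permute duration-category labels within each action of one fly
permute_durations <- function(etho) {
  df <- etho$bouts
  for (a in unique(df$action)) {
    sel <- which(df$action == a)
    if (length(sel) > 1L) {
      perm <- sample(length(sel))
      df$category[sel] <- df$category[sel][perm]
      df$duration[sel] <- df$duration[sel][perm]  # durations ride with labels
    }
  }
  df
}

#' Monte-Carlo permutation null transition matrices
#'
#' Estimates a null transition matrix by repeatedly permuting each fly's
#' ethogram and refitting the MLE. `kind = "duration"` permutes duration
#' labels (with their durations) among each action's bouts, within fly,
#' preserving bout order. `kind = "order"` permutes bout order within fly
#' (durations ride with their bouts); since a shuffle can place same-action
#' bouts adjacently, which discretization forbids, such pairs are skipped when
#' counting transitions -- the convention under which the Monte-Carlo mean
#' converges to the analytic [order_permuted_null()] with
#' `renormalize_self = TRUE`.
#'
#' @param cohort Binned [bout_ethogram()] or list of them.
#' @param space A [build_state_space()].
#' @param kind `"duration"` or `"order"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return List with `mean` (a [transition_matrix()] whose rows are
#'   renormalized means over permutations), `se` (elementwise standard error
#'   matrix), and a `provenance` record `{kind, n_perm, seed}`.
#' @export
monte_carlo_null <- function(cohort, space, kind = c("duration", "order"),
                             n_perm = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_perm >= 1L)
  cohort <- as_cohort(cohort)
  v <- space$v
  acc <- matrix(0, v, v)
  acc2 <- matrix(0, v, v)
  nsup <- matrix(0, v, v)  # permutations in which the row was supported
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      counts <- matrix(0, v, v)
      for (e in cohort) {
        df <- e$bouts
        n <- nrow(df)
        if (n < 2L) next
        if (kind == "duration") {
          df <- permute_durations(e)
          idx <- state_index(space, df$action, df$category)
          keep <- rep(TRUE, n - 1L)
        } else {
          ord <- sample(n)
          df <- df[ord, , drop = FALSE]
          idx <- state_index(space, df$action, df$category)
          keep <- df$action[-n] != df$action[-1L]  # skip same-action pairs
        }
        from <- idx[-n][keep]
        to <- idx[-1L][keep]
        counts <- counts + matrix(tabulate(from + (to - 1L) * v, nbins = v * v), v, v)
      }
      rs <- rowSums(counts)
      sup <- rs > 0
      m <- counts / ifelse(sup, rs, 1)
      acc <- acc + m
      acc2 <- acc2 + m * m
      nsup <- nsup + matrix(sup, v, v)
    }
  })
  nsup[nsup == 0] <- NA
  mean_m <- acc / nsup
  var_m <- pmax(acc2 / nsup - mean_m^2, 0)
  se <- sqrt(var_m / nsup)
  mean_m[is.na(mean_m)] <- 0
  rs <- rowSums(mean_m)
  support <- rs > 1e-15
  probs <- mean_m / ifelse(support, rs, 1)
  se[is.na(se)] <- 0
  dimnames(se) <- list(space$states$label, space$states$label)
  list(mean = transition_matrix(probs, space, row_support = support),
       raw_mean = mean_m, se = se,
       provenance = list(kind = kind, n_perm = as.integer(n_perm),
                         seed = as.integer(seed)))
}
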