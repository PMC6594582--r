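#' Construct a transition matrix object
#'
#' Internal-facing constructor used by the fitting and null-model routines;
#' validates row-stochasticity on supported rows and the zero same-action
#' block structure imposed by discretization (self-transitions are impossible
#' because consecutive bouts have distinct actions).
#'
#' @param probs v x v numeric matrix.
#' @param space The [build_state_space()] the matrix lives on.
#' @param row_support Logical vector: which rows had observations (unsupported
#'   rows are all-zero and excluded from likelihoods).
#' @return An object of class `transition_matrix` with fields `probs`,
#'   `space`, `row_support`.
#' @export
transition_matrix <- function(probs, space, row_support = NULL) {
  stopifnot(inherits(space, "state_space"))
  probs <- as.matrix(probs)
  if (!all(dim(probs) == space$v)) stop("matrix dimensions do not match state space")
  dimnames(probs) <- list(space$states$label, space$states$label)
  if (is.null(row_support)) row_support <- rowSums(probs) > 0
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]")
  rs <- rowSums(probs)
  if (any(abs(rs[row_support] - 1) > 1e-9))
    stop("supported rows must sum to 1")
  blocked <- !allowed_mask(space)
  if (any(abs(probs[blocked]) > 1e-12))
    stop("same-action block entries must be zero (self-transitions prohibited)")
  probs[blocked] <- 0
  structure(list(probs = probs, space = space, row_support = row_support),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d states, %d supported rows\n",
              x$space$v, sum(x$row_support)))
  invisible(x)
}

# per-fly (from, to) state-index pairs, never crossing fly boundaries
cohort_transitions <- function(cohort, space) {
  cohort <- as_cohort(cohort)
  pairs <- lapply(cohort, function(e) {
    stopifnot(inherits(e, "bout_ethogram"))
    idx <- state_index(space, e$bouts$action, e$bouts$category)
    n <- length(idx)
    if (n < 2L) return(NULL)
    cbind(from = idx[-n], to = idx[-1L])
  })
  do.call(rbind, pairs)
}

#' Count state transitions in a cohort
#'
#' Tallies consecutive-bout transitions, pooled across flies; transitions
#' never cross fly boundaries. Same-action entries are structurally zero.
#'
#' @param cohort A binned [bout_ethogram()] or list of them.
#' @param space A [build_state_space()].
#' @return An object of class `transition_counts`: list with `counts`
#'   (v x v integer matrix), `space` and `n_total`.
#' @export
count_transitions <- function(cohort, space) {
  stopifnot(inherits(space, "state_space"))
  tr <- cohort_transitions(cohort, space)
  counts <- matrix(0L, space$v, space$v,
                   dimnames = list(space$states$label, space$states$label))
  if (!is.null(tr)) {
    tab <- table(factor(tr[, "from"], levels = seq_len(space$v)),
                 factor(tr[, "to"], levels = seq_len(space$v)))
    counts <- matrix(as.integer(tab), space$v, space$v,
                     dimnames = dimnames(counts))
  }
  structure(list(counts = counts, space = space, n_total = sum(counts)),
            class = "transition_counts")
}

#' Maximum-likelihood transition matrix
#'
#' Row-normalizes transition counts: entry (i, j) is n_ij / sum_u n_iu, the
#' maximum-likelihood estimate of a first-order Markov chain's transition
#' probabilities. Rows with no observations are flagged unsupported and left
#' all-zero rather than NaN.
#'
#' @param counts A [count_transitions()] result.
#' @return A [transition_matrix()].
#' @export
mle_transition_matrix <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  rs <- rowSums(counts$counts)
  support <- rs > 0
  probs <- counts$counts / ifelse(rs > 0, rs, 1)
  transition_matrix(probs, counts$space, row_support = support)
}

#' Log-likelihood of a cohort under a transition matrix
#'
#' Sums log P(next state | current state) over all consecutive bout pairs,
#' per fly. An observed transition with zero model probability yields `-Inf`,
#' with the offending transitions attached as attribute `zero_transitions`.
#'
#' @param cohort Binned [bout_ethogram()] or list of them.
#' @param M A [transition_matrix()].
#' @return Log-likelihood in nats.
#' @export
log_likelihood <- function(cohort, M) {
  stopifnot(inherits(M, "transition_matrix"))
  tr <- cohort_transitions(cohort, M$space)
  if (is.null(tr)) return(0)
  p <- M$probs[tr]
  if (any(p == 0)) {
    bad <- tr[p == 0, , drop = FALSE]
    lab <- M$space$states$label
    out <- -Inf
    attr(out, "zero_transitions") <-
      unique(paste(lab[bad[, 1L]], lab[bad[, 2L]], sep = " -> "))
    return(out)
  }
  sum(log(p))
}

#' Count free parameters of a transition matrix
#'
#' Two conventions are supported. `structural` (default): each supported row
#' contributes its structurally allowed entries (v minus the same-action block
#' width, i.e. `v - n_bins`) minus one normalization constraint. `observed`:
#' the number of strictly positive entries minus the number of supported rows.
#' Unsupported rows contribute nothing under either convention.
#'
#' @param M A [transition_matrix()].
#' @param convention `"structural"` or `"observed"`.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(M, convention = c("structural", "observed")) {
  convention <- match.arg(convention)
  v <- M$space$v
  nb <- M$space$n_bins
  if (convention == "structural") {
    sum(M$row_support) * (v - nb - 1L)
  } else {
    sum(M$probs > 0) - sum(M$row_support)
  }
}

#' Free-parameter counts of the analytic null models
#'
#' The permutation nulls are parameterized by fewer quantities than a full
#' transition matrix: the duration-permuted null by an action-level transition
#' matrix plus per-action duration-category distributions, and the
#' order-permuted null by the state marginal alone.
#'
#' @param space A [build_state_space()].
#' @param kind `"duration"` or `"order"`.
#' @return Integer parameter count.
#' @export
null_free_parameters <- function(space, kind = c("duration", "order")) {
  kind <- match.arg(kind)
  na <- length(space$actions)
  if (kind == "duration") {
    na * (na - 1L) - na + na * (space$n_bins - 1L)
  } else {
    space$v - 1L
  }
}

#' BIC model score
#'
#' Computes `BIC = log(n) * k - 2 * logL` (natural log), where n is the
#' number of observed transitions in the cohort. Lower is better. The free
#' parameter count defaults to [count_free_parameters()] of the matrix, but
#' can be supplied explicitly (e.g. [null_free_parameters()] for null models).
#'
#' @param cohort Binned [bout_ethogram()] or list of them.
#' @param M A [transition_matrix()].
#' @param convention Parameter-count convention, see
#'   [count_free_parameters()].
#' @param k Optional explicit free-parameter count.
#' @return An object of class `model_score`: list with `log_likelihood`, `k`,
#'   `n`, `bic`, `convention`.
#' @export
bic_score <- function(cohort, M, convention = c("structural", "observed"),
                      k = NULL) {
  convention <- match.arg(convention)
  tr <- cohort_transitions(cohort, M$space)
  n <- if (is.null(tr)) 0L else nrow(tr)
  if (n < 1L) stop("BIC requires at least one observed transition")
  if (is.null(k)) k <- count_free_parameters(M, convention)
  ll <- log_likelihood(cohort, M)
  bic <- log(n) * k - 2 * as.numeric(ll)
  structure(list(log_likelihood = as.numeric(ll), k = k, n = n, bic = bic,
                 convention = convention),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> logL = %.2f, k = %d, n = %d, BIC = %.2f (%s)\n",
              x$log_likelihood, x$k, x$n, x$bic, x$convention))
  invisible(x)
}

#' Order candidate models by BIC
#'
#' @param scores A named list of `model_score` objects.
#' @return A data frame sorted by increasing BIC (best first).
#' @export
rank_models <- function(scores) {
  df <- data.frame(model = names(scores),
                   log_likelihood = vapply(scores, `[[`, 0, "log_likelihood"),
                   k = vapply(scores, function(s) as.numeric(s$k), 0),
                   n = vapply(scores, function(s) as.numeric(s$n), 0),
                   bic = vapply(scores, `[[`, 0, "bic"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$bic), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Split a cohort into early and late grooming phases
#'
#' Supported rules: `"half-bouts-average"` (per fly, the elapsed time at
#' which the bout count reaches half its total; averaged across flies and
#' applied as a fixed time), `"fixed-time"` (explicit boundary in minutes),
#' `"edge-bouts"` (first/last `n_bouts` bouts per fly, as used to fit the
#' renewal process's early and late matrices), and `"thirds"` (first and last
#' third of each fly's bouts, discarding the middle). A bout straddling a time
#' boundary is assigned whole to the phase containing its start.
#'
#' @param cohort [bout_ethogram()] or list of them.
#' @param rule Splitting rule.
#' @param boundary Boundary in minutes (required for `"fixed-time"`).
#' @param n_bouts Edge width for `"edge-bouts"` (default 200).
#' @return An object of class `phase_partition`: list with `early` and `late`
#'   cohorts, `boundary` (minutes, `NA` for bout-index rules) and `rule`.
#' @export
split_phases <- function(cohort,
                         rule = c("half-bouts-average", "fixed-time",
                                  "edge-bouts", "thirds"),
                         boundary = NULL, n_bouts = 200L) {
  rule <- match.arg(rule)
  cohort <- as_cohort(cohort)
  take <- function(e, idx) {
    df <- e$bouts[idx, , drop = FALSE]
    bout_ethogram(df$action, df$duration, df$category,
                  frame_rate = e$frame_rate, fly_id = e$fly_id)
  }
  if (rule %in% c("half-bouts-average", "fixed-time")) {
    if (rule == "half-bouts-average") {
      half_times <- vapply(cohort, function(e) {
        nb <- n_bouts(e)
        sum(e$bouts$duration[seq_len(floor(nb / 2))])
      }, 0)
      boundary <- mean(half_times) / 60
    } else if (is.null(boundary)) {
      stop("fixed-time rule requires a boundary in minutes")
    }
    bsec <- boundary * 60
    early <- lapply(cohort, function(e) {
      start <- cumsum(c(0, e$bouts$duration[-n_bouts(e)]))
      take(e, which(start < bsec))
    })
    late <- lapply(cohort, function(e) {
      start <- cumsum(c(0, e$bouts$duration[-n_bouts(e)]))
      take(e, which(start >= bsec))
    })
  } else if (rule == "edge-bouts") {
    early <- lapply(cohort, function(e) {
      nb <- n_bouts(e)
      if (nb < 2L * n_bouts)
        warning(sprintf("fly has %d bouts, fewer than 2 x %d; phases overlap-truncated",
                        nb, n_bouts))
      take(e, seq_len(min(n_bouts, nb)))
    })
    late <- lapply(cohort, function(e) {
      nb <- n_bouts(e)
      take(e, seq.int(max(1L, nb - min(n_bouts, nb) + 1L), nb))
    })
    boundary <- NA_real_
  } else { # thirds
    early <- lapply(cohort, function(e) take(e, seq_len(floor(n_bouts(e) / 3))))
    late <- lapply(cohort, function(e) {
      nb <- n_bouts(e)
      take(e, seq.int(nb - floor(nb / 3) + 1L, nb))
    })
    boundary <- NA_real_
  }
  structure(list(early = early, late = late, boundary = boundary, rule = rule),
            class = "phase_partition")
}

#' Elementwise comparison of two transition matrices
#'
#' Computes the residual matrix `M1 - M2` and, over entries that are non-zero
#' in both matrices, the counts and fractions changing by less than each
#' threshold (used to assess stationarity of grooming rules between early and
#' late phases).
#'
#' @param M1,M2 [transition_matrix()] objects on the same state space.
#' @param thresholds Probability deltas (default `c(0.01, 0.05)`).
#' @return List with `residuals` (matrix), `n_nonzero` (jointly non-zero
#'   entries) and `below`, a data frame of threshold/count/fraction rows.
#' @export
compare_matrices <- function(M1, M2, thresholds = c(0.01, 0.05)) {
  stopifnot(inherits(M1, "transition_matrix"), inherits(M2, "transition_matrix"))
  if (!same_space(M1$space, M2$space)) stop("matrices live on different state spaces")
  res <- M1$probs - M2$probs
  joint <- M1$probs > 0 & M2$probs > 0
  n_nz <- sum(joint)
  below <- data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(th) sum(abs(res[joint]) < th), 0),
    stringsAsFactors = FALSE)
  below$fraction <- if (n_nz > 0) below$count / n_nz else NA_real_
  list(residuals = res, n_nonzero = n_nz, below = below)
}
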