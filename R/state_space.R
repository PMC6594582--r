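#' Build an action-by-duration-category state space
#'
#' The Markov models operate over a product state space of behavior codes and
#' duration categories. With the six non-standing behaviors this gives 6, 12
#' or 18 states for 1, 2 or 3 duration bins. Ordering is deterministic:
#' actions in the given (canonical) order, categories ascending within each
#' action. State labels follow the `action.category` convention, e.g. `h.s`
#' is a short head-cleaning bout.
#'
#' @param actions Ordered, distinct behavior codes (default
#'   [grooming_actions()]).
#' @param n_bins Duration categories per action (default 1).
#' @return An object of class `state_space`: list with `actions`, `n_bins`,
#'   `v` (state count) and `states`, a data frame with columns `action`,
#'   `category` (0-based) and `label`.
#' @export
build_state_space <- function(actions = grooming_actions(), n_bins = 1L) {
  actions <- as.character(actions)
  n_bins <- as.integer(n_bins)
  if (length(actions) == 0L) stop("actions must be non-empty")
  if (anyDuplicated(actions)) stop("duplicate action codes in state space")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  cl <- category_labels(n_bins)
  states <- data.frame(
    action = rep(actions, each = n_bins),
    category = rep(seq_len(n_bins) - 1L, times = length(actions)),
    stringsAsFactors = FALSE)
  states$label <- if (n_bins == 1L) states$action else
    paste(states$action, cl[states$category + 1L], sep = ".")
  structure(list(actions = actions, n_bins = n_bins,
                 v = nrow(states), states = states),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> v = %d (%d actions x %d bins)\n",
              x$v, length(x$actions), x$n_bins))
  invisible(x)
}

# 1-based state index for vectors of actions/categories; errors on unknowns
state_index <- function(space, action, category) {
  ai <- match(action, space$actions)
  if (anyNA(ai)) {
    bad <- action[which(is.na(ai))[1L]]
    stop(sprintf("action '%s' is not in the state space", bad))
  }
  if (space$n_bins > 1L) {
    if (anyNA(category))
      stop("unbinned bout encountered in a multi-bin state space; run apply_binning() first")
    if (any(category < 0L | category >= space$n_bins))
      stop("duration category outside the state space's bins")
  } else {
    category <- rep(0L, length(ai))
  }
  (ai - 1L) * space$n_bins + category + 1L
}

same_space <- function(s1, s2) {
  identical(s1$actions, s2$actions) && identical(s1$n_bins, s2$n_bins)
}

# logical v x v mask of structurally allowed transitions (different actions)
allowed_mask <- function(space) {
  act <- space$states$action
  outer(act, act, FUN = "!=")
}
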