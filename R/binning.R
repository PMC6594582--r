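#' Fit a per-action equal-occupancy duration binning scheme
#'
#' Bout durations are collapsed into per-action categories (short/medium/long
#' for three bins). Bin edges are fit independently for each action because
#' each action has its own duration distribution; edges are placed so that the
#' categories hold equal numbers of the fitting corpus's bouts (within one,
#' when the sample size is not divisible by `n_bins`).
#'
#' Thresholds are midpoints between the bracketing order statistics. With
#' heavily tied samples exact balance can be impossible; the achieved
#' occupancy deviation per action is reported in the `occupancy_deviation`
#' attribute.
#'
#' @param cohort A [bout_ethogram()] or list of them (the fitting corpus).
#' @param n_bins Number of duration categories (>= 1; default 3).
#' @param actions Actions to fit edges for; defaults to every action present.
#' @return An object of class `binning_scheme`: list with `n_bins` and
#'   `edges`, a named list mapping action to its `n_bins - 1` increasing
#'   thresholds (seconds).
#' @export
fit_binning_scheme <- function(cohort, n_bins = 3L, actions = NULL) {
  cohort <- as_cohort(cohort)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  all_bouts <- do.call(rbind, lapply(cohort, function(e) e$bouts))
  if (is.null(actions)) actions <- unique(all_bouts$action)
  edges <- list()
  deviation <- numeric(0)
  for (a in actions) {
    d <- sort(all_bouts$duration[all_bouts$action == a])
    m <- length(d)
    if (m < n_bins)
      stop(sprintf("action '%s' has %d bouts, fewer than n_bins = %d", a, m, n_bins))
    if (n_bins == 1L) {
      edges[[a]] <- numeric(0)
      deviation[a] <- 0
      next
    }
    cut_at <- round(seq_len(n_bins - 1L) * m / n_bins)  # elements left of each edge
    e <- (d[cut_at] + d[cut_at + 1L]) / 2
    if (any(diff(e) <= 0) || any(e <= 0)) {
      # ties collapsed an edge; nudge to strictly increasing (best effort)
      e <- cummax(e + seq_along(e) * .Machine$double.eps * abs(e))
      if (any(diff(e) <= 0))
        stop(sprintf("cannot place strictly increasing edges for action '%s' (ties)", a))
    }
    counts <- tabulate(findInterval(d, e) + 1L, nbins = n_bins)
    deviation[a] <- max(counts) - min(counts)
    edges[[a]] <- e
  }
  structure(list(n_bins = n_bins, edges = edges),
            occupancy_deviation = deviation,
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %d bins, actions: %s\n", x$n_bins,
              paste(names(x$edges), collapse = ", ")))
  invisible(x)
}

#' Assign duration categories to bouts
#'
#' Annotates each bout with the 0-based index of the duration category whose
#' half-open interval `[low, high)` contains its duration: a duration exactly
#' equal to a threshold goes to the upper bin. Actions and durations are left
#' untouched.
#'
#' @param etho A [bout_ethogram()].
#' @param scheme A [fit_binning_scheme()] result.
#' @return The ethogram with its `category` column filled.
#' @export
apply_binning <- function(etho, scheme) {
  stopifnot(inherits(etho, "bout_ethogram"), inherits(scheme, "binning_scheme"))
  df <- etho$bouts
  cat <- integer(nrow(df))
  if (scheme$n_bins > 1L) {
    for (a in unique(df$action)) {
      if (is.null(scheme$edges[[a]]))
        stop(sprintf("action '%s' has no edges in the binning scheme", a))
      sel <- df$action == a
      # findInterval counts edges <= x, so x == edge lands in the upper bin
      cat[sel] <- findInterval(df$duration[sel], scheme$edges[[a]])
    }
  }
  bout_ethogram(df$action, df$duration, cat,
                frame_rate = etho$frame_rate, fly_id = etho$fly_id)
}

#' Serialize / read a binning scheme as JSON
#'
#' @param scheme A `binning_scheme`.
#' @param path File path.
#' @return `read_binning_scheme` returns the `binning_scheme`.
#' @export
write_binning_scheme <- function(scheme, path) {
  jsonlite::write_json(list(n_bins = scheme$n_bins, edges = scheme$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binning_scheme
#' @export
read_binning_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- lapply(x$edges, as.numeric)
  structure(list(n_bins = as.integer(x$n_bins), edges = edges),
            class = "binning_scheme")
}
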