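bout_class <- function(action) {
  ifelse(action %in% .ANTERIOR, "anterior",
         ifelse(action %in% .POSTERIOR, "posterior", "other"))
}

#' Sliding-window behavior proportions
#'
#' The long-time grooming progression: for each window center, the fraction
#' of window frames spent in each behavior. Windows are centered and
#' truncated at the record edges. Given a list of frame ethograms the per-fly
#' curves are averaged pointwise (records truncated to the shortest).
#'
#' @param frames A [frame_ethogram()] or list of them.
#' @param window Window width in frames (default 500, i.e. 16.7 s at 30 Hz).
#' @param stride Step between window centers in frames (default 1).
#' @return An object of class `progression_curve`: a data frame with a
#'   `time` column (window-center time, seconds) and one proportion column
#'   per behavior; attributes `window`, `stride`, `frame_rate`.
#' @export
sliding_window_proportions <- function(frames, window = 500L, stride = 1L) {
  if (!inherits(frames, "frame_ethogram")) {
    curves <- lapply(frames, sliding_window_proportions,
                     window = window, stride = stride)
    n <- min(vapply(curves, nrow, 0L))
    avg <- curves[[1L]][seq_len(n), , drop = FALSE]
    for (cn in setdiff(names(avg), "time")) {
      avg[[cn]] <- rowMeans(vapply(curves, function(cv) cv[[cn]][seq_len(n)],
                                   numeric(n)))
    }
    return(avg)
  }
  n <- length(frames$labels)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (window < 1L || window > n)
    stop("window must be between 1 and the record length")
  centers <- seq.int(1L, n, by = stride)
  lo <- pmax(1L, centers - (window %/% 2L))
  hi <- pmin(n, centers + ((window - 1L) %/% 2L))
  width <- hi - lo + 1L
  out <- data.frame(time = (centers - 1L) / frames$frame_rate)
  for (a in .ALPHABET) {
    cs <- cumsum(c(0L, frames$labels == a))
    out[[a]] <- (cs[hi + 1L] - cs[lo]) / width
  }
  structure(out, window = window, stride = stride,
            frame_rate = frames$frame_rate, class = c("progression_curve",
                                                      "data.frame"))
}

#' Segment an ethogram into motifs
#'
#' Motifs are maximal runs of bouts executed with the same leg pair: anterior
#' motifs contain only head cleaning (`h`) and front leg rubbing (`f`);
#' posterior motifs only abdomen (`a`), wing (`w`) and back leg rubbing
#' (`b`). Walking, standing and the other motif's actions terminate a run.
#' Each motif's time is split into body-directed (h; a and w) and
#' leg-directed (f; b) components.
#'
#' @param etho A de-noised [bout_ethogram()].
#' @param min_bouts Discard motifs with fewer bouts (default 1, keep all).
#' @return A data frame with one row per motif: `motif_class`, `start_bout`,
#'   `end_bout`, `n_bouts`, `body_time`, `leg_time`, `total_time` (seconds).
#' @export
segment_motifs <- function(etho, min_bouts = 1L) {
  stopifnot(inherits(etho, "bout_ethogram"))
  df <- etho$bouts
  if (nrow(df) == 0L)
    return(data.frame(motif_class = character(0), start_bout = integer(0),
                      end_bout = integer(0), n_bouts = integer(0),
                      body_time = numeric(0), leg_time = numeric(0),
                      total_time = numeric(0), stringsAsFactors = FALSE))
  cls <- bout_class(df$action)
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c("anterior", "posterior") & r$lengths >= min_bouts
  out <- data.frame(motif_class = r$values[keep],
                    start_bout = starts[keep], end_bout = ends[keep],
                    n_bouts = r$lengths[keep], stringsAsFactors = FALSE)
  out$body_time <- vapply(seq_len(nrow(out)), function(i) {
    sel <- seq.int(out$start_bout[i], out$end_bout[i])
    sum(df$duration[sel][df$action[sel] %in% .BODY])
  }, 0)
  out$leg_time <- vapply(seq_len(nrow(out)), function(i) {
    sel <- seq.int(out$start_bout[i], out$end_bout[i])
    sum(df$duration[sel][df$action[sel] %in% .LEG])
  }, 0)
  out$total_time <- out$body_time + out$leg_time
  out
}

#' Body-time versus leg-time relation across motifs
#'
#' For motifs of `min_bouts` or more bouts, relates each motif's total
#' body-directed time to its leg-directed time via least squares and Pearson
#' correlation, separately per motif class. With fewer than two qualifying
#' motifs (or degenerate variance) the fit is reported as undefined (`NA`).
#'
#' @param motifs A [segment_motifs()] result, or a list of them (pooled).
#' @param min_bouts Minimum bouts per motif (default 4).
#' @return Named list (by motif class) of lists with `points` (data frame of
#'   `body_time`, `leg_time`), `slope`, `intercept`, `correlation`, `n`.
#' @export
motif_body_leg_relation <- function(motifs, min_bouts = 4L) {
  if (is.list(motifs) && !is.data.frame(motifs))
    motifs <- do.call(rbind, motifs)
  motifs <- motifs[motifs$n_bouts >= min_bouts, , drop = FALSE]
  out <- list()
  for (cl in c("anterior", "posterior")) {
    m <- motifs[motifs$motif_class == cl, , drop = FALSE]
    pts <- data.frame(body_time = m$body_time, leg_time = m$leg_time)
    res <- list(points = pts, slope = NA_real_, intercept = NA_real_,
                correlation = NA_real_, n = nrow(pts))
    if (nrow(pts) >= 2L && stats::sd(pts$body_time) > 0 &&
        stats::sd(pts$leg_time) > 0) {
      fit <- stats::lm(leg_time ~ body_time, data = pts)
      res$slope <- unname(stats::coef(fit)[2L])
      res$intercept <- unname(stats::coef(fit)[1L])
      res$correlation <- stats::cor(pts$body_time, pts$leg_time)
    }
    out[[cl]] <- res
  }
  out
}

#' Intra-motif transition fractions
#'
#' Over all consecutive-bout transitions whose source is an anterior action
#' (`f`, `h`): the fraction whose destination is also anterior; analogously
#' for posterior sources (`a`, `b`, `w`). These are the "within-motif mass"
#' summaries of the transition structure.
#'
#' @param cohort [bout_ethogram()] or list of them.
#' @return Named numeric vector `c(anterior = ..., posterior = ...)`; `NA`
#'   when a class has no source bouts.
#' @export
intra_motif_transition_fractions <- function(cohort) {
  cohort <- as_cohort(cohort)
  num <- c(anterior = 0, posterior = 0)
  den <- c(anterior = 0, posterior = 0)
  for (e in cohort) {
    act <- e$bouts$action
    n <- length(act)
    if (n < 2L) next
    src <- bout_class(act[-n])
    dst <- bout_class(act[-1L])
    for (cl in c("anterior", "posterior")) {
      den[cl] <- den[cl] + sum(src == cl)
      num[cl] <- num[cl] + sum(src == cl & dst == cl)
    }
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Consecutive within-class bout duration pairs
#'
#' Collects (duration_t, duration_{t+1}) for consecutive bout pairs whose
#' actions both belong to the given motif class, with a linear regression of
#' the second duration on the first. A near-zero R-squared indicates that
#' consecutive bout durations are not linearly related even when total motif
#' times are tightly coupled.
#'
#' @param cohort [bout_ethogram()] or list of them.
#' @param class `"anterior"` or `"posterior"`.
#' @return List with `pairs` (data frame `d_t`, `d_t1`), `slope`,
#'   `intercept`, `r_squared`, `n`; degenerate fits reported as `NA`.
#' @export
consecutive_bout_scatter <- function(cohort, class = c("anterior", "posterior")) {
  class <- match.arg(class)
  cohort <- as_cohort(cohort)
  pairs <- lapply(cohort, function(e) {
    act <- e$bouts$action
    n <- length(act)
    if (n < 2L) return(NULL)
    cl <- bout_class(act)
    sel <- cl[-n] == class & cl[-1L] == class
    data.frame(d_t = e$bouts$duration[-n][sel], d_t1 = e$bouts$duration[-1L][sel])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) pairs <- data.frame(d_t = numeric(0), d_t1 = numeric(0))
  res <- list(pairs = pairs, slope = NA_real_, intercept = NA_real_,
              r_squared = NA_real_, n = nrow(pairs))
  if (nrow(pairs) >= 2L && stats::sd(pairs$d_t) > 0 && stats::sd(pairs$d_t1) > 0) {
    fit <- stats::lm(d_t1 ~ d_t, data = pairs)
    res$slope <- unname(stats::coef(fit)[2L])
    res$intercept <- unname(stats::coef(fit)[1L])
    res$r_squared <- summary(fit)$r.squared
  }
  res
}
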