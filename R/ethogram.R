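#' Frame-level ethogram
#'
#' A frame ethogram is the raw record produced by a video classifier: one
#' behavior label per frame at a fixed frame rate.
#'
#' @param labels Character vector of behavior codes, one per frame. Every
#'   label must belong to [behavior_alphabet()].
#' @param frame_rate Frames per second (Hz), a single positive number.
#' @param fly_id Optional identifier carried through analyses.
#' @return An object of class `frame_ethogram` with fields `labels`,
#'   `frame_rate` and `fly_id`.
#' @export
frame_ethogram <- function(labels, frame_rate, fly_id = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a frame ethogram needs at least one frame")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a single positive number (Hz)")
  bad <- which(!(labels %in% .ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf("unknown behavior label '%s' at frame %d", labels[bad[1L]], bad[1L]))
  }
  structure(list(labels = labels, frame_rate = as.numeric(frame_rate),
                 fly_id = fly_id),
            class = "frame_ethogram")
}

#' @export
print.frame_ethogram <- function(x, ...) {
  cat(sprintf("<frame_ethogram> %d frames @ %g Hz (%.2f min)%s\n",
              length(x$labels), x$frame_rate,
              length(x$labels) / x$frame_rate / 60,
              if (is.null(x$fly_id)) "" else paste0(" fly ", x$fly_id)))
  invisible(x)
}

#' Discrete bout ethogram
#'
#' A bout ethogram is the run-length-encoded form of a frame ethogram: an
#' ordered sequence of (action, duration) bouts in which no two consecutive
#' bouts share an action. Durations are in seconds. Bouts may optionally carry
#' a 0-based duration-category index assigned by [apply_binning()].
#'
#' @param action Character vector of behavior codes.
#' @param duration Numeric vector of bout durations in seconds (> 0).
#' @param category Optional integer vector of 0-based duration categories
#'   (`NA` when unbinned).
#' @param frame_rate Provenance: the source frame rate in Hz (`NA` when the
#'   bouts did not come from frames).
#' @param fly_id Optional identifier.
#' @return An object of class `bout_ethogram`: a list with a `bouts`
#'   data frame (`action`, `duration`, `category`), `frame_rate`, `fly_id`
#'   and `total_time` (seconds).
#' @export
bout_ethogram <- function(action, duration, category = NULL,
                          frame_rate = NA_real_, fly_id = NULL) {
  action <- as.character(action)
  duration <- as.numeric(duration)
  n <- length(action)
  if (length(duration) != n) stop("action and duration lengths differ")
  if (is.null(category)) category <- rep(NA_integer_, n)
  category <- as.integer(category)
  if (length(category) != n) stop("category length differs from action")
  if (n > 0L) {
    bad <- which(!(action %in% .ALPHABET))
    if (length(bad) > 0L)
      stop(sprintf("unknown behavior code '%s' at bout %d", action[bad[1L]], bad[1L]))
    if (any(duration <= 0)) stop("bout durations must be > 0")
    if (n > 1L && any(action[-1L] == action[-n]))
      stop("consecutive bouts must have distinct actions")
  }
  structure(list(bouts = data.frame(action = action, duration = duration,
                                    category = category,
                                    stringsAsFactors = FALSE),
                 frame_rate = as.numeric(frame_rate), fly_id = fly_id,
                 total_time = sum(duration)),
            class = "bout_ethogram")
}

#' @export
print.bout_ethogram <- function(x, ...) {
  cat(sprintf("<bout_ethogram> %d bouts, %.2f min total%s%s\n",
              nrow(x$bouts), x$total_time / 60,
              if (all(is.na(x$bouts$category))) "" else " (binned)",
              if (is.null(x$fly_id)) "" else paste0(", fly ", x$fly_id)))
  invisible(x)
}

n_bouts <- function(etho) nrow(etho$bouts)

# accept a single ethogram or a list of them, always return a list
as_cohort <- function(x) {
  if (inherits(x, "bout_ethogram") || inherits(x, "frame_ethogram")) list(x) else x
}

#' Discretize a frame ethogram into bouts
#'
#' Collapses runs of consecutive identical frame labels into (action, duration)
#' bouts; each bout's duration is its run length divided by the frame rate.
#' The transformation is lossless: [expand_frames()] reconstructs the input
#' exactly.
#'
#' @param frames A [frame_ethogram()].
#' @return A [bout_ethogram()].
#' @export
discretize <- function(frames) {
  stopifnot(inherits(frames, "frame_ethogram"))
  r <- rle(frames$labels)
  bout_ethogram(action = r$values,
                duration = r$lengths / frames$frame_rate,
                frame_rate = frames$frame_rate, fly_id = frames$fly_id)
}

#' Expand a bout ethogram back to frames
#'
#' Inverse of [discretize()]: repeats each bout's label for
#' `round(duration * frame_rate)` frames.
#'
#' @param etho A [bout_ethogram()] whose `frame_rate` is known.
#' @param frame_rate Frame rate override (Hz); defaults to the ethogram's own.
#' @return A [frame_ethogram()].
#' @export
expand_frames <- function(etho, frame_rate = etho$frame_rate) {
  stopifnot(inherits(etho, "bout_ethogram"))
  if (is.na(frame_rate)) stop("no frame rate available to expand bouts")
  nf <- round(etho$bouts$duration * frame_rate)
  if (any(nf < 1L)) stop("a bout is shorter than one frame at this frame rate")
  frame_ethogram(rep(etho$bouts$action, times = nf), frame_rate,
                 fly_id = etho$fly_id)
}

# merge adjacent same-action bouts in one pass (durations summed; the merged
# bout keeps the first bout's category, which callers re-bin if it matters)
merge_adjacent <- function(df) {
  if (nrow(df) < 2L) return(df)
  grp <- cumsum(c(TRUE, df$action[-1L] != df$action[-nrow(df)]))
  if (max(grp) == nrow(df)) return(df)
  first <- !duplicated(grp)
  out <- df[first, , drop = FALSE]
  out$duration <- as.numeric(tapply(df$duration, grp, sum))
  rownames(out) <- NULL
  out
}

#' Delete sub-threshold artifact bouts
#'
#' Bouts shorter than `min_duration` are treated as classifier artifacts and
#' deleted; their time is dropped from the record (not redistributed). When a
#' deletion leaves two same-action bouts adjacent they are merged in a single
#' pass so the consecutive-distinct invariant holds. The default threshold of
#' 167 ms is the approximate duration of a single leg sweep.
#'
#' @param etho A [bout_ethogram()].
#' @param min_duration Deletion threshold in seconds (default 0.167).
#' @return The filtered [bout_ethogram()], with attributes
#'   `deleted_time` (seconds), `deleted_fraction` (of the original total time)
#'   and `n_deleted`. If everything is deleted an empty ethogram is returned
#'   with a warning.
#' @export
remove_short_bouts <- function(etho, min_duration = 0.167) {
  stopifnot(inherits(etho, "bout_ethogram"), min_duration >= 0)
  df <- etho$bouts
  drop <- df$duration < min_duration
  deleted <- sum(df$duration[drop])
  kept <- merge_adjacent(df[!drop, , drop = FALSE])
  if (nrow(kept) == 0L)
    warning("all bouts fell below the threshold; returning an empty ethogram")
  out <- bout_ethogram(kept$action, kept$duration, kept$category,
                       frame_rate = etho$frame_rate, fly_id = etho$fly_id)
  attr(out, "deleted_time") <- deleted
  attr(out, "deleted_fraction") <- if (etho$total_time > 0) deleted / etho$total_time else 0
  attr(out, "n_deleted") <- sum(drop)
  out
}

#' Remove all bouts of one action
#'
#' Deletes every bout of the given action (standing by default, which accounts
#' for under 1% of recording time) and merges same-action bouts left adjacent.
#'
#' @param etho A [bout_ethogram()].
#' @param action Behavior code to remove (default `"s"`).
#' @return The filtered [bout_ethogram()]; identity when the action is absent.
#' @export
drop_action <- function(etho, action = "s") {
  stopifnot(inherits(etho, "bout_ethogram"))
  if (!(action %in% .ALPHABET)) stop(sprintf("unknown behavior code '%s'", action))
  df <- etho$bouts
  drop <- df$action == action
  if (!any(drop)) return(etho)
  kept <- merge_adjacent(df[!drop, , drop = FALSE])
  if (nrow(kept) == 0L)
    warning("dropping '", action, "' emptied the ethogram")
  bout_ethogram(kept$action, kept$duration, kept$category,
                frame_rate = etho$frame_rate, fly_id = etho$fly_id)
}

#' Standard ethogram de-noising pipeline
#'
#' Convenience wrapper: short-bout deletion first, then standing removal
#' (order configurable).
#'
#' @param etho A [bout_ethogram()].
#' @param min_duration Threshold for [remove_short_bouts()].
#' @param drop Action to remove afterwards; `NULL` to skip.
#' @param standing_first If `TRUE`, remove standing before the short-bout
#'   filter instead of after.
#' @return A de-noised [bout_ethogram()].
#' @export
denoise_ethogram <- function(etho, min_duration = 0.167, drop = "s",
                             standing_first = FALSE) {
  if (standing_first && !is.null(drop)) etho <- drop_action(etho, drop)
  etho <- remove_short_bouts(etho, min_duration)
  if (!standing_first && !is.null(drop)) etho <- drop_action(etho, drop)
  etho
}
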