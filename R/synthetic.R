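# Ground-truth cohort generator. The defaults state the world the analysis
# assumes: six non-standing behaviors; per-action log-normal bout-duration
# distributions with modes near 1 s for the anterior actions (f, h), near
# 250 ms for abdomen/wing and intermediate for back leg rubbing; ~88% / ~70%
# within-motif transition mass for anterior / posterior sources; and a slow
# anterior-to-posterior drift with a 13-minute interpolation horizon.

default_duration_specs <- function() {
  # meanlog = log(mode) + sdlog^2
  list(f = c(meanlog = 0.36, sdlog = 0.6),
       h = c(meanlog = 0.36, sdlog = 0.6),
       a = c(meanlog = -1.136, sdlog = 0.5),
       b = c(meanlog = -0.333, sdlog = 0.6),
       w = c(meanlog = -1.136, sdlog = 0.5),
       wk = c(meanlog = 0.64, sdlog = 0.8))
}

default_drift <- function() {
  list(t_switch = 13,
       anterior_tilt = 0.10,            # late anterior block = 0.88 - 0.10
       posterior_escape_anterior = c(early = 0.75, late = 0.25),
       wk_to_anterior = c(early = 0.80, late = 0.20))
}

#' Ground-truth specification for synthetic cohorts
#'
#' Collects every parameter of the synthetic world: cohort size, recording
#' length, duration distributions, within-motif transition masses, duration
#' coupling, drift, and classifier-noise rate. The defaults are the stated
#' conditions the analysis emulates and are not meant to be tuned per run.
#'
#' @param n_flies Number of flies (default 92).
#' @param total_time Recording length in minutes (default 27.8).
#' @param actions Behavior alphabet (default [grooming_actions()]).
#' @param n_bins Duration categories (default 3).
#' @param anterior_block_mass Within-motif transition mass from anterior
#'   sources in the early phase (default 0.88).
#' @param posterior_block_mass Within-motif mass from posterior sources
#'   (default 0.70).
#' @param duration_specs Named list of `c(meanlog, sdlog)` per action.
#' @param duration_floor Lower truncation of all duration distributions in
#'   seconds (default 0.2, just above the artifact threshold so that only
#'   injected noise is ever deleted by de-noising).
#' @param duration_coupling `"symmetric"` (anterior category coupling with a
#'   dominant long-to-long transition, asymmetric posterior coupling) or
#'   `"independent"` (destination category independent of source category).
#' @param drift `NULL` for a stationary model, otherwise a list like
#'   `default_drift()`.
#' @param noise_rate Fraction of frames overwritten with 1-4-frame artifact
#'   insertions (default 0).
#' @param frame_rate Rasterization frame rate in Hz (default 30).
#' @param seed Cohort seed; per-fly seeds are derived as `seed + fly index`.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_flies = 92L, total_time = 27.8,
                              actions = grooming_actions(), n_bins = 3L,
                              anterior_block_mass = 0.88,
                              posterior_block_mass = 0.70,
                              duration_specs = default_duration_specs(),
                              duration_floor = 0.2,
                              duration_coupling = c("symmetric", "independent"),
                              drift = default_drift(),
                              noise_rate = 0, frame_rate = 30, seed = 1L) {
  duration_coupling <- match.arg(duration_coupling)
  stopifnot(n_flies >= 1L, total_time > 0,
            anterior_block_mass >= 0, anterior_block_mass <= 1,
            posterior_block_mass >= 0, posterior_block_mass <= 1,
            noise_rate >= 0, noise_rate < 1, duration_floor > 0)
  structure(list(n_flies = as.integer(n_flies), total_time = total_time,
                 actions = actions, n_bins = as.integer(n_bins),
                 anterior_block_mass = anterior_block_mass,
                 posterior_block_mass = posterior_block_mass,
                 duration_specs = duration_specs,
                 duration_floor = duration_floor,
                 duration_coupling = duration_coupling,
                 drift = drift, noise_rate = noise_rate,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "ground_truth_spec")
}

# category-coupling matrices: rows = source category, cols = destination
# category, rows sum to 1
coupling_matrix <- function(n_bins, kind = c("anterior", "posterior", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform" || n_bins == 1L)
    return(matrix(1 / n_bins, n_bins, n_bins))
  if (n_bins == 3L) {
    if (kind == "anterior") {
      # symmetric, long-to-long dominant
      m <- matrix(c(0.55, 0.30, 0.15,
                    0.30, 0.40, 0.30,
                    0.15, 0.30, 0.55), 3, 3, byrow = TRUE)
    } else {
      # asymmetric, biased toward short destinations
      m <- matrix(c(0.55, 0.30, 0.15,
                    0.45, 0.35, 0.20,
                    0.30, 0.35, 0.35), 3, 3, byrow = TRUE)
    }
    return(m)
  }
  # generic fallback for other bin counts
  idx <- seq_len(n_bins) - 1L
  if (kind == "anterior") {
    w <- exp(-abs(outer(idx, idx, "-"))) + 0.75 * diag(n_bins)
  } else {
    w <- exp(-outer(rep(0, n_bins), idx, "+") / 1.5 - 0.5 * abs(outer(idx, idx, "-")))
  }
  w / rowSums(w)
}

# action-level transition matrix for one phase
phase_action_matrix <- function(spec, phase = c("early", "late")) {
  phase <- match.arg(phase)
  acts <- spec$actions
  stopifnot(identical(acts, .ACTIONS))  # generator assumes the canonical alphabet
  drift <- spec$drift
  abm <- spec$anterior_block_mass
  pbm <- spec$posterior_block_mass
  if (is.null(drift)) {
    pea <- 0.75; wka <- 0.80
  } else {
    if (phase == "late") abm <- abm - drift$anterior_tilt
    pea <- drift$posterior_escape_anterior[[phase]]
    wka <- drift$wk_to_anterior[[phase]]
  }
  if (abm < 0 || abm > 1)
    stop(sprintf("anterior block mass %.3f outside [0, 1] after drift tilt", abm))
  A <- matrix(0, 6, 6, dimnames = list(acts, acts))
  esc_a <- 1 - abm  # anterior escape mass: 2/3 to posterior, 1/3 to walking
  for (src in c("f", "h")) {
    A[src, setdiff(.ANTERIOR, src)] <- abm
    A[src, .POSTERIOR] <- esc_a * (2 / 3) * c(0.375, 0.375, 0.25)
    A[src, "wk"] <- esc_a / 3
  }
  esc_p <- 1 - pbm
  within_p <- list(a = c(b = 5 / 7, w = 2 / 7),
                   b = c(a = 5 / 7, w = 2 / 7),
                   w = c(a = 4 / 7, b = 3 / 7))
  for (src in .POSTERIOR) {
    A[src, names(within_p[[src]])] <- pbm * within_p[[src]]
    A[src, .ANTERIOR] <- esc_p * pea / 2
    A[src, "wk"] <- esc_p * (1 - pea)
  }
  A["wk", .ANTERIOR] <- wka / 2
  A["wk", .POSTERIOR] <- (1 - wka) * c(0.40, 0.35, 0.25)
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop("generator rows failed to normalize")
  A
}

# expand an action-level matrix to the full state space using category
# couplings: within-motif destinations use the class's coupling row, all
# other destinations are uniform over categories
expand_action_matrix <- function(A, space, coupling) {
  nb <- space$n_bins
  v <- space$v
  C_ant <- coupling_matrix(nb, if (coupling == "symmetric") "anterior" else "uniform")
  C_post <- coupling_matrix(nb, if (coupling == "symmetric") "posterior" else "uniform")
  C_unif <- coupling_matrix(nb, "uniform")
  st <- space$states
  probs <- matrix(0, v, v)
  for (i in seq_len(v)) {
    ai <- st$action[i]; ci <- st$category[i] + 1L
    for (j in seq_len(v)) {
      aj <- st$action[j]
      if (ai == aj) next
      K <- if (ai %in% .ANTERIOR && aj %in% .ANTERIOR) C_ant
           else if (ai %in% .POSTERIOR && aj %in% .POSTERIOR) C_post
           else C_unif
      probs[i, j] <- A[ai, aj] * K[ci, st$category[j] + 1L]
    }
  }
  transition_matrix(probs, space)
}

# true equal-occupancy binning scheme: category edges at the k/n_bins
# quantiles of each action's floored log-normal duration distribution
true_binning_scheme <- function(spec) {
  edges <- list()
  for (a in spec$actions) {
    ds <- spec$duration_specs[[a]]
    plo <- stats::plnorm(spec$duration_floor, ds["meanlog"], ds["sdlog"])
    ks <- seq_len(spec$n_bins - 1L) / spec$n_bins
    edges[[a]] <- unname(stats::qlnorm(plo + ks * (1 - plo),
                                       ds["meanlog"], ds["sdlog"]))
  }
  structure(list(n_bins = spec$n_bins, edges = edges), class = "binning_scheme")
}

#' Build the ground-truth MRP model from a specification
#'
#' Constructs the early and late transition matrices (elevated anterior mass
#' early; elevated posterior and walking mass late; symmetric anterior and
#' asymmetric posterior duration coupling within motifs) and per-state
#' duration samplers: each state's durations follow the action's log-normal
#' truncated to that category's quantile interval, so the marginal category
#' distribution per action is uniform by construction. The initial
#' distribution is uniform over anterior states, matching the
#' anterior-dominated onset of grooming.
#'
#' @param spec A [ground_truth_spec()].
#' @return An [mrp_model()], with the matching true [fit_binning_scheme()]
#'   scheme attached as attribute `scheme`.
#' @export
make_ground_truth_mrp <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  space <- build_state_space(spec$actions, spec$n_bins)
  A_early <- phase_action_matrix(spec, "early")
  A_late <- if (is.null(spec$drift)) A_early else phase_action_matrix(spec, "late")
  M_early <- expand_action_matrix(A_early, space, spec$duration_coupling)
  M_late <- expand_action_matrix(A_late, space, spec$duration_coupling)
  scheme <- true_binning_scheme(spec)
  samplers <- list()
  for (i in seq_len(space$v)) {
    a <- space$states$action[i]
    cat <- space$states$category[i]
    ds <- spec$duration_specs[[a]]
    bounds <- c(spec$duration_floor, scheme$edges[[a]], Inf)
    samplers[[space$states$label[i]]] <-
      lnorm_sampler(ds["meanlog"], ds["sdlog"],
                    lower = bounds[cat + 1L], upper = bounds[cat + 2L])
  }
  p0 <- numeric(space$v)
  ant <- space$states$action %in% .ANTERIOR
  p0[ant] <- 1 / sum(ant)
  model <- mrp_model(M_early, M_late, samplers, p0,
                     t_switch = if (is.null(spec$drift)) 13 else spec$drift$t_switch)
  attr(model, "scheme") <- scheme
  model
}

#' Rasterize a bout ethogram to frame labels
#'
#' Rounds each bout to whole frames (minimum one) and repeats its label;
#' the output is padded with the final label or truncated so its length is
#' exactly `round(total_time * 60 * frame_rate)` frames.
#'
#' @param etho A [bout_ethogram()].
#' @param frame_rate Frames per second.
#' @param total_time Target record length in minutes (defaults to the
#'   ethogram's total time).
#' @return A [frame_ethogram()].
#' @export
rasterize_ethogram <- function(etho, frame_rate = 30,
                               total_time = etho$total_time / 60) {
  stopifnot(inherits(etho, "bout_ethogram"))
  nf <- pmax(1L, round(etho$bouts$duration * frame_rate))
  labels <- rep(etho$bouts$action, times = nf)
  target <- round(total_time * 60 * frame_rate)
  if (length(labels) > target) labels <- labels[seq_len(target)]
  if (length(labels) < target)
    labels <- c(labels, rep(labels[length(labels)], target - length(labels)))
  frame_ethogram(labels, frame_rate, fly_id = etho$fly_id)
}

#' Inject sub-threshold classifier noise into a frame ethogram
#'
#' Overwrites randomly placed 1-4-frame spans (133 ms or less at 30 Hz, below
#' the 167 ms artifact threshold) with an alien label differing from the span
#' and its neighbors, until approximately `noise_rate` of frames are
#' corrupted. Spans never overlap. Reproducible under `seed`.
#'
#' @param frames A [frame_ethogram()].
#' @param noise_rate Target corrupted fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The corrupted [frame_ethogram()] with attribute `noise_frames`
#'   (indices of overwritten frames).
#' @export
inject_label_noise <- function(frames, noise_rate, seed = 1L) {
  stopifnot(inherits(frames, "frame_ethogram"), noise_rate >= 0, noise_rate < 1)
  labels <- frames$labels
  n <- length(labels)
  if (noise_rate == 0) {
    out <- frames
    attr(out, "noise_frames") <- integer(0)
    return(out)
  }
  target <- round(noise_rate * n)
  mask <- logical(n)
  withr::with_seed(as.integer(seed), {
    inserted <- 0L
    tries <- 0L
    while (inserted < target && tries < 100L * target) {
      tries <- tries + 1L
      len <- min(sample.int(4L, 1L), target - inserted)
      pos <- sample.int(n - len + 1L, 1L)
      span <- seq.int(pos, pos + len - 1L)
      ctx <- seq.int(max(1L, pos - 1L), min(n, pos + len))
      if (any(mask[ctx])) next
      alien <- setdiff(.ALPHABET, labels[ctx])
      if (length(alien) == 0L) next
      labels[span] <- alien[sample.int(length(alien), 1L)]
      mask[span] <- TRUE
      inserted <- inserted + len
    }
  })
  out <- frame_ethogram(labels, frames$frame_rate, fly_id = frames$fly_id)
  attr(out, "noise_frames") <- which(mask)
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates `n_flies` independent ethograms from the ground-truth MRP
#' (per-fly seeds `seed + fly`), rasterizes each to frame labels, and
#' optionally corrupts them with sub-threshold label noise. The returned
#' truth objects support end-to-end parameter-recovery tests.
#'
#' @param spec A [ground_truth_spec()].
#' @return List with `frames` (list of [frame_ethogram()]), `bouts` (the
#'   pre-rasterization binned [bout_ethogram()]s), `mrp` (the true
#'   [mrp_model()]), `scheme` (the true `binning_scheme`) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  mrp <- make_ground_truth_mrp(spec)
  scheme <- attr(mrp, "scheme")
  bouts <- vector("list", spec$n_flies)
  frames <- vector("list", spec$n_flies)
  for (i in seq_len(spec$n_flies)) {
    sim <- simulate_ethogram(mrp, total_time = spec$total_time,
                             seed = spec$seed + i,
                             fly_id = sprintf("synth_%03d", i))
    bouts[[i]] <- sim$ethogram
    fr <- rasterize_ethogram(sim$ethogram, spec$frame_rate,
                             total_time = spec$total_time)
    if (spec$noise_rate > 0)
      fr <- inject_label_noise(fr, spec$noise_rate,
                               seed = spec$seed + 100000L + i)
    frames[[i]] <- fr
  }
  list(frames = frames, bouts = bouts, mrp = mrp, scheme = scheme, spec = spec)
}
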