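# Behavioral alphabet for dusted-fly grooming ethograms.
#
# Five grooming actions plus two non-grooming actions:
#   f  front leg rubbing      (anterior motif, leg-directed)
#   h  head cleaning          (anterior motif, body-directed)
#   a  abdomen cleaning       (posterior motif, body-directed)
#   b  back leg rubbing       (posterior motif, leg-directed)
#   w  wing cleaning          (posterior motif, body-directed)
#   wk walking
#   s  standing (removed from most analyses; < 1% of recording time)

.ACTIONS <- c("f", "h", "a", "b", "w", "wk")
.ALPHABET <- c(.ACTIONS, "s")
.ANTERIOR <- c("f", "h")
.POSTERIOR <- c("a", "b", "w")
.BODY <- c("h", "a", "w")
.LEG <- c("f", "b")

#' Behavioral alphabets
#'
#' `grooming_actions()` returns the six non-standing behavior codes in
#' canonical order (f, h, a, b, w, wk); `behavior_alphabet()` additionally
#' includes standing (`s`). `anterior_actions()` and `posterior_actions()`
#' return the motif memberships: anterior motifs are executed with the front
#' legs (head cleaning `h`, front leg rubbing `f`), posterior motifs with the
#' back legs (abdomen `a`, wing `w`, back leg rubbing `b`).
#'
#' @return A character vector of behavior codes.
#' @export
grooming_actions <- function() .ACTIONS

#' @rdname grooming_actions
#' @export
behavior_alphabet <- function() .ALPHABET

#' @rdname grooming_actions
#' @export
anterior_actions <- function() .ANTERIOR

#' @rdname grooming_actions
#' @export
posterior_actions <- function() .POSTERIOR

# short/medium/long style labels used in matrix headers ("h.s", "h.m", "h.l")
category_labels <- function(n_bins) {
  if (n_bins == 1L) return("")
  if (n_bins == 2L) return(c("s", "l"))
  if (n_bins == 3L) return(c("s", "m", "l"))
  paste0("d", seq_len(n_bins))
}
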