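#' Cultural niche-construction parameters
#'
#' When the niche feedback is enabled, the fixed vertical-learning schedule
#' `V` is replaced by a frequency-dependent vertical contact time
#' `v = v_b * (1 - epsilon * x4_lagged)`: as the trait spreads through the
#' adult population, children spend less time learning from their parents and
#' correspondingly more from peers and unrelated elders.
#'
#' @param v_b Baseline proportion of learning time spent with parents, in
#'   \[0, 1\].
#' @param epsilon Niche-construction strength, `>= 0`.  `epsilon = 0`
#'   disables the feedback (contact time stays at `v_b`); `epsilon = 1` makes
#'   vertical contact vanish as the adult frequency approaches 1.
#' @param enabled Logical; whether the feedback replaces the fixed schedule.
#' @return An object of class `"niche_params"`.
#' @export
niche_params <- function(v_b = 0.6, epsilon = 0, enabled = TRUE) {
  if (!is.numeric(v_b) || length(v_b) != 1L || is.na(v_b) || v_b < 0 || v_b > 1)
    stop("`v_b` must be a proportion in [0, 1]")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0)
    stop("`epsilon` must be a non-negative number")
  structure(list(v_b = v_b, epsilon = epsilon, enabled = isTRUE(enabled)),
            class = "niche_params")
}

#' @export
print.niche_params <- function(x, ...) {
  cat(sprintf("Niche construction: v_b = %g, epsilon = %g (%s)\n",
              x$v_b, x$epsilon, if (x$enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Frequency-dependent vertical contact time
#'
#' `v = v_b * (1 - epsilon * x4_lagged)`, clamped to \[0, 1\] (clamping can
#' only trigger for `epsilon > 1`; the canonical analyses use `epsilon` of 0
#' or 1, where the raw value is always in range).
#'
#' @param params A [niche_params()] object.
#' @param x4_lagged Adult trait frequency at the learner cohort's birth, in
#'   \[0, 1\].
#' @return Vertical contact proportion in \[0, 1\].
#' @export
#' @examples
#' vertical_time(niche_params(v_b = 0.6, epsilon = 1), 0.25) # 0.45
vertical_time <- function(params, x4_lagged) {
  stopifnot(inherits(params, "niche_params"))
  if (x4_lagged < 0 || x4_lagged > 1) stop("`x4_lagged` must lie in [0, 1]")
  min(1, max(0, params$v_b * (1 - params$epsilon * x4_lagged)))
}

#' One learning update for a stage under the niche-construction feedback
#'
#' The combined recursion for learners entering stage `j` (`j` in 2..4):
#' the fixed vertical proportion `V_j` of [update_class_frequency()] is
#' replaced by the dynamic contact time [vertical_time()] evaluated at the
#' lagged adult frequency of the learner cohort's parental generation, the
#' parental frequency term accounts for the trait's fitness effect
#' ([surviving_parent_frequency()]), and the horizontal/oblique term pools
#' stages `j..omega` ([pooled_source_frequency()]).
#'
#' The lag convention is cohort-consistent: a cohort entering stage `j` was
#' produced `j - 1` steps before the current state, so both the contact time
#' and the parental frequency are evaluated at that lag (with the survival
#' discount compounding over the `j` steps elapsed at the time the update
#' lands).
#'
#' @param state A [population_state()].
#' @param j Learner's new stage index (2, 3, or 4).
#' @param mode Fitness mode: `"fertility"`, `"survival"`, or `"neutral"`.
#' @param dem A [demography_params()] object.
#' @param lp A [learning_params()] object.
#' @param np A [niche_params()] object.
#' @return Updated stage-`j` frequency.
#' @export
niche_update_class_frequency <- function(state, j, mode, dem, lp, np) {
  stopifnot(inherits(state, "population_state"))
  j <- as.integer(j)
  if (!j %in% 2:4) stop("`j` must be 2, 3, or 4")
  x4_lag <- lagged_adult_freq(state, j - 1L)
  v <- vertical_time(np, x4_lag)
  xc <- surviving_parent_frequency(mode, dem, x4_lag, j)
  xd <- if (j <= lp$omega) pooled_source_frequency(state, j, lp$omega) else 0
  update_class_frequency(state$x[j - 1L], v, lp$p_v, lp$p_h, xc, xd)
}
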