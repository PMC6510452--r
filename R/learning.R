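#' Learning parameters: transmission fidelities and the vertical-learning
#' schedule
#'
#' @param p_v Vertical transmission fidelity in \[0, 1\]: the probability that
#'   a naive individual acquires the trait from a single knowledgeable parent
#'   role model.
#' @param p_h Horizontal/oblique transmission fidelity in \[0, 1\].
#' @param omega Oldest stage from which one can learn non-vertically (integer
#'   1..5; the canonical analyses use 5, the whole population).
#' @param V Vector of 3 per-stage vertical-learning proportions for learners
#'   entering stages 2, 3 and 4, each in \[0, 1\].  Stage 1 learns purely
#'   vertically at birth; stage 5 does not learn.  Ignored when the
#'   niche-construction feedback is enabled (contact time then replaces the
#'   fixed schedule).
#' @return An object of class `"learning_params"`.
#' @seealso [scenario()], [niche_params()]
#' @export
learning_params <- function(p_v, p_h, omega = 5L, V = c(1, 1, 1)) {
  for (nm in c("p_v", "p_h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a probability in [0, 1]")
  }
  omega <- as.integer(omega)
  if (is.na(omega) || omega < 1L || omega > 5L)
    stop("`omega` must be an integer stage index in 1..5")
  if (length(V) != 3L || any(V < 0 | V > 1) || anyNA(V))
    stop("`V` must be 3 proportions in [0, 1] (stages 2-4)")
  structure(list(p_v = p_v, p_h = p_h, omega = omega, V = as.numeric(V)),
            class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat(sprintf("Learning parameters: p_v = %g, p_h = %g, omega = %d\n",
              x$p_v, x$p_h, x$omega))
  cat("  vertical proportions V (stages 2-4):",
      paste(format(x$V), collapse = ", "), "\n")
  invisible(x)
}

# Bundled learning life histories. A and D are the reference extremes; the
# hunter-gatherer and agriculturalist schedules are configurable stand-ins
# shaped like the published time-allocation bars (no numeric schedule is
# printed for them), with vertical reliance high-then-declining vs low from
# early childhood on.
.scenario_table <- function() {
  list(
    all_vertical    = list(V = c(1, 1, 1),
      label = "All-vertical reference (horizontal/oblique only late, i.e. never before stage 5)"),
    hunter_gatherer = list(V = c(0.8, 0.8, 0.4),
      label = "Hunter-gatherer-like: predominantly vertical before adulthood"),
    agriculturalist = list(V = c(0.5, 0.25, 0.1),
      label = "Agriculturalist-like: horizontal/oblique from early childhood"),
    all_horizontal  = list(V = c(0, 0, 0),
      label = "All-horizontal reference (only the newborn round is vertical)")
  )
}

#' Bundled learning life histories
#'
#' A learning life history is the schedule of how much learning is vertical
#' at each life stage.  Four named schedules are bundled: the two reference
#' extremes (`all_vertical`, `all_horizontal`) and two empirically motivated
#' mixed schedules (`hunter_gatherer`, with predominantly vertical learning
#' before adulthood; `agriculturalist`, with horizontal/oblique learning from
#' early childhood).  The mixed schedules are configurable defaults, not
#' published numbers.
#'
#' @param name Scenario name (see [scenario_library()]), or an existing
#'   scenario object (returned unchanged).
#' @param V Optional explicit 3-vector of vertical proportions for stages
#'   2-4, overriding the bundled schedule (with `name` used as a label).
#' @return An object of class `"scenario"` with elements `name`, `V`,
#'   `label`.
#' @export
#' @examples
#' scenario("hunter_gatherer")$V
scenario <- function(name, V = NULL) {
  if (inherits(name, "scenario")) return(name)
  tab <- .scenario_table()
  if (!is.null(V)) {
    if (length(V) != 3L || any(V < 0 | V > 1)) stop("`V` must be 3 proportions")
    return(structure(list(name = name, V = as.numeric(V), label = "custom"),
                     class = "scenario"))
  }
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; see scenario_library()")
  structure(list(name = name, V = tab[[name]]$V, label = tab[[name]]$label),
            class = "scenario")
}

#' @rdname scenario
#' @return `scenario_library()` returns a data.frame of the bundled schedules
#'   (one row per scenario, columns `V2`, `V3`, `V4`, `label`).
#' @export
scenario_library <- function() {
  tab <- .scenario_table()
  data.frame(name = names(tab),
             V2 = vapply(tab, function(s) s$V[1], 0),
             V3 = vapply(tab, function(s) s$V[2], 0),
             V4 = vapply(tab, function(s) s$V[3], 0),
             label = vapply(tab, function(s) s$label, ""),
             row.names = NULL)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Learning life history '%s': V(stages 2-4) = %s\n  %s\n",
              x$name, paste(format(x$V), collapse = ", "), x$label))
  invisible(x)
}

#' Trait frequency among newborns after the first (vertical) learning round
#'
#' Newborns are produced by stage-4 adults, carriers of a fertility-modifying
#' trait contributing offspring in proportion `b + w_f` versus `b`.  A
#' newborn acquires the trait with probability `p_v` if its parent is a
#' carrier, so the newborn frequency is the fertility-weighted parental
#' frequency times the vertical fidelity:
#' `p_v * (b + w_f) * x4 / ((b + w_f) * x4 + b * (1 - x4))`.
#'
#' @param b Baseline fertility (non-negative).
#' @param w_f Additive fertility increment of the trait.
#' @param x4_prev Adult (stage 4) trait frequency at the parents' time of
#'   reproduction, in \[0, 1\].
#' @param p_v Vertical fidelity in \[0, 1\].
#' @return Newborn trait frequency in \[0, 1\].
#' @export
#' @examples
#' newborn_frequency(5, 1, 0.5, 1) # 6/11
newborn_frequency <- function(b, w_f, x4_prev, p_v) {
  if (x4_prev < 0 || x4_prev > 1) stop("`x4_prev` must lie in [0, 1]")
  if (p_v < 0 || p_v > 1) stop("`p_v` must lie in [0, 1]")
  den <- (b + w_f) * x4_prev + b * (1 - x4_prev)
  if (den <= 0)
    stop("no reproduction: (b + w_f) * x4 + b * (1 - x4) must be positive")
  p_v * (b + w_f) * x4_prev / den
}

#' Trait frequency in the pooled horizontal/oblique role-model set
#'
#' The potential non-vertical role models of a learner entering stage `j`
#' are all individuals in stages `j` through `omega` (own stage: horizontal;
#' older stages: oblique), pooled with weights proportional to stage sizes:
#' `sum(n_z x_z) / sum(n_z)` over `z = j..omega`.
#'
#' @param state A [population_state()].
#' @param j Learner's (new) stage index, `j <= omega`.
#' @param omega Oldest source stage (integer `j..5`).
#' @return Trait frequency among pooled role models.
#' @export
#' @examples
#' st <- population_state(n = c(5, 10, 20, 40, 25), x = c(0, 0.1, 0.2, 0.5, 0.8))
#' pooled_source_frequency(st, j = 2, omega = 5) # 45/95
pooled_source_frequency <- function(state, j, omega = 5L) {
  stopifnot(inherits(state, "population_state"))
  j <- as.integer(j); omega <- as.integer(omega)
  if (j < 1L || j > 5L || omega < 1L || omega > 5L || j > omega)
    stop("need stage indices with 1 <= j <= omega <= 5")
  idx <- j:omega
  tot <- sum(state$a[idx])
  if (tot <= 0) stop("empty role-model pool: no individuals in stages ",
                     j, "..", omega)
  sum(state$a[idx] * state$x[idx]) / tot
}

#' Trait frequency among parents surviving to the learner's current stage
#'
#' Vertical learning after infancy uses the frequency of the trait among the
#' learner's parental cohort, which must account for the trait's fitness
#' effect.  In `"fertility"` mode carrier parents are over-represented among
#' parents in proportion to their fertility, `(b + w_f) x / ((b + w_f) x +
#' b (1 - x))`.  In `"survival"` mode carrier parents out-survive
#' non-carriers over the `j` steps since reproduction:
#' `(s4 + w_s)^j x / ((s4 + w_s)^j x + s4^j (1 - x))` (a stylized discount
#' using the adult survival rate throughout).  In `"neutral"` mode the lagged
#' frequency is returned unchanged.
#'
#' @param mode `"fertility"`, `"survival"`, or `"neutral"`.
#' @param params A [demography_params()] object.
#' @param x4_lagged Adult frequency at the parents' time of reproduction.
#' @param j Number of steps since the learner's birth cohort was produced
#'   (its current stage index), `j >= 1`.
#' @return Parental trait frequency in \[0, 1\].
#' @export
surviving_parent_frequency <- function(mode, params, x4_lagged, j) {
  stopifnot(inherits(params, "demography_params"))
  mode <- match.arg(mode, c("fertility", "survival", "neutral"))
  if (x4_lagged < 0 || x4_lagged > 1) stop("`x4_lagged` must lie in [0, 1]")
  if (j < 1) stop("`j` must be >= 1")
  switch(mode,
    fertility = {
      den <- (params$b + params$w_f) * x4_lagged + params$b * (1 - x4_lagged)
      if (den <= 0) stop("zero parental weight: no reproduction")
      (params$b + params$w_f) * x4_lagged / den
    },
    survival = {
      s4 <- params$s[4]
      num <- (s4 + params$w_s)^j * x4_lagged
      den <- num + s4^j * (1 - x4_lagged)
      if (den <= 0) stop("zero parental weight: no surviving parents")
      num / den
    },
    neutral = x4_lagged)
}

#' One learning update for a stage under a fixed vertical/horizontal split
#'
#' The per-stage recursion of the fixed-schedule model: individuals who
#' already carry the trait keep it (there is no unlearning), and the naive
#' remainder makes one learning attempt, vertical with probability `V_j`
#' (success `p_v` against the parental frequency) and horizontal/oblique
#' otherwise (success `p_h` against the pooled role-model frequency):
#' `x' = x_prev + (1 - x_prev) * (V_j * x_parent * p_v +
#' (1 - V_j) * p_h * x_pool)`.
#'
#' @param x_prev_class Trait frequency of the cohort at the previous stage
#'   and time step.
#' @param V_j Proportion of learning that is vertical for this stage.
#' @param p_v,p_h Transmission fidelities.
#' @param x_parent Parental frequency (see [surviving_parent_frequency()]).
#' @param x_pool Pooled role-model frequency (see
#'   [pooled_source_frequency()]).
#' @return Updated frequency, in `[x_prev_class, 1]`.
#' @export
#' @examples
#' update_class_frequency(0.2, 0.5, 0.8, 0.6, 0.5, 0.25) # 0.42
update_class_frequency <- function(x_prev_class, V_j, p_v, p_h,
                                   x_parent, x_pool) {
  args <- c(x_prev_class, V_j, p_v, p_h, x_parent, x_pool)
  if (any(args < 0 | args > 1) || anyNA(args))
    stop("all arguments must lie in [0, 1]")
  x_prev_class + (1 - x_prev_class) *
    (V_j * x_parent * p_v + (1 - V_j) * p_h * x_pool)
}

#' Trait frequency of the post-reproductive stage after merging
#'
#' Stage 5 does not learn; its members at the next step are the stage-4
#' survivors maturing in plus the stage-5 survivors remaining:
#' `(x4 s4 n4 + x5 s5 n5) / (s4 n4 + s5 n5)`.  If the denominator is zero
#' the stage is empty next step and the frequency is 0 by convention (a
#' warning is raised).
#'
#' @param state A [population_state()].
#' @param s4,s5 Survival probabilities of stages 4 and 5.
#' @return Updated stage-5 frequency.
#' @export
update_oldest_class <- function(state, s4, s5) {
  stopifnot(inherits(state, "population_state"))
  den <- s4 * state$a[4] + s5 * state$a[5]
  if (den <= 0) {
    warning("stage 5 empty next step; frequency set to 0 by convention")
    return(0)
  }
  (state$x[4] * s4 * state$a[4] + state$x[5] * s5 * state$a[5]) / den
}
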