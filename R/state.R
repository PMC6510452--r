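#' Population state: stage counts, trait frequencies, and the parental lag
#' buffer
#'
#' A snapshot of the coupled system at one time step.  Internally the state
#' stores stage proportions `a` and the log of total size, so that thousands
#' of steps of super-critical growth never overflow; raw counts are exposed
#' through [state_counts()] and `$n`-style accessors and may print as `Inf`
#' after extreme growth even though all frequencies remain finite.
#'
#' The buffer `adult_freq_history` holds past stage-4 (adult) trait
#' frequencies, most recent last, and is padded with the initial adult
#' frequency so that lags up to 4 steps are always served.  It feeds the
#' lagged parental frequencies used by vertical learning and by the
#' niche-construction contact-time rule.
#'
#' @param n Non-negative vector of 5 stage counts (at least one positive).
#' @param x Vector of 5 per-stage trait frequencies in \[0, 1\].  A single
#'   value is recycled.
#' @param tau Integer time index of the snapshot.
#' @param adult_freq_history Optional numeric vector of past adult (stage 4)
#'   frequencies, most recent last; padded on the left with `x[4]` to length
#'   4.
#' @return An object of class `"population_state"` with elements `a`
#'   (proportions), `log_total`, `x`, `tau`, `adult_freq_history`.
#' @export
#' @examples
#' population_state(n = rep(20, 5), x = 0.005)
population_state <- function(n, x, tau = 0L, adult_freq_history = NULL) {
  if (length(x) == 1L) x <- rep(x, 5L)
  if (length(n) != 5L || any(n < 0) || anyNA(n) || sum(n) <= 0)
    stop("`n` must be 5 non-negative counts with a positive total")
  if (length(x) != 5L || any(x < 0 | x > 1) || anyNA(x))
    stop("`x` must be 5 frequencies in [0, 1]")
  .make_state(n / sum(n), log(sum(n)), as.numeric(x), as.integer(tau),
              adult_freq_history)
}

# internal constructor on the (proportions, log size) scale
.make_state <- function(a, log_total, x, tau, adult_freq_history = NULL) {
  h <- as.numeric(adult_freq_history)
  if (length(h) < 4L) h <- c(rep(if (length(h)) h[1L] else x[4L], 4L - length(h)), h)
  if (length(h) > 4L) h <- h[(length(h) - 3L):length(h)]
  structure(list(a = a, log_total = log_total, x = x, tau = as.integer(tau),
                 adult_freq_history = h),
            class = "population_state")
}

#' Stage counts of a population state
#'
#' @param state A [population_state()].
#' @return Numeric vector of 5 stage counts (`a * exp(log_total)`); may be
#'   `Inf` after extreme growth.
#' @export
state_counts <- function(state) {
  stopifnot(inherits(state, "population_state"))
  state$a * exp(state$log_total)
}

#' Adult trait frequency `lag` steps before the state's time index
#'
#' `lag = 0` returns the current stage-4 frequency; `lag >= 1` reads the
#' history buffer (padded with the initial adult frequency).
#'
#' @param state A [population_state()].
#' @param lag Non-negative integer lag, at most 4.
#' @return A frequency in \[0, 1\].
#' @export
lagged_adult_freq <- function(state, lag) {
  stopifnot(inherits(state, "population_state"), lag >= 0, lag <= 4)
  if (lag == 0) state$x[4L]
  else {
    h <- state$adult_freq_history
    h[length(h) - lag + 1L]
  }
}

#' @export
print.population_state <- function(x, ...) {
  n <- state_counts(x)
  cat(sprintf("Population state at tau = %d (total size %.6g)\n",
              x$tau, sum(n)))
  m <- rbind(n = n, a = x$a, x = x$x)
  colnames(m) <- paste0("stage", 1:5)
  print(round(m, 6))
  invisible(x)
}

#' Generate a starting population state
#'
#' Convenience constructor for the canonical initial conditions: a `uniform`
#' structure (20% of the population in each stage, the baseline starting
#' structure), a `pyramid` (decreasing proportions 0.35, 0.25, 0.2, 0.12,
#' 0.08), or a `skewed` structure with extreme mass in the first stage (0.8,
#' 0.05, 0.05, 0.05, 0.05).  The trait starts at the same frequency in every
#' stage.
#'
#' @param kind `"uniform"`, `"pyramid"`, or `"skewed"`.
#' @param total Positive total population size (default 100).
#' @param freq Initial trait frequency in every stage (default 0.005).
#' @param proportions Optional explicit 5-vector of stage proportions
#'   (summing to 1) overriding `kind`.
#' @return A [population_state()].
#' @export
#' @examples
#' generate_fixture("uniform", 100, 0.005)
generate_fixture <- function(kind = c("uniform", "pyramid", "skewed"),
                             total = 100, freq = 0.005, proportions = NULL) {
  kind <- match.arg(kind)
  if (total <= 0) stop("`total` must be positive")
  if (is.null(proportions)) {
    proportions <- switch(kind,
      uniform = rep(0.2, 5),
      pyramid = c(0.35, 0.25, 0.2, 0.12, 0.08),
      skewed  = c(0.8, 0.05, 0.05, 0.05, 0.05))
  }
  if (length(proportions) != 5L || abs(sum(proportions) - 1) > 1e-9)
    stop("`proportions` must be 5 values summing to 1")
  population_state(n = proportions * total, x = freq)
}
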