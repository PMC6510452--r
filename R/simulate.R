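#' Assemble a full simulation configuration
#'
#' Bundles demography, learning, optional niche-construction feedback, the
#' fitness mode, and initial conditions into a validated configuration.  The
#' trait affects either fertility or survival in a given run (or neither,
#' `"neutral"`); the unused increment is carried but inactive.
#'
#' @param demography A [demography_params()] object.
#' @param learning A [learning_params()] object.
#' @param niche Optional [niche_params()] object; when present and enabled,
#'   its dynamic contact time replaces the fixed schedule `V` for learners
#'   entering stages 2-4 (the newborn round is unaffected).
#' @param mode Fitness mode: `"fertility"`, `"survival"`, or `"neutral"`.
#' @param n_steps Number of time steps to iterate (`>= 0`).
#' @param initial_total Starting population size (default 100).
#' @param initial_age_structure Starting stage proportions (default uniform,
#'   20% per stage); must sum to 1 within 1e-9.
#' @param initial_trait_freq Starting trait frequency in every stage
#'   (default 0.005).
#' @param scenario Optional scenario name or [scenario()] object; overrides
#'   `learning$V` with the bundled schedule.
#' @param collapse_threshold Population size below which a run is flagged as
#'   collapsed (a reporting convention, default 1; the dynamics are not
#'   altered).
#' @return An object of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(
#'   demography = demography_params(5, c(0.5, 0.6, 0.6, 0.6, 0.2), w_f = 1),
#'   learning = learning_params(p_v = 0.6, p_h = 0.6),
#'   scenario = "hunter_gatherer", n_steps = 100)
sim_config <- function(demography, learning, niche = NULL,
                       mode = c("fertility", "survival", "neutral"),
                       n_steps = 5000L, initial_total = 100,
                       initial_age_structure = rep(0.2, 5),
                       initial_trait_freq = 0.005,
                       scenario = NULL, collapse_threshold = 1) {
  stopifnot(inherits(demography, "demography_params"),
            inherits(learning, "learning_params"))
  mode <- match.arg(mode)
  if (!is.null(niche) && !inherits(niche, "niche_params"))
    stop("`niche` must be NULL or a niche_params object")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 0L) stop("`n_steps` must be >= 0")
  if (initial_total <= 0) stop("`initial_total` must be positive")
  if (length(initial_age_structure) != 5L ||
      any(initial_age_structure < 0) ||
      abs(sum(initial_age_structure) - 1) > 1e-9)
    stop("`initial_age_structure` must be 5 non-negative proportions summing to 1 (within 1e-9)")
  if (initial_trait_freq < 0 || initial_trait_freq > 1)
    stop("`initial_trait_freq` must lie in [0, 1]")
  scen <- NULL
  if (!is.null(scenario)) {
    scen <- scenario(scenario)
    learning$V <- scen$V
  }
  structure(list(demography = demography, learning = learning, niche = niche,
                 mode = mode, n_steps = n_steps,
                 initial_total = initial_total,
                 initial_age_structure = as.numeric(initial_age_structure),
                 initial_trait_freq = initial_trait_freq,
                 scenario = scen, collapse_threshold = collapse_threshold),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  mode: %s, n_steps: %d, initial total %g at frequency %g\n",
              x$mode, x$n_steps, x$initial_total, x$initial_trait_freq))
  print(x$demography)
  print(x$learning)
  if (!is.null(x$niche)) print(x$niche)
  if (!is.null(x$scenario)) cat("  scenario:", x$scenario$name, "\n")
  invisible(x)
}

#' Canonical default configuration
#'
#' The baseline parameterization used throughout: fertility-enhancing trait
#' with `b = 5`, `s = (0.5, 0.6, 0.6, 0.6, 0.2)`, `w_f = 1`, `w_s = 0.05`
#' (inactive in fertility mode), fidelities `p_v = p_h = 0.6`, the
#' hunter-gatherer learning schedule, a uniform starting structure of 100
#' individuals, initial trait frequency 0.005, and 5000 steps.
#'
#' @param ... Overrides passed on to [sim_config()] (e.g. `n_steps`,
#'   `scenario`, `mode`).
#' @return A [sim_config()] object.
#' @export
default_config <- function(...) {
  args <- list(...)
  base <- list(
    demography = demography_params(b = 5, s = c(0.5, 0.6, 0.6, 0.6, 0.2),
                                   w_f = 1, w_s = 0.05),
    learning = learning_params(p_v = 0.6, p_h = 0.6, omega = 5L),
    mode = "fertility", scenario = "hunter_gatherer")
  base[names(args)] <- args
  do.call(sim_config, base)
}

#' Initial population state implied by a configuration
#'
#' @param config A [sim_config()] object.
#' @return A [population_state()] at `tau = 0`.
#' @export
initial_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  population_state(n = config$initial_age_structure * config$initial_total,
                   x = config$initial_trait_freq, tau = 0L)
}

# Flatten a configuration into the scalar fields the inner loop touches.
.sim_pars <- function(config) {
  dem <- config$demography; lp <- config$learning
  use_niche <- !is.null(config$niche) && config$niche$enabled
  list(b = dem$b, s = dem$s,
       wf_eff = if (config$mode == "fertility") dem$w_f else 0,
       ws_eff = if (config$mode == "survival") dem$w_s else 0,
       mode = config$mode,
       p_v = lp$p_v, p_h = lp$p_h, omega = lp$omega, V = lp$V,
       use_niche = use_niche,
       v_b = if (use_niche) config$niche$v_b else NA_real_,
       eps = if (use_niche) config$niche$epsilon else NA_real_)
}

# One synchronous step on the (proportions, log size) scale.  All new
# frequencies are computed from the time-tau state; counts advance with the
# projection matrix built from time-tau frequencies; the adult frequency is
# then pushed onto the lag buffer.  h is the lag buffer, most recent last
# (h[4] = adult frequency one step back).
.step_core <- function(a, logN, x, h, pp) {
  b <- pp$b; s <- pp$s; wf <- pp$wf_eff; ws <- pp$ws_eff
  xn <- numeric(5L)
  clamped <- 0L

  # stage 1: newborn vertical round against current adults
  den <- (b + wf) * x[4L] + b * (1 - x[4L])
  xn[1L] <- if (den > 0) pp$p_v * (b + wf) * x[4L] / den else 0

  # stages 2-4: cohort keeps what it knows, naive remainder attempts once
  for (j in 2:4) {
    xl <- h[6L - j]  # adult frequency j-1 steps back (cohort's parents)
    if (pp$use_niche) {
      v <- pp$v_b * (1 - pp$eps * xl)
      if (v < 0 || v > 1) { v <- min(1, max(0, v)); clamped <- clamped + 1L }
    } else v <- pp$V[j - 1L]
    C <- switch(pp$mode,
      fertility = {
        d <- (b + wf) * xl + b * (1 - xl)
        if (d > 0) (b + wf) * xl / d else 0
      },
      survival = {
        num <- (s[4L] + ws)^j * xl
        d <- num + s[4L]^j * (1 - xl)
        if (d > 0) num / d else 0
      },
      neutral = xl)
    if (j <= pp$omega) {
      idx <- j:pp$omega
      tot <- sum(a[idx])
      D <- if (tot > 0) sum(a[idx] * x[idx]) / tot else 0
    } else D <- 0
    xn[j] <- x[j - 1L] + (1 - x[j - 1L]) * (v * C * pp$p_v + (1 - v) * pp$p_h * D)
  }

  # stage 5: stage-4 survivors maturing in plus stage-5 survivors (no learning)
  d5 <- s[4L] * a[4L] + s[5L] * a[5L]
  xn[5L] <- if (d5 > 0) (x[4L] * s[4L] * a[4L] + x[5L] * s[5L] * a[5L]) / d5 else 0

  # counts: adapted Leslie projection with trait-dependent vital rates
  f4 <- b + wf * x[4L]
  se <- s + ws * x
  m <- c(f4 * a[4L], se[1L] * a[1L], se[2L] * a[2L], se[3L] * a[3L],
         se[4L] * a[4L] + se[5L] * a[5L])
  tot <- sum(m)
  if (tot <= 0) {
    return(list(a = rep(0, 5L), logN = -Inf, x = xn,
                h = c(h[2:4], x[4L]), extinct = TRUE, clamped = clamped))
  }
  list(a = m / tot, logN = logN + log(tot), x = xn,
       h = c(h[2:4], x[4L]), extinct = FALSE, clamped = clamped)
}

#' Advance a population state by one time step
#'
#' Applies the synchronous update: (1) all five stage frequencies are
#' recomputed from the current state (newborn vertical round for stage 1;
#' mixed vertical + pooled horizontal/oblique learning for stages 2-4, with
#' either the fixed schedule or the niche-construction contact time; survivor
#' merging without learning for stage 5); (2) stage counts advance through
#' the projection matrix built from current frequencies; (3) the current
#' adult frequency is pushed onto the lag buffer and the time index
#' increments.
#'
#' @param state A [population_state()].
#' @param config A [sim_config()] object.
#' @return The updated [population_state()]; if the population is fully
#'   extinct the state is returned with attribute `"extinct"` set.
#' @export
step_state <- function(state, config) {
  stopifnot(inherits(state, "population_state"),
            inherits(config, "sim_config"))
  pp <- .sim_pars(config)
  out <- .step_core(state$a, state$log_total, state$x,
                    state$adult_freq_history, pp)
  st <- .make_state(out$a, out$logN, out$x, state$tau + 1L, out$h)
  if (out$extinct) attr(st, "extinct") <- TRUE
  st
}

#' Run a full deterministic simulation
#'
#' Iterates [step_state()]'s update for `config$n_steps` steps from the
#' configured initial state, recording the trajectory.  The run is fully
#' deterministic: identical configurations give identical trajectories.
#' Internally the population is tracked as stage proportions plus log total
#' size, so super-critical growth over thousands of steps cannot overflow;
#' raw counts in the recorded trajectory may reach `Inf` in extreme runs
#' while all frequencies and proportions stay finite.
#'
#' @param config A [sim_config()] object.
#' @param record `"trajectory"` (default) records every step;
#'   `"final"` records only the initial and final states (faster for sweeps).
#' @return An object of class `"cultsim"`: a list with the recorded
#'   `trajectory` (data.frame with columns `tau`, `n1..n5`, `x1..x5`,
#'   `n_total`, `log_n_total`, `mean_freq`), the `final_state`, the
#'   `final_mean_freq` (size-weighted), the time-averaged
#'   `time_mean_freq` when the full trajectory is recorded, and flags
#'   `collapsed` (total ever below the collapse threshold), `extinct`,
#'   and `clamp_events`.
#' @export
#' @examples
#' sim <- run_simulation(default_config(n_steps = 200))
#' sim$final_mean_freq
run_simulation <- function(config, record = c("trajectory", "final")) {
  stopifnot(inherits(config, "sim_config"))
  record <- match.arg(record)
  pp <- .sim_pars(config)
  st <- initial_state(config)
  n_steps <- config$n_steps
  full <- record == "trajectory"

  a <- st$a; logN <- st$log_total; x <- st$x; h <- st$adult_freq_history
  if (full) {
    A <- matrix(NA_real_, n_steps + 1L, 5L)
    X <- matrix(NA_real_, n_steps + 1L, 5L)
    LN <- numeric(n_steps + 1L)
    A[1L, ] <- a; X[1L, ] <- x; LN[1L] <- logN
  }
  collapsed <- exp(logN) < config$collapse_threshold
  extinct <- FALSE
  clamp_events <- 0L
  if (n_steps > 0L) {
    for (k in seq_len(n_steps)) {
      out <- .step_core(a, logN, x, h, pp)
      a <- out$a; logN <- out$logN; x <- out$x; h <- out$h
      clamp_events <- clamp_events + out$clamped
      if (out$extinct) extinct <- TRUE
      if (!collapsed && (is.infinite(logN) && logN < 0 ||
                         logN < log(config$collapse_threshold)))
        collapsed <- TRUE
      if (full) { A[k + 1L, ] <- a; X[k + 1L, ] <- x; LN[k + 1L] <- logN }
      if (extinct) {
        if (full && k < n_steps) {
          rows <- (k + 2L):(n_steps + 1L)
          A[rows, ] <- rep(a, each = length(rows))
          X[rows, ] <- rep(x, each = length(rows))
          LN[rows] <- logN
        }
        break
      }
    }
  }
  final_state <- .make_state(a, logN, x, n_steps, h)
  if (full) {
    N <- exp(LN)
    traj <- data.frame(tau = 0:n_steps, A * N, X, n_total = N,
                       log_n_total = LN,
                       mean_freq = rowSums(A * X))
    names(traj)[2:11] <- c(paste0("n", 1:5), paste0("x", 1:5))
  } else {
    traj <- NULL
  }
  structure(list(trajectory = traj, config = config,
                 final_state = final_state,
                 final_mean_freq = sum(a * x),
                 time_mean_freq = if (full) mean(rowSums(A * X)) else NA_real_,
                 final_log_total = logN,
                 collapsed = collapsed, extinct = extinct,
                 clamp_events = clamp_events),
            class = "cultsim")
}

#' Size-weighted mean trait frequency of a population state
#'
#' `sum(n_i x_i) / sum(n_i)`, the population-wide frequency of the trait.
#'
#' @param state A [population_state()].
#' @return A frequency in \[0, 1\].
#' @export
#' @examples
#' st <- population_state(n = c(50, 20, 15, 10, 5),
#'                        x = c(0.1, 0.2, 0.3, 0.8, 0.9))
#' mean_population_frequency(st) # 0.26
mean_population_frequency <- function(state) {
  stopifnot(inherits(state, "population_state"))
  if (sum(state$a) <= 0) stop("empty population")
  sum(state$a * state$x)
}

#' @export
print.cultsim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Age-structured cultural transmission run (%s mode, %d steps)\n",
              cfg$mode, cfg$n_steps))
  cat(sprintf("  final mean trait frequency: %.6g\n", x$final_mean_freq))
  cat(sprintf("  final population size: %.6g (log %.6g)\n",
              exp(x$final_log_total), x$final_log_total))
  if (x$collapsed) cat("  population fell below the collapse threshold\n")
  if (x$extinct) cat("  population went fully extinct\n")
  if (x$clamp_events > 0)
    cat("  contact time clamped to [0, 1] in", x$clamp_events, "updates\n")
  invisible(x)
}

#' @export
summary.cultsim <- function(object, ...) {
  st <- object$final_state
  cat("Final state:\n")
  print(st)
  cat(sprintf("Mean trait frequency: %.6g", object$final_mean_freq))
  if (!is.na(object$time_mean_freq))
    cat(sprintf(" (time average %.6g)", object$time_mean_freq))
  cat("\n")
  invisible(object)
}

#' @export
as.data.frame.cultsim <- function(x, ...) {
  if (is.null(x$trajectory))
    stop("run was recorded with record = \"final\"; no trajectory available")
  x$trajectory
}

#' @export
plot.cultsim <- function(x, ...) {
  traj <- x$trajectory
  if (is.null(traj))
    stop("run was recorded with record = \"final\"; no trajectory to plot")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(traj$tau, traj[paste0("x", 1:5)], type = "l", lty = 1,
                    col = grDevices::hcl.colors(5, "Dark 3"),
                    xlab = "time step", ylab = "trait frequency",
                    main = "Per-stage trait frequency", ...)
  graphics::lines(traj$tau, traj$mean_freq, lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = c(rep(1, 5), 2),
                   col = c(grDevices::hcl.colors(5, "Dark 3"), "black"),
                   legend = c(paste("stage", 1:5), "population mean"),
                   cex = 0.7)
  graphics::plot(traj$tau, traj$log_n_total / log(10), type = "l",
                 xlab = "time step", ylab = "log10 population size",
                 main = "Population size")
  invisible(x)
}
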