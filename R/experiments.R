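#' Sweep transmission fidelities over a grid
#'
#' Runs one independent simulation per `(p_v, p_h)` cell, holding everything
#' else in `config` fixed, and records the chosen summary statistic: the
#' end-state size-weighted mean trait frequency (`"final_freq"`) or its
#' time average over the whole trajectory (`"mean_freq"`).
#'
#' @param config A [sim_config()] object (its `p_v`/`p_h` are overridden
#'   cell by cell).
#' @param pv_values,ph_values Numeric grids in \[0, 1\] (default 11 evenly
#'   spaced values).
#' @param statistic `"final_freq"` or `"mean_freq"`.
#' @return An object of class `"fidelity_sweep"`: a matrix with rows indexed
#'   by `p_v` and columns by `p_h`, plus attributes `pv`, `ph`, `statistic`.
#' @export
#' @examples
#' cfg <- default_config(n_steps = 200)
#' sw <- sweep_fidelity_grid(cfg, seq(0, 1, 0.5), seq(0, 1, 0.5))
sweep_fidelity_grid <- function(config,
                                pv_values = seq(0, 1, length.out = 11),
                                ph_values = seq(0, 1, length.out = 11),
                                statistic = c("final_freq", "mean_freq")) {
  stopifnot(inherits(config, "sim_config"))
  statistic <- match.arg(statistic)
  if (any(pv_values < 0 | pv_values > 1) || any(ph_values < 0 | ph_values > 1))
    stop("fidelity grids must lie in [0, 1]")
  record <- if (statistic == "final_freq") "final" else "trajectory"
  out <- matrix(NA_real_, length(pv_values), length(ph_values),
                dimnames = list(pv = format(pv_values, trim = TRUE),
                                ph = format(ph_values, trim = TRUE)))
  for (i in seq_along(pv_values)) {
    for (k in seq_along(ph_values)) {
      cfg <- config
      cfg$learning$p_v <- pv_values[i]
      cfg$learning$p_h <- ph_values[k]
      sim <- run_simulation(cfg, record = record)
      out[i, k] <- if (statistic == "final_freq") sim$final_mean_freq
                   else sim$time_mean_freq
    }
  }
  structure(out, pv = pv_values, ph = ph_values, statistic = statistic,
            class = c("fidelity_sweep", "matrix"))
}

#' @export
print.fidelity_sweep <- function(x, ...) {
  cat(sprintf("Fidelity sweep (%s): %d x %d grid (rows p_v, cols p_h)\n",
              attr(x, "statistic"), nrow(x), ncol(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
plot.fidelity_sweep <- function(x, ...) {
  graphics::image(attr(x, "pv"), attr(x, "ph"), unclass(x),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = expression(p[v]), ylab = expression(p[h]),
                  main = paste("Trait", attr(x, "statistic")),
                  zlim = c(0, 1), ...)
  invisible(x)
}

#' Frequency gain of a selected trait over its neutral twin
#'
#' Runs the configured simulation and a twin with `w_f = w_s = 0`
#' (everything else identical, including scenario and fidelities) and
#' returns the difference in end-state size-weighted mean frequency,
#' selected minus neutral.  This isolates the contribution of the trait's
#' fitness effect to its spread, over and above pure transmission.
#'
#' @param config A [sim_config()] object.
#' @return A single number (positive when selection helps the trait spread),
#'   with attributes `selected` and `neutral` holding the two final
#'   frequencies.
#' @export
compare_to_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sel <- run_simulation(config, record = "final")$final_mean_freq
  cfg0 <- config
  cfg0$demography$w_f <- 0
  cfg0$demography$w_s <- 0
  neu <- run_simulation(cfg0, record = "final")$final_mean_freq
  structure(sel - neu, selected = sel, neutral = neu)
}

#' Demographic rescue/collapse comparison across learning life histories
#'
#' Runs the same precarious demography under two (or more) learning
#' scenarios and reports the final population size of each: in a population
#' whose baseline growth rate is sub-critical but whose all-carrier growth
#' rate is super-critical, a schedule that spreads a fertility-enhancing
#' trait quickly can rescue the population while a slower schedule lets it
#' collapse.
#'
#' @param config A [sim_config()] object; the canonical setup starts 50
#'   individuals for 2500 steps.
#' @param scenarios Character vector of scenario names (or list of
#'   [scenario()] objects) to compare.
#' @return A data.frame with one row per scenario: final population size,
#'   its log, final mean trait frequency, and a `collapsed` flag (size ever
#'   below the collapse threshold).
#' @export
#' @examples
#' cfg <- sim_config(
#'   demography = demography_params(3, c(0.6, 0.6, 0.6, 0.6, 0.4), w_f = 1.7),
#'   learning = learning_params(0.6, 0.6),
#'   n_steps = 2500, initial_total = 50)
#' \donttest{rescue_experiment(cfg)}
rescue_experiment <- function(config,
                              scenarios = c("all_vertical", "all_horizontal")) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(scenarios, function(sc) {
    sc <- scenario(sc)
    cfg <- config
    cfg$scenario <- sc
    cfg$learning$V <- sc$V
    sim <- run_simulation(cfg, record = "final")
    data.frame(scenario = sc$name,
               final_n = exp(sim$final_log_total),
               final_log_n = sim$final_log_total,
               final_mean_freq = sim$final_mean_freq,
               collapsed = sim$collapsed)
  })
  do.call(rbind, rows)
}
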