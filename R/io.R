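# Config documents are YAML with four sections (demography, learning, niche,
# simulation); every key is optional and falls back to the canonical default,
# which is logged.  Unknown keys are rejected so typos cannot silently
# produce a default run.

.config_defaults <- function() {
  list(
    demography = list(b = 5, s1 = 0.5, s2 = 0.6, s3 = 0.6, s4 = 0.6,
                      s5 = 0.2, w_f = 1, w_s = 0.05, mode = "fertility"),
    learning = list(p_v = 0.6, p_h = 0.6, omega = 5,
                    scenario = "hunter_gatherer", V = NULL),
    niche = list(enabled = FALSE, v_b = 0.6, epsilon = 0),
    simulation = list(n_steps = 5000, initial_total = 100,
                      initial_trait_freq = 0.005,
                      initial_age_structure = rep(0.2, 5),
                      collapse_threshold = 1)
  )
}

#' Load (and validate) a simulation configuration
#'
#' Reads a YAML document with sections `demography`, `learning`, `niche`,
#' `simulation`, fills unspecified keys from the canonical defaults (each
#' applied default is logged with `message()`), rejects unknown keys, and
#' returns a validated [sim_config()].  `overrides` are applied after the
#' file using `"section.key"` names, so every file value can also be set
#' programmatically or from a command line.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @param overrides Named list of `"section.key" = value` overrides, e.g.
#'   `list("demography.b" = 4, "learning.p_v" = 0.8)`.
#' @param quiet Suppress the applied-default log messages.
#' @return A [sim_config()] object.
#' @export
#' @examples
#' cfg <- load_config(overrides = list("simulation.n_steps" = 100),
#'                    quiet = TRUE)
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  defaults <- .config_defaults()
  doc <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  bad_sections <- setdiff(names(doc), names(defaults))
  if (length(bad_sections))
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  for (ov in names(overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("override names must look like 'section.key', got '", ov, "'")
    doc[[parts[1]]][[parts[2]]] <- overrides[[ov]]
  }
  merged <- defaults
  for (sec in names(doc)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: ", sec)
    bad <- setdiff(names(doc[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    merged[[sec]][names(doc[[sec]])] <- doc[[sec]]
  }
  if (!quiet) {
    for (sec in names(defaults)) {
      missing <- setdiff(names(defaults[[sec]]), names(doc[[sec]]))
      missing <- missing[!vapply(defaults[[sec]][missing], is.null, TRUE)]
      if (length(missing))
        message("config: section '", sec, "' using defaults for: ",
                paste(missing, collapse = ", "))
    }
  }
  d <- merged$demography
  s <- as.numeric(c(d$s1, d$s2, d$s3, d$s4, d$s5))
  if (any(s < 0 | s > 1))
    stop("survival probabilities s1..s5 must lie in [0, 1]; got (",
         paste(format(s), collapse = ", "), ")")
  dem <- demography_params(b = d$b, s = s, w_f = d$w_f, w_s = d$w_s)
  l <- merged$learning
  lp <- learning_params(p_v = l$p_v, p_h = l$p_h, omega = l$omega,
                        V = if (is.null(l$V)) c(1, 1, 1) else l$V)
  scen <- if (is.null(l$V)) l$scenario else scenario("custom", V = l$V)
  np <- merged$niche
  niche <- if (isTRUE(np$enabled))
    niche_params(v_b = np$v_b, epsilon = np$epsilon, enabled = TRUE)
  else NULL
  sm <- merged$simulation
  sim_config(demography = dem, learning = lp, niche = niche,
             mode = d$mode, n_steps = sm$n_steps,
             initial_total = sm$initial_total,
             initial_age_structure = as.numeric(sm$initial_age_structure),
             initial_trait_freq = sm$initial_trait_freq,
             scenario = scen, collapse_threshold = sm$collapse_threshold)
}

#' Serialize a configuration back to its document form
#'
#' Returns the nested section/key list of all effective values, suitable for
#' [write_config()]; `load_config(write_config(cfg))` reproduces every
#' effective value (the config round-trip invariant).
#'
#' @param config A [sim_config()] object.
#' @return A nested list with sections `demography`, `learning`, `niche`,
#'   `simulation`.
#' @export
serialize_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$demography; l <- config$learning
  list(
    demography = list(b = d$b, s1 = d$s[1], s2 = d$s[2], s3 = d$s[3],
                      s4 = d$s[4], s5 = d$s[5], w_f = d$w_f, w_s = d$w_s,
                      mode = config$mode),
    learning = list(p_v = l$p_v, p_h = l$p_h, omega = l$omega, V = l$V),
    niche = if (is.null(config$niche)) list(enabled = FALSE)
            else list(enabled = config$niche$enabled,
                      v_b = config$niche$v_b,
                      epsilon = config$niche$epsilon),
    simulation = list(n_steps = config$n_steps,
                      initial_total = config$initial_total,
                      initial_trait_freq = config$initial_trait_freq,
                      initial_age_structure = config$initial_age_structure,
                      collapse_threshold = config$collapse_threshold)
  )
}

#' @rdname serialize_config
#' @param path File to write the YAML document to.
#' @return `write_config()` invisibly returns `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path)
  invisible(path)
}

#' Write a recorded trajectory to CSV
#'
#' Columns `tau`, `n1..n5`, `x1..x5`, `n_total`, `log_n_total`,
#' `mean_freq`; values round-trip losslessly well beyond 12 significant
#' digits.
#'
#' @param traj A `"cultsim"` object (run with `record = "trajectory"`) or
#'   its trajectory data.frame.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "cultsim")) traj <- as.data.frame(traj)
  if (!is.data.frame(traj)) stop("`traj` must be a cultsim run or data.frame")
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path File path.
#' @return The trajectory data.frame.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}
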