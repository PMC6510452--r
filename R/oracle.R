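#' Stochastic individual-based twin of the deterministic recursions
#'
#' `abm_init()` builds an agent population matching a configuration's
#' initial conditions; [abm_step()] advances it one step; [abm_run()]
#' iterates and records per-stage counts and frequencies.  The agent model
#' draws Bernoulli survival, Poisson offspring numbers (mean `b` or
#' `b + w_f` by parental trait in fertility mode), and one learning attempt
#' per eligible agent per step, and is used to verify that the deterministic
#' recursion is the large-population mean of the individual-level rules.
#'
#' Each agent records the trait state of its parent at birth.  The newborn
#' vertical round uses the agent's own parent; later vertical attempts draw
#' a role model uniformly from the learner cohort's recorded parental pool
#' (the realized traits of that cohort's actual parents).  Drawing from the
#' pool rather than re-using the agent's own parent matches the
#' deterministic recursion, which treats the parental role model of each
#' attempt as an independent draw from the parental generation; conditioning
#' on the learner's own parent would correlate repeated vertical attempts
#' and depress acquisition below the recursion's prediction.
#'
#' In survival mode the deterministic recursion uses a stylized parental
#' survival discount (adult survival compounded over the learner's age)
#' that the agent model does not reproduce exactly; oracle-equivalence
#' checks are therefore run in fertility or neutral mode.
#'
#' @param config A [sim_config()] object.
#' @param n0 Initial number of agents (allocated to stages by rounding
#'   `n0` times the configured stage proportions).
#' @return `abm_init()`: an object of class `"abm_population"` with integer
#'   stage vector `age`, logical vectors `trait` and `ptrait` (agent and
#'   recorded-parent trait states), and the realized adult-frequency lag
#'   buffer `x4_history` (most recent last).
#' @seealso [replicate_summary()]
#' @export
abm_init <- function(config, n0 = 10000) {
  stopifnot(inherits(config, "sim_config"))
  counts <- round(n0 * config$initial_age_structure)
  age <- rep.int(1:5, counts)
  N <- length(age)
  x0 <- config$initial_trait_freq
  pp <- .sim_pars(config)
  # parental-pool padding mirrors the deterministic lag-buffer padding:
  # fertility-weighted initial adult frequency
  den <- (pp$b + pp$wf_eff) * x0 + pp$b * (1 - x0)
  g0 <- if (den > 0) (pp$b + pp$wf_eff) * x0 / den else 0
  structure(list(age = age,
                 trait = stats::runif(N) < x0,
                 ptrait = stats::runif(N) < g0,
                 x4_history = rep(x0, 4L)),
            class = "abm_population")
}

#' Advance the agent population one synchronous step
#'
#' Mirrors the deterministic update order: learning attempts are resolved
#' against the pre-step population, then survival and stage advancement are
#' drawn, then stage-4 agents reproduce (offspring record the parent's trait
#' and make their newborn vertical attempt), and the realized adult
#' frequency is pushed onto the lag buffer.
#'
#' @param pop An `"abm_population"` (see [abm_init()]).
#' @param config A [sim_config()] object.
#' @return The updated `"abm_population"`; an empty population is returned
#'   unchanged (extinct).
#' @export
abm_step <- function(pop, config) {
  stopifnot(inherits(pop, "abm_population"), inherits(config, "sim_config"))
  pp <- .sim_pars(config)
  age <- pop$age; trait <- pop$trait; ptrait <- pop$ptrait
  N <- length(age)
  if (N == 0L) return(pop)
  h <- pop$x4_history

  in4 <- age == 4L
  x4_real <- if (any(in4)) mean(trait[in4]) else h[4L]

  # learning: agents in stages 1-3 (entering stages 2-4); synchronous, so
  # all pools and parental shares use pre-step states
  new_trait <- trait
  for (cls in 1:3) {
    j <- cls + 1L
    cohort <- age == cls
    if (!any(cohort)) next
    naive <- which(cohort & !trait)
    if (!length(naive)) next
    q <- mean(ptrait[cohort])
    if (j <= pp$omega) {
      pool <- age >= j & age <= pp$omega
      share <- if (any(pool)) mean(trait[pool]) else 0
    } else share <- 0
    v <- if (pp$use_niche) {
      xl <- h[5L - j + 1L]  # adult frequency j-1 steps back
      min(1, max(0, pp$v_b * (1 - pp$eps * xl)))
    } else pp$V[j - 1L]
    prob <- v * pp$p_v * q + (1 - v) * pp$p_h * share
    new_trait[naive[stats::runif(length(naive)) < prob]] <- TRUE
  }

  # reproduction from pre-step stage-4 agents (Leslie semantics: fertility
  # applies to those alive at tau, independent of their own survival draw)
  if (any(in4)) {
    par_trait <- trait[in4]
    mean_off <- pp$b + pp$wf_eff * as.numeric(par_trait)
    noff <- stats::rpois(length(par_trait), mean_off)
    ptr_new <- rep(par_trait, noff)
    tr_new <- ptr_new & (stats::runif(length(ptr_new)) < pp$p_v)
  } else {
    ptr_new <- logical(0); tr_new <- logical(0)
  }

  # survival (trait-dependent in survival mode, using pre-learning states)
  p_surv <- pp$s[age] + pp$ws_eff * as.numeric(trait)
  keep <- stats::runif(N) < p_surv
  age_new <- pmin(age + 1L, 5L)

  structure(list(age = c(rep.int(1L, length(tr_new)), age_new[keep]),
                 trait = c(tr_new, new_trait[keep]),
                 ptrait = c(ptr_new, ptrait[keep]),
                 x4_history = c(h[2:4], x4_real)),
            class = "abm_population")
}

#' Run the agent-based model and record per-stage summaries
#'
#' @param config A [sim_config()] object.
#' @param n_steps Number of steps.
#' @param n0 Initial number of agents.
#' @param seed Integer seed for reproducibility (same seed, same
#'   trajectory).
#' @return A list with `freq` (an `(n_steps + 1) x 5` matrix of per-stage
#'   trait frequencies, `NA` where a stage is empty), `counts` (stage
#'   sizes), and `extinct`.
#' @export
abm_run <- function(config, n_steps = 100L, n0 = 10000, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  pop <- abm_init(config, n0)
  freq <- matrix(NA_real_, n_steps + 1L, 5L)
  counts <- matrix(0, n_steps + 1L, 5L)
  snap <- function(pop, row) {
    for (cls in 1:5) {
      idx <- pop$age == cls
      counts[row, cls] <<- sum(idx)
      if (any(idx)) freq[row, cls] <<- mean(pop$trait[idx])
    }
  }
  snap(pop, 1L)
  for (k in seq_len(n_steps)) {
    pop <- abm_step(pop, config)
    snap(pop, k + 1L)
    if (length(pop$age) == 0L) break
  }
  list(freq = freq, counts = counts, extinct = length(pop$age) == 0L)
}

#' Replicate the agent-based model and summarize across runs
#'
#' Runs `n_replicates` independently seeded agent-based simulations and
#' returns the per-step, per-stage mean and standard error of trait
#' frequencies and stage sizes across replicates.
#'
#' @param config A [sim_config()] object.
#' @param n_replicates Number of replicates (`>= 2`).
#' @param n_steps Steps per replicate.
#' @param n0 Initial agents per replicate.
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @return A list with matrices `freq_mean`, `freq_se`, `count_mean`,
#'   `count_se` (rows = time steps 0..n_steps, columns = stages) and the
#'   number of replicates `n_replicates`.
#' @export
replicate_summary <- function(config, n_replicates = 50L, n_steps = 100L,
                              n0 = 10000, seed = 1L) {
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2")
  freqs <- array(NA_real_, c(n_steps + 1L, 5L, n_replicates))
  cnts <- array(NA_real_, c(n_steps + 1L, 5L, n_replicates))
  for (r in seq_len(n_replicates)) {
    run <- abm_run(config, n_steps = n_steps, n0 = n0, seed = seed + r - 1L)
    freqs[, , r] <- run$freq
    cnts[, , r] <- run$counts
  }
  m <- apply(freqs, c(1, 2), mean, na.rm = TRUE)
  s <- apply(freqs, c(1, 2), stats::sd, na.rm = TRUE) / sqrt(n_replicates)
  mc <- apply(cnts, c(1, 2), mean)
  sc <- apply(cnts, c(1, 2), stats::sd) / sqrt(n_replicates)
  list(freq_mean = m, freq_se = s, count_mean = mc, count_se = sc,
       n_replicates = n_replicates)
}
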