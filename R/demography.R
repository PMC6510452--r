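#' Demographic parameters for the stage-structured model
#'
#' Bundles the vital rates of the five-stage population projection: a baseline
#' fertility for the single reproductive stage (stage 4), per-stage survival
#' probabilities, and the additive fitness increments a carrier of the
#' cultural trait enjoys.  The five stages loosely represent infancy, early
#' childhood, late childhood, adulthood, and post-reproductive life; only
#' stage 4 reproduces, and stage-5 survivors remain in stage 5.
#'
#' @param b Baseline number of offspring per reproducing (stage 4) individual
#'   per time step, for non-carriers.  Non-negative.
#' @param s Numeric vector of 5 survival probabilities `s1..s5`, each in
#'   \[0, 1\]: `s[i]` is the probability of surviving from stage i to the next
#'   time step.
#' @param w_f Additive fertility increment of the trait: carriers in stage 4
#'   produce `b + w_f` offspring.  May be negative; `b + w_f` must be
#'   non-negative.
#' @param w_s Additive survival increment of the trait, applied uniformly to
#'   all stages when the trait affects survival; `s[i] + w_s` must lie in
#'   \[0, 1\] for every stage whenever `w_s != 0`.
#' @param n_classes Number of life stages (fixed at 5).
#'
#' @return An object of class `"demography_params"`.
#' @seealso [projection_matrix()], [effective_fertility()],
#'   [effective_survival()]
#' @export
#' @examples
#' demography_params(b = 5, s = c(0.5, 0.6, 0.6, 0.6, 0.2), w_f = 1)
demography_params <- function(b, s, w_f = 0, w_s = 0, n_classes = 5L) {
  if (!identical(as.integer(n_classes), 5L))
    stop("the model is defined for exactly 5 life stages")
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0)
    stop("`b` must be a single non-negative number")
  if (!is.numeric(s) || length(s) != 5L || anyNA(s) || any(s < 0 | s > 1))
    stop("`s` must be 5 survival probabilities in [0, 1]")
  if (!is.numeric(w_f) || length(w_f) != 1L || is.na(w_f))
    stop("`w_f` must be a single number")
  if (b + w_f < 0)
    stop("effective fertility b + w_f must be non-negative (b = ", b,
         ", w_f = ", w_f, ")")
  if (!is.numeric(w_s) || length(w_s) != 1L || is.na(w_s))
    stop("`w_s` must be a single number")
  if (w_s != 0 && any(s + w_s < 0 | s + w_s > 1))
    stop("s_i + w_s must lie in [0, 1] for every stage when w_s != 0")
  structure(list(b = b, s = as.numeric(s), w_f = w_f, w_s = w_s,
                 n_classes = 5L),
            class = "demography_params")
}

#' @export
print.demography_params <- function(x, ...) {
  cat("Stage-structured vital rates (5 stages, stage 4 reproduces)\n")
  cat(sprintf("  b   = %g  (carrier fertility b + w_f = %g)\n", x$b, x$b + x$w_f))
  cat("  s   =", paste(format(x$s), collapse = ", "), "\n")
  cat(sprintf("  w_f = %g, w_s = %g\n", x$w_f, x$w_s))
  invisible(x)
}

#' Trait-dependent effective fertility of the reproductive stage
#'
#' Mean offspring number of stage-4 individuals when a fraction `x4` of them
#' carry the fertility-modifying trait:
#' `(b + w_f) * x4 + b * (1 - x4)`, i.e. `b + w_f * x4`.
#'
#' @param params A [demography_params()] object.
#' @param x4 Trait frequency in stage 4, in \[0, 1\].
#' @return Effective fertility, a single non-negative number.
#' @export
#' @examples
#' p <- demography_params(5, c(0.5, 0.6, 0.6, 0.6, 0.2), w_f = 1)
#' effective_fertility(p, 0.5) # 5.5
effective_fertility <- function(params, x4) {
  stopifnot(inherits(params, "demography_params"))
  if (!is.numeric(x4) || length(x4) != 1L || is.na(x4) || x4 < 0 || x4 > 1)
    stop("`x4` must be a frequency in [0, 1]")
  (params$b + params$w_f) * x4 + params$b * (1 - x4)
}

#' Trait-dependent effective survival of a stage
#'
#' Aggregate survival probability of a stage in which a fraction `x_i` of
#' individuals carry a survival-enhancing trait:
#' `s_i * (1 - x_i) + x_i * (s_i + w_s)`, i.e. `s_i + w_s * x_i`.
#' Vectorized over `s_i` and `x_i`.
#'
#' @param params A [demography_params()] object (supplies `w_s`).
#' @param s_i Baseline survival probability (or vector thereof), in \[0, 1\].
#' @param x_i Trait frequency in the stage (or vector), in \[0, 1\].
#' @return Effective survival probabilities; an error is raised if any value
#'   falls outside \[0, 1\].
#' @export
#' @examples
#' p <- demography_params(5, c(0.5, 0.6, 0.6, 0.6, 0.2), w_s = 0.05)
#' effective_survival(p, 0.7, 0.4) # 0.72
effective_survival <- function(params, s_i, x_i) {
  stopifnot(inherits(params, "demography_params"))
  if (any(s_i < 0 | s_i > 1) || anyNA(s_i)) stop("`s_i` must lie in [0, 1]")
  if (any(x_i < 0 | x_i > 1) || anyNA(x_i)) stop("`x_i` must lie in [0, 1]")
  out <- s_i + params$w_s * x_i
  if (any(out < 0 | out > 1))
    stop("effective survival s_i + w_s * x_i falls outside [0, 1]")
  out
}

#' Build the stage-structured projection matrix
#'
#' Constructs the adapted Leslie matrix `L` for the current population state.
#' Its top row is `(0, 0, 0, f4, 0)` (only stage 4 reproduces), the
#' subdiagonal carries `s1..s3`, and the bottom row carries `s4` and `s5` in
#' columns 4 and 5 (stage-5 survivors remain in stage 5).  In `"fertility"`
#' mode `f4` is the trait-dependent [effective_fertility()]; in `"survival"`
#' mode the survival entries are trait-dependent [effective_survival()]
#' values; in `"neutral"` mode the matrix is independent of trait frequencies.
#'
#' @param params A [demography_params()] object.
#' @param x Numeric vector of 5 per-stage trait frequencies.
#' @param mode One of `"fertility"`, `"survival"`, `"neutral"`: which vital
#'   rate the trait affects.
#' @return A 5x5 non-negative matrix.
#' @export
#' @examples
#' p <- demography_params(3, c(0.6, 0.6, 0.6, 0.6, 0.4), w_f = 1.7)
#' projection_matrix(p, rep(1, 5), mode = "fertility")[1, 4] # 4.7
projection_matrix <- function(params, x,
                              mode = c("fertility", "survival", "neutral")) {
  stopifnot(inherits(params, "demography_params"))
  mode <- match.arg(mode)
  if (length(x) != 5L || any(x < 0 | x > 1) || anyNA(x))
    stop("`x` must be 5 frequencies in [0, 1]")
  f4 <- if (mode == "fertility") effective_fertility(params, x[4]) else params$b
  s <- if (mode == "survival") effective_survival(params, params$s, x)
       else params$s
  L <- matrix(0, 5, 5)
  L[1, 4] <- f4
  L[2, 1] <- s[1]
  L[3, 2] <- s[2]
  L[4, 3] <- s[3]
  L[5, 4] <- s[4]
  L[5, 5] <- s[5]
  L
}

#' Project stage counts one time step forward
#'
#' Returns `L %*% n`: componentwise, `n1' = f4 n4`, `n2' = s1 n1`,
#' `n3' = s2 n2`, `n4' = s3 n3`, `n5' = s4 n4 + s5 n5`.
#'
#' @param L A 5x5 projection matrix (see [projection_matrix()]).
#' @param n Non-negative vector of 5 stage counts.
#' @return The projected count vector.
#' @export
advance_counts <- function(L, n) {
  if (length(n) != 5L || any(n < 0) || anyNA(n))
    stop("`n` must be 5 non-negative counts")
  drop(L %*% n)
}

#' Dominant eigenvalue (asymptotic growth factor) of a projection matrix
#'
#' The spectral radius of a non-negative projection matrix, which for this
#' model equals its Perron-Frobenius eigenvalue: the long-run per-step
#' population growth factor.  Used for validating simulated growth against
#' matrix theory.
#'
#' @param L A non-negative square matrix.
#' @return The spectral radius, a non-negative number.
#' @seealso [stable_stage_distribution()]
#' @export
dominant_eigenvalue <- function(L) {
  if (any(L < 0)) stop("`L` must be non-negative")
  max(Mod(eigen(L, only.values = TRUE)$values))
}

#' Stable stage distribution of a projection matrix
#'
#' The right eigenvector associated with the dominant eigenvalue, normalized
#' to sum to 1: the long-run proportions of the population in each stage.
#'
#' @param L A non-negative square matrix.
#' @return A probability vector of length `nrow(L)`.
#' @export
stable_stage_distribution <- function(L) {
  if (any(L < 0)) stop("`L` must be non-negative")
  e <- eigen(L)
  # with a single reproductive stage the matrix is imprimitive and several
  # eigenvalues share the spectral radius; the Perron root is the one closest
  # to the positive real value rho
  rho <- max(Mod(e$values))
  k <- which.min(Mod(e$values - rho))
  v <- abs(Re(e$vectors[, k]))
  v / sum(v)
}
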