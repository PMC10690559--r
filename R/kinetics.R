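#' @useDynLib ctdnakin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif setNames integrate dnorm sd median
#' @importFrom utils read.csv write.csv modifyList
NULL

# canonical parameter order used everywhere; gamma_deg is a fixed constant
.FULL_PAR_ORDER <- c("B0", "c0pb", "gamma_d", "s_c", "alpha", "gamma_t")

.MODEL_PARS <- list(
  one_step   = c("c0pb", "alpha"),
  two_step   = c("B0", "c0pb", "alpha", "gamma_t"),
  three_step = c("B0", "c0pb", "gamma_d", "s_c", "alpha", "gamma_t")
)
.MODEL_STATES <- list(
  one_step   = "cpb",
  two_step   = c("B", "cpb"),
  three_step = c("B", "cbm", "cpb")
)
.MODEL_OBS <- list(
  one_step   = "y_ctdna",
  two_step   = c("y_ctdna", "y_blast"),
  three_step = c("y_ctdna", "y_blast")
)

# two rates are treated as equal when |a - b| <= tol * max(a, b)
.RATE_MERGE_TOL <- 1e-8

.kind_code <- function(kind) match(kind, c("one_step", "two_step", "three_step"))

#' Kinetic model definition
#'
#' Defines one of the three compartment models of ctDNA kinetics during
#' induction chemotherapy:
#' \describe{
#'   \item{one_step}{exponential decay of peripheral-blood ctDNA:
#'     \eqn{\dot c_{pb} = -\gamma_{deg} c_{pb}}; observable
#'     \eqn{y = \alpha c_{pb}}.}
#'   \item{two_step}{bone-marrow blasts release ctDNA directly into blood:
#'     \eqn{\dot B = -\gamma_t B}, \eqn{\dot c_{pb} = \gamma_t B -
#'     \gamma_{deg} c_{pb}}; observables \eqn{\alpha c_{pb}} and \eqn{B}.}
#'   \item{three_step}{dying blasts release ctDNA in the bone marrow, which
#'     then transits to blood: \eqn{\dot B = -\gamma_d B},
#'     \eqn{\dot c_{bm} = \gamma_d B - \gamma_t c_{bm}},
#'     \eqn{\dot c_{pb} = \gamma_t c_{bm} - \gamma_{deg} c_{pb}}.}
#' }
#'
#' The per-model parameter vectors follow the fixed canonical order
#' `B0, c0pb, gamma_d, s_c, alpha, gamma_t` (subset per model);
#' `gamma_deg` is a fixed constant, 33/day by default.
#'
#' @param kind one of `"one_step"`, `"two_step"`, `"three_step"`.
#' @return an object of class `kinetic_model` with fields `kind`,
#'   `state_names`, `parameter_names`, `observable_names`.
#' @export
#' @examples
#' kinetic_model("three_step")
kinetic_model <- function(kind = c("one_step", "two_step", "three_step")) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 state_names = .MODEL_STATES[[kind]],
                 parameter_names = .MODEL_PARS[[kind]],
                 observable_names = .MODEL_OBS[[kind]]),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("<kinetic_model>", x$kind, "\n")
  cat("  states:     ", paste(x$state_names, collapse = ", "), "\n")
  cat("  parameters: ", paste(x$parameter_names, collapse = ", "),
      " (gamma_deg fixed)\n", sep = "")
  cat("  observables:", paste(x$observable_names, collapse = ", "), "\n")
  invisible(x)
}

.as_model <- function(model) {
  if (inherits(model, "kinetic_model")) model else kinetic_model(model)
}

#' Default fixed ctDNA degradation rate (1/day)
#'
#' The degradation rate of cell-free DNA in peripheral blood is treated as a
#' fixed constant, 33/day, corresponding to a half-life of about 30 minutes.
#' It is never estimated.
#'
#' @return numeric scalar, 33.
#' @export
gamma_deg_default <- function() 33

#' Convert a half-life to a first-order decay rate
#'
#' @param half_life_minutes half-life in minutes (> 0).
#' @return decay rate in 1/day, `log(2) * 1440 / half_life_minutes`.
#' @export
#' @examples
#' decay_rate_from_half_life(30) # ~33.3/day, rounded to the fixed 33/day
decay_rate_from_half_life <- function(half_life_minutes) {
  if (!is.numeric(half_life_minutes) || any(half_life_minutes <= 0))
    stop("half_life_minutes must be positive")
  log(2) * 1440 / half_life_minutes
}

#' Patient-level natural-scale parameter vector
#'
#' Assembles and validates the natural-scale kinetic parameters of one
#' patient. All entries are strictly positive; `s_c >= 1` so that the
#' peripheral-blood ctDNA gradient at treatment start is non-negative;
#' `alpha <= 1` (fraction of total ctDNA carrying the assayed mutation).
#'
#' @param B0 blast cells in bone marrow at treatment start (count).
#' @param c0pb total ctDNA molecules in peripheral blood at t = 0 (count).
#' @param gamma_d blast death rate (1/day).
#' @param s_c initial bone-marrow ctDNA scaling factor (dimensionless, >= 1).
#' @param alpha measured-mutation fraction of total ctDNA, in (0, 1].
#' @param gamma_t bone-marrow to blood transition rate (1/day).
#' @param gamma_deg fixed ctDNA degradation rate (1/day).
#' @return an object of class `effect_vector` (named numeric vector plus
#'   `gamma_deg` attribute).
#' @export
effect_vector <- function(B0 = 1, c0pb = 1, gamma_d = 1, s_c = 1, alpha = 1,
                          gamma_t = 1, gamma_deg = gamma_deg_default()) {
  v <- c(B0 = B0, c0pb = c0pb, gamma_d = gamma_d, s_c = s_c, alpha = alpha,
         gamma_t = gamma_t)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all effect entries must be finite and strictly positive")
  if (s_c < 1) stop("s_c must be >= 1 (non-negative ctDNA gradient at t = 0)")
  if (alpha > 1) stop("alpha must be <= 1")
  if (!is.finite(gamma_deg) || gamma_deg <= 0) stop("gamma_deg must be > 0")
  structure(v, gamma_deg = gamma_deg, class = "effect_vector")
}

.gdeg_of <- function(params) {
  g <- attr(params, "gamma_deg")
  if (is.null(g)) gamma_deg_default() else g
}

.full_par <- function(params) {
  unname(params[.FULL_PAR_ORDER])
}

#' Implied initial bone-marrow ctDNA amount
#'
#' `c0bm = (gamma_deg / gamma_t) * c0pb * s_c`, the smallest initial
#' bone-marrow ctDNA pool (scaled by `s_c >= 1`) for which the
#' peripheral-blood ctDNA gradient at t = 0 is non-negative.
#'
#' @param params an [effect_vector()].
#' @return numeric scalar.
#' @export
c0bm_implied <- function(params) {
  .gdeg_of(params) / params[["gamma_t"]] * params[["c0pb"]] * params[["s_c"]]
}

#' Right-hand side of the model ODEs
#'
#' @param model a [kinetic_model()] or kind string.
#' @param state named or ordered numeric state vector (non-negative).
#' @param params an [effect_vector()].
#' @return derivative of each state (1/day), named as the model's states.
#' @export
rhs <- function(model, state, params) {
  model <- .as_model(model)
  if (length(state) != length(model$state_names))
    stop("state length does not match model '", model$kind, "'")
  if (any(state < 0)) stop("state must be non-negative")
  gdeg <- .gdeg_of(params)
  out <- switch(model$kind,
    one_step = c(cpb = -gdeg * state[[1]]),
    two_step = {
      gt <- params[["gamma_t"]]
      c(B = -gt * state[[1]], cpb = gt * state[[1]] - gdeg * state[[2]])
    },
    three_step = {
      gd <- params[["gamma_d"]]; gt <- params[["gamma_t"]]
      c(B = -gd * state[[1]],
        cbm = gd * state[[1]] - gt * state[[2]],
        cpb = gt * state[[2]] - gdeg * state[[3]])
    })
  out
}

#' Initial state of a kinetic model
#'
#' For the three-step model the initial bone-marrow ctDNA is set to
#' `c0bm = (gamma_deg / gamma_t) * c0pb * s_c` so that the t = 0 gradient of
#' peripheral-blood ctDNA is non-negative (with equality at `s_c = 1`).
#'
#' @inheritParams rhs
#' @return named numeric state vector at t = 0.
#' @export
initial_state <- function(model, params) {
  model <- .as_model(model)
  if (params[["s_c"]] < 1) stop("s_c must be >= 1")
  switch(model$kind,
    one_step = c(cpb = params[["c0pb"]]),
    two_step = c(B = params[["B0"]], cpb = params[["c0pb"]]),
    three_step = c(B = params[["B0"]], cbm = unname(c0bm_implied(params)),
                   cpb = params[["c0pb"]]))
}

.check_times <- function(times) {
  if (length(times) == 0 || any(!is.finite(times)))
    stop("times must be finite")
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times, strictly = FALSE)) stop("times must be ascending")
  as.numeric(times)
}

#' Closed-form model trajectory
#'
#' Evaluates the analytic solution of the chosen model at the given times.
#' All exponential terms are computed with confluent divided differences of
#' `exp(-r t)`, so every rate-degeneracy branch (`gamma_deg = gamma_t =
#' gamma_d` and all partial coincidences) is covered by the same uniformly
#' stable closed form; rates closer than a relative `1e-8` are treated as
#' equal (`branch = "auto"`). `branch = "generic"` disables the rate merge
#' and forces the distinct-rate treatment, which is useful for
#' branch-continuity checks.
#'
#' @inheritParams rhs
#' @param times ascending non-negative vector of days since treatment start.
#' @param branch `"auto"` (tolerance-based degeneracy handling, default) or
#'   `"generic"`.
#' @return object of class `trajectory`: list with `times`, `states`
#'   (time x state matrix), `observables` (time x observable matrix,
#'   `y_ctdna = alpha * cpb`, `y_blast = B`) and the degeneracy `branch`
#'   label.
#' @export
#' @examples
#' m <- kinetic_model("three_step")
#' p <- effect_vector(B0 = 1e12, c0pb = 1e6, gamma_d = 0.5, s_c = 2,
#'                    alpha = 0.2, gamma_t = 3)
#' tr <- solve_analytic(m, p, seq(0, 21, by = 1))
solve_analytic <- function(model, params, times, branch = c("auto", "generic")) {
  model <- .as_model(model)
  branch <- match.arg(branch)
  times <- .check_times(times)
  tol <- if (branch == "auto") .RATE_MERGE_TOL else 0
  out <- cpp_eval_kinetics(.kind_code(model$kind), .full_par(params),
                           .gdeg_of(params), times, FALSE, tol)
  states <- out$states
  colnames(states) <- model$state_names
  y <- out$y
  colnames(y) <- model$observable_names
  structure(list(times = times, states = states, observables = y,
                 branch = classify_branch(model, params)),
            class = "trajectory")
}

#' Degeneracy branch of the active decay rates
#'
#' Classifies which of the model's rates coincide, using the documented
#' relative tolerance `1e-8`.
#'
#' @inheritParams rhs
#' @return character branch label.
#' @export
classify_branch <- function(model, params) {
  model <- .as_model(model)
  eq <- function(a, b) abs(a - b) <= .RATE_MERGE_TOL * max(a, b)
  gdeg <- .gdeg_of(params)
  if (model$kind == "one_step") return("single_rate")
  if (model$kind == "two_step")
    return(if (eq(params[["gamma_t"]], gdeg)) "gdeg_eq_gt" else "distinct")
  gd <- params[["gamma_d"]]; gt <- params[["gamma_t"]]
  e1 <- eq(gd, gt); e2 <- eq(gt, gdeg); e3 <- eq(gd, gdeg)
  if (sum(c(e1, e2, e3)) >= 2) "all_equal"
  else if (e1) "gt_eq_gd"
  else if (e2) "gdeg_eq_gt"
  else if (e3) "gdeg_eq_gd"
  else "distinct"
}

#' Numerical reference trajectory (matrix-exponential oracle)
#'
#' Independent oracle for [solve_analytic()]: the models are linear
#' time-invariant systems `x' = M x`, so the exact solution is
#' `expm(M t) x0`, evaluated with [Matrix::expm()]. This path shares no code
#' with the closed forms and is used throughout the test-suite as ground
#' truth.
#'
#' @inheritParams solve_analytic
#' @return object of class `trajectory`.
#' @export
solve_numeric <- function(model, params, times) {
  model <- .as_model(model)
  times <- .check_times(times)
  gdeg <- .gdeg_of(params)
  M <- switch(model$kind,
    one_step = matrix(-gdeg, 1, 1),
    two_step = {
      gt <- params[["gamma_t"]]
      matrix(c(-gt, 0, gt, -gdeg), 2, 2, byrow = TRUE)
    },
    three_step = {
      gd <- params[["gamma_d"]]; gt <- params[["gamma_t"]]
      matrix(c(-gd, 0, 0, gd, -gt, 0, 0, gt, -gdeg), 3, 3, byrow = TRUE)
    })
  x0 <- initial_state(model, params)
  states <- matrix(vapply(times, function(tt)
    as.numeric(Matrix::expm(M * tt) %*% x0), numeric(length(x0))),
    ncol = length(x0), byrow = TRUE)
  colnames(states) <- model$state_names
  y <- cbind(y_ctdna = params[["alpha"]] * states[, "cpb"])
  if (model$kind != "one_step") y <- cbind(y, y_blast = states[, "B"])
  structure(list(times = times, states = states, observables = y,
                 branch = classify_branch(model, params)),
            class = "trajectory")
}

#' Analytic parameter sensitivities of the observables
#'
#' Returns \eqn{\partial y / \partial \theta} on the natural parameter scale
#' for every parameter in the model's `parameter_names`, at each time and
#' observable, including all rate-degeneracy branches. The coupling of the
#' initial bone-marrow ctDNA `c0bm` to `(c0pb, s_c, gamma_t)` is applied by
#' the chain rule.
#'
#' @inheritParams solve_analytic
#' @return object of class `sensitivity_tensor`: list with `times` and
#'   `d_observable_d_parameter`, a `time x observable x parameter` array.
#' @export
sensitivities_analytic <- function(model, params, times,
                                   branch = c("auto", "generic")) {
  model <- .as_model(model)
  branch <- match.arg(branch)
  times <- .check_times(times)
  tol <- if (branch == "auto") .RATE_MERGE_TOL else 0
  out <- cpp_eval_kinetics(.kind_code(model$kind), .full_par(params),
                           .gdeg_of(params), times, TRUE, tol)
  dy <- out$dy
  dimnames(dy) <- list(NULL, model$observable_names, model$parameter_names)
  structure(list(times = times, d_observable_d_parameter = dy),
            class = "sensitivity_tensor")
}

#' Estimated-parameter counts of a model
#'
#' Population parameters = mixed-effect means + random-effect variances +
#' shared fixed effects (`gamma_t` where present) + the ctDNA noise standard
#' deviation. Patient-specific parameters = the mixed effects.
#'
#' @inheritParams rhs
#' @return named integer vector `c(population, patient_specific)`:
#'   one-step (5, 2), two-step (8, 3), three-step (12, 5).
#' @export
count_parameters <- function(model) {
  model <- .as_model(model)
  q <- switch(model$kind, one_step = 2L, two_step = 3L, three_step = 5L)
  n_fixed_only <- if (model$kind == "one_step") 0L else 1L
  c(population = q + q + n_fixed_only + 1L, patient_specific = q)
}

#' Export a trajectory as a tidy data frame
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return data frame with columns `time_days`, `name`, `value` covering all
#'   states and observables.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  cols <- cbind(x$states, x$observables)
  data.frame(time_days = rep(x$times, ncol(cols)),
             name = rep(colnames(cols), each = length(x$times)),
             value = as.vector(cols), row.names = NULL)
}
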