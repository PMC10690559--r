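# Numerical structural-identifiability diagnostics: rank of the Fisher
# information (sensitivity) matrix on a time grid, with near-null
# directions, replacing symbolic observability analysis.

#' Sensitivity-rank identifiability analysis
#'
#' Stacks the log-parameter sensitivities `d log y / d log theta` of the
#' observed outputs over the time grid and computes the numerical rank via
#' singular values. Singular values below `1e-10` times the largest are
#' counted as null; the corresponding right singular vectors are the
#' non-identifiable parameter directions (in log-parameter space).
#'
#' Expected results for generic parameters: the one-step model observed
#' through ctDNA alone has rank deficiency 1 with null direction
#' proportional to `(d/d log c0pb - d/d log alpha)` (only the product
#' `c0pb * alpha` is identifiable); two- and three-step models are full
#' rank with both observables; the three-step model loses exactly one
#' direction when only ctDNA is observed.
#'
#' @param model a [kinetic_model()] or kind string.
#' @param params an [effect_vector()] with generic (non-degenerate) rates.
#' @param observed subset of the model's observables.
#' @param times time grid (needs at least as many points as parameters).
#' @return object of class `identifiability_report` with `model`,
#'   `observed`, `fim_rank`, `n_parameters`, `singular_values`,
#'   `null_directions` (columns = unit vectors, rows named by parameter)
#'   and `verdict` (`"identifiable"` or `"rank_deficient"`).
#' @export
fim_rank_analysis <- function(model, params,
                              observed = NULL,
                              times = seq(0, 18, length.out = 30)) {
  model <- .as_model(model)
  if (is.null(observed)) observed <- model$observable_names
  if (!all(observed %in% model$observable_names))
    stop("observed must be a subset of the model's observables")
  if (length(times) < length(model$parameter_names))
    stop("need at least as many time points as parameters")
  if (model$kind != "one_step" &&
      classify_branch(model, params) != "distinct")
    warning("degenerate rates: rank may be inflated at branch boundaries")
  sens <- sensitivities_analytic(model, params, times)
  tr <- solve_analytic(model, params, times)
  pn <- model$parameter_names
  blocks <- lapply(observed, function(o) {
    y <- tr$observables[, o]
    J <- vapply(pn, function(p)
      params[[p]] * sens$d_observable_d_parameter[, o, p] /
        pmax(abs(y), 1e-300),
      numeric(length(times)))
    J
  })
  J <- do.call(rbind, blocks)
  sv <- svd(J)
  thresh <- 1e-10 * sv$d[1]
  rank <- sum(sv$d > thresh)
  null_idx <- which(sv$d <= thresh)
  nd <- sv$v[, null_idx, drop = FALSE]
  rownames(nd) <- pn
  structure(list(model = model$kind, observed = observed,
                 fim_rank = rank, n_parameters = length(pn),
                 singular_values = sv$d, null_directions = nd,
                 verdict = if (rank == length(pn)) "identifiable"
                           else "rank_deficient"),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report>", x$model, "observing",
      paste(x$observed, collapse = " + "), "\n")
  cat("  rank ", x$fim_rank, " of ", x$n_parameters, " -> ", x$verdict,
      "\n", sep = "")
  if (ncol(x$null_directions) > 0) {
    cat("  null direction(s) in log-parameter space:\n")
    print(round(x$null_directions, 4))
  }
  invisible(x)
}

#' Validate analytic sensitivities against finite differences
#'
#' For seeded random parameter draws per degeneracy branch, compares the
#' analytic sensitivities with central finite differences of the
#' matrix-exponential reference solution ([solve_numeric()]). The outputs
#' are exactly linear in `B0`, `c0pb`, `s_c` and `alpha`, so those use a
#' large central step (no truncation error, far less subtractive
#' cancellation); the rates use a relative step of `1e-6`. Discrepancies
#' are normalized per (observable, parameter) by the largest sensitivity
#' magnitude over the grid. Failures (> 1e-4) are reported, not raised.
#'
#' @param model a [kinetic_model()] or kind string.
#' @param n_random_params draws per branch.
#' @param seed integer seed.
#' @param times evaluation grid.
#' @return data frame with columns `branch`, `draw`, `observable`,
#'   `parameter`, `max_rel_discrepancy`, `ok`.
#' @export
validate_sensitivities <- function(model, n_random_params = 5, seed = 1,
                                   times = seq(0.1, 18, length.out = 12)) {
  model <- .as_model(model)
  set.seed(seed)
  branches <- switch(model$kind,
    one_step = "single_rate",
    two_step = c("distinct", "gdeg_eq_gt"),
    three_step = c("distinct", "gt_eq_gd", "gdeg_eq_gt", "gdeg_eq_gd",
                   "all_equal"))
  draw_params <- function(branch) {
    p <- list(B0 = 10^runif(1, 10.5, 12), c0pb = 10^runif(1, 4, 8),
              gamma_d = 10^runif(1, -1, 0.8), s_c = 1 + 10^runif(1, -1, 1),
              alpha = 10^runif(1, -3, -0.01), gamma_t = 10^runif(1, -0.5, 1.2),
              gamma_deg = gamma_deg_default())
    if (model$kind == "two_step" && branch == "gdeg_eq_gt")
      p$gamma_t <- p$gamma_deg
    if (model$kind == "three_step") {
      if (branch == "gt_eq_gd") p$gamma_t <- p$gamma_d
      if (branch == "gdeg_eq_gt") p$gamma_t <- p$gamma_deg
      if (branch == "gdeg_eq_gd") p$gamma_d <- p$gamma_deg
      if (branch == "all_equal") {
        p$gamma_t <- p$gamma_d
        p$gamma_deg <- p$gamma_d
      }
    }
    do.call(effect_vector, p)
  }
  rows <- list()
  for (br in branches) {
    for (dr in seq_len(n_random_params)) {
      params <- draw_params(br)
      an <- sensitivities_analytic(model, params, times)
      for (pnm in model$parameter_names) {
        h <- if (pnm %in% c("B0", "c0pb", "s_c", "alpha")) {
          # outputs are linear in these, so a large step is exact
          v <- params[[pnm]]
          switch(pnm,
                 s_c = min(0.5 * v, 0.9 * (v - 1)),
                 alpha = min(0.5 * v, 0.9 * (1 - v)),
                 0.5 * v)
        } else 1e-6 * params[[pnm]]
        bump <- function(s) {
          pl <- as.list(unclass(params))
          pl[[pnm]] <- pl[[pnm]] + s
          pl$gamma_deg <- .gdeg_of(params)
          suppressWarnings(do.call(effect_vector, pl))
        }
        yp <- solve_numeric(model, bump(h), times)$observables
        ym <- solve_numeric(model, bump(-h), times)$observables
        fd <- (yp - ym) / (2 * h)
        for (o in model$observable_names) {
          a <- an$d_observable_d_parameter[, o, pnm]
          scale <- max(abs(fd[, o]), abs(a), 1e-300)
          disc <- max(abs(a - fd[, o])) / scale
          rows[[length(rows) + 1]] <- data.frame(
            branch = br, draw = dr, observable = o, parameter = pnm,
            max_rel_discrepancy = disc, ok = disc <= 1e-4)
        }
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
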