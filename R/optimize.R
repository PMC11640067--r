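#' Specify the constrained blend optimization
#'
#' The optimization seeks the flaxseed fraction whose predicted
#' characteristics are closest to a reference (control) oil, under
#' per-group importance weights, subject to minimum predicted sensory
#' scores.
#'
#' Each output's squared deviation from its target is divided by a
#' per-output scale before group averaging. Two scale conventions are
#' combined (see the methods vignette for the full rationale): the
#' oxidation-quality outputs are scaled by the magnitude of their control
#' value, so that a p-anisidine value four times the control's counts as a
#' large difference; all other outputs are scaled by their observed span
#' across the samples and the control, which bounds each contribution near
#' 1 regardless of units. Outputs with zero scale carry no information and
#' are dropped with a warning.
#'
#' @param samples A `blend_samples` object providing the observed spans and
#'   (by default) the control targets; may be `NULL` when both `control`
#'   and `scales` are supplied.
#' @param control Named vector of target values for the modelled outputs;
#'   defaults to the control sample's measurements with `deltaE = 0` (the
#'   control is the colour reference).
#' @param weights Group importance weights (must be non-negative and sum to
#'   1). Default: sensory 0.20, colour 0.15, quality 0.40, fatty acids
#'   0.25.
#' @param threshold Minimum admissible predicted sensory score (0--5 scale,
#'   default 2.8).
#' @param constrained Sensory outputs the threshold applies to (default all
#'   five).
#' @param resolution Grid resolution in percentage points of flaxseed share
#'   (default 0.1).
#' @param scales Optional named vector overriding the per-output deviation
#'   scales.
#' @return An object of class `optimization_spec`.
#' @export
optimization_spec <- function(samples = NULL,
                              control = NULL,
                              weights = c(sensory = 0.20, color = 0.15,
                                          quality = 0.40,
                                          fatty_acids = 0.25),
                              threshold = 2.8,
                              constrained = blend_variables("sensory"),
                              resolution = 0.1,
                              scales = NULL) {
  groups <- variable_groups()
  outputs <- names(groups)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop("group weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(weights), unique(groups))) {
    stop("weights must name the groups: ",
         paste(unique(groups), collapse = ", "), call. = FALSE)
  }
  if (threshold < 0 || threshold > 5) {
    stop("sensory threshold must lie in [0, 5]", call. = FALSE)
  }
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  stopifnot(all(constrained %in% blend_variables("sensory")))

  if (is.null(samples) && (is.null(control) || is.null(scales))) {
    stop("samples are required unless both control and scales are given",
         call. = FALSE)
  }
  if (is.null(control)) {
    control <- sample_values(samples, "Control")
    control <- control[names(control) %in% outputs]
    control["deltaE"] <- 0
  }
  missing <- setdiff(outputs, names(control))
  if (length(missing) > 0) {
    stop("control targets missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  control <- control[outputs]

  if (is.null(scales)) {
    obs <- blend_matrix(samples, outputs, include_control = FALSE)
    span <- apply(rbind(obs, control), 2, function(col)
      diff(range(col, na.rm = TRUE)))
    scales <- span
    qv <- blend_variables("quality")
    scales[qv] <- abs(control[qv])
  } else {
    scales <- scales[outputs]
  }
  drop <- names(scales)[!is.finite(scales) | scales == 0]
  if (length(drop) > 0) {
    warning("dropping zero-scale outputs from the objective: ",
            paste(drop, collapse = ", "), call. = FALSE)
  }
  structure(list(control = control, weights = weights,
                 threshold = threshold, constrained = constrained,
                 resolution = resolution, scales = scales,
                 active = setdiff(outputs, drop), groups = groups),
            class = "optimization_spec")
}

# predictions for a vector of flaxseed fractions, rows = fractions
.predict_fraction <- function(model, f) {
  x <- cbind(s_share = 100 * (1 - f), f_share = 100 * f)
  if (inherits(model, "mlp_ensemble")) ensemble_forward(model, x)
  else mlp_forward(model, x)
}

#' Group-weighted objective of the blend optimization
#'
#' `J(f) = sum_g w_g * mean_{k in g} ((pred_k(f) - target_k) / scale_k)^2`,
#' evaluated on the surrogate's predictions at flaxseed fraction `f`.
#'
#' @param model An [mlp_surrogate()] or [surrogate_ensemble()].
#' @param spec An [optimization_spec()].
#' @param f Flaxseed fraction(s) in \[0, 1\].
#' @return Numeric vector of objective values.
#' @export
blend_objective <- function(model, spec, f) {
  stopifnot(inherits(spec, "optimization_spec"))
  if (any(f < 0 | f > 1)) {
    stop("flaxseed fraction must lie in [0, 1]", call. = FALSE)
  }
  act <- spec$active
  bad <- act[!is.finite(spec$scales[act]) | spec$scales[act] == 0]
  if (length(bad) > 0) {
    stop("zero deviation scale for output: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pred <- .predict_fraction(model, f)
  dev2 <- sweep(sweep(pred[, act, drop = FALSE], 2, spec$control[act]), 2,
                spec$scales[act], "/")^2
  vapply(seq_along(f), function(i) {
    sum(vapply(names(spec$weights), function(g) {
      cols <- act[spec$groups[act] == g]
      spec$weights[[g]] * mean(dev2[i, cols])
    }, numeric(1)))
  }, numeric(1))
}

#' Find the optimal blend composition
#'
#' Exhaustive grid search of the flaxseed fraction over \[0, 1\] at the
#' spec's resolution. Grid points whose predicted constrained sensory
#' scores fall below the threshold are infeasible; among feasible points
#' the minimizer of [blend_objective()] is returned, ties broken toward the
#' lower flaxseed share. If no point is feasible the least-violating
#' candidate is reported with `feasible = FALSE`.
#'
#' @inheritParams blend_objective
#' @return An object of class `blend_optimum`: a list with the optimal
#'   shares, the 28 predicted values at the optimum, the objective value,
#'   per-constraint slacks and the feasibility flag.
#' @export
optimize_blend <- function(model, spec) {
  stopifnot(inherits(spec, "optimization_spec"))
  f <- seq(0, 100, by = spec$resolution) / 100
  J <- blend_objective(model, spec, f)
  pred <- .predict_fraction(model, f)
  slack <- pred[, spec$constrained, drop = FALSE] - spec$threshold
  feas <- apply(slack >= 0, 1, all)
  if (any(feas)) {
    cand <- which(feas)
    best <- cand[which.min(J[cand])]  # which.min takes the first: lower f wins ties
    feasible <- TRUE
  } else {
    best <- which.max(apply(slack, 1, min))
    feasible <- FALSE
  }
  structure(list(
    f_opt = f[best],
    flaxseed_share = 100 * f[best],
    sunflower_share = 100 * (1 - f[best]),
    predicted = stats::setNames(pred[best, ], colnames(pred)),
    objective = J[best],
    slack = stats::setNames(slack[best, ], spec$constrained),
    feasible = feasible
  ), class = "blend_optimum")
}

#' @export
print.blend_optimum <- function(x, ...) {
  cat(sprintf("Optimal blend: %.1f%% sunflower / %.1f%% flaxseed (%s)\n",
              x$sunflower_share, x$flaxseed_share,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  cat(sprintf("  objective J = %.4f; min sensory slack = %.3f (%s)\n",
              x$objective, min(x$slack), names(x$slack)[which.min(x$slack)]))
  invisible(x)
}
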