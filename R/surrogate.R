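# ---- min-max scaling -------------------------------------------------------

#' Fit a min-max scaler mapping columns to [-1, 1]
#'
#' Columns with zero span are mapped to 0 and descaled back to their
#' constant value.
#'
#' @param x Numeric matrix.
#' @return A `minmax_scaler` (list with `min` and `max` per column).
#' @export
minmax_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_scaler")
}

#' Apply / invert a min-max scaler
#'
#' @param x Numeric matrix (columns in scaler order).
#' @param scaler A [minmax_scaler()].
#' @return The scaled (to \[-1, 1\]) or descaled matrix.
#' @export
scale_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  span <- scaler$max - scaler$min
  out <- sweep(sweep(x, 2, scaler$min), 2, ifelse(span == 0, 1, span), "/")
  out <- 2 * out - 1
  out[, span == 0] <- 0
  out
}

#' @rdname scale_minmax
#' @export
descale_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  span <- scaler$max - scaler$min
  out <- sweep(sweep((x + 1) / 2, 2, span, "*"), 2, scaler$min, "+")
  for (j in which(span == 0)) out[, j] <- scaler$min[j]
  out
}

# ---- model object ----------------------------------------------------------

.activations <- list(
  identity    = list(f = function(z) z, df = function(z, a) rep(1, length(z))),
  exponential = list(f = function(z) exp(z), df = function(z, a) a),
  logistic    = list(f = function(z) 1 / (1 + exp(-z)),
                     df = function(z, a) a * (1 - a)),
  tanh        = list(f = function(z) tanh(z), df = function(z, a) 1 - a^2)
)

#' Construct a multilayer-perceptron surrogate
#'
#' A single-hidden-layer network `Y = f1(W2 f2(W1 X + B1) + B2)` mapping the
#' scaled blend shares to the scaled output characteristics, together with
#' the min-max scalers that translate between physical units and network
#' units.
#'
#' @param W1 Hidden-layer weight matrix (hidden x inputs).
#' @param b1 Hidden-layer bias vector.
#' @param W2 Output-layer weight matrix (outputs x hidden).
#' @param b2 Output-layer bias vector.
#' @param hidden_activation,output_activation Activation names; one of
#'   `"identity"`, `"exponential"`, `"logistic"`, `"tanh"`.
#' @param x_scaler,y_scaler [minmax_scaler()]s for inputs and outputs; pass
#'   `NULL` for networks operating directly in physical units.
#' @param outputs Character vector naming the outputs (row order of `W2`).
#' @param inputs Character vector naming the inputs (default
#'   `c("s_share", "f_share")`).
#' @return An object of class `mlp_surrogate`.
#' @export
mlp_surrogate <- function(W1, b1, W2, b2,
                          hidden_activation = "exponential",
                          output_activation = "identity",
                          x_scaler = NULL, y_scaler = NULL,
                          outputs = NULL,
                          inputs = c("s_share", "f_share")) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  hidden_activation <- match.arg(hidden_activation, names(.activations))
  output_activation <- match.arg(output_activation, names(.activations))
  if (nrow(W1) != length(b1) || ncol(W2) != nrow(W1) ||
      nrow(W2) != length(b2) || ncol(W1) != length(inputs)) {
    stop("inconsistent network dimensions", call. = FALSE)
  }
  if (is.null(outputs)) outputs <- paste0("y", seq_len(nrow(W2)))
  if (length(outputs) != nrow(W2)) {
    stop("outputs must name the rows of W2", call. = FALSE)
  }
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 x_scaler = x_scaler, y_scaler = y_scaler,
                 outputs = outputs, inputs = inputs),
            class = "mlp_surrogate")
}

# forward pass in scaled (network) units
.mlp_forward_scaled <- function(m, Xs) {
  act_h <- .activations[[m$hidden_activation]]
  act_o <- .activations[[m$output_activation]]
  H <- act_h$f(sweep(Xs %*% t(m$W1), 2, m$b1, "+"))
  act_o$f(sweep(H %*% t(m$W2), 2, m$b2, "+"))
}

#' Evaluate the surrogate at blend shares
#'
#' Scales the inputs, runs the forward pass
#' `f1(W2 f2(W1 X + B1) + B2)`, and descales every output back to its
#' physical units.
#'
#' @param m An [mlp_surrogate()].
#' @param x Input matrix (rows are samples, columns follow `m$inputs`) or a
#'   single input vector.
#' @return Matrix of predictions (rows match `x`, columns `m$outputs`).
#' @export
#' @examples
#' m <- mlp_surrogate(W1 = matrix(c(1, 1), 1), b1 = 0,
#'                    W2 = matrix(0.5), b2 = 0.1,
#'                    hidden_activation = "exponential")
#' mlp_forward(m, c(0.3, 0.7))  # 0.5 * exp(1) + 0.1
mlp_forward <- function(m, x) {
  stopifnot(inherits(m, "mlp_surrogate"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(m$W1)) {
    stop("input has ", ncol(x), " columns; model expects ", ncol(m$W1),
         call. = FALSE)
  }
  Xs <- if (is.null(m$x_scaler)) x else scale_minmax(x, m$x_scaler)
  Ys <- .mlp_forward_scaled(m, Xs)
  out <- if (is.null(m$y_scaler)) Ys else descale_minmax(Ys, m$y_scaler)
  colnames(out) <- m$outputs
  out
}

#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  mlp_forward(object, newdata)
}

# ---- training --------------------------------------------------------------

.par_split <- function(par, h, p, q) {
  i <- 0
  W1 <- matrix(par[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(q * h)], q, h); i <- i + q * h
  b2 <- par[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# sum-of-squares loss and analytic gradient in scaled units
.mlp_sos <- function(par, Xs, Ts, h, act_h) {
  p <- ncol(Xs); q <- ncol(Ts)
  w <- .par_split(par, h, p, q)
  Z <- sweep(Xs %*% t(w$W1), 2, w$b1, "+")
  if (any(abs(Z) > 50)) return(1e12 + sum(pmax(abs(Z) - 50, 0)))
  H <- .activations[[act_h]]$f(Z)
  Y <- sweep(H %*% t(w$W2), 2, w$b2, "+")
  sum((Y - Ts)^2)
}

.mlp_sos_grad <- function(par, Xs, Ts, h, act_h) {
  p <- ncol(Xs); q <- ncol(Ts)
  w <- .par_split(par, h, p, q)
  Z <- sweep(Xs %*% t(w$W1), 2, w$b1, "+")
  if (any(abs(Z) > 50)) {
    # gradient of the overflow-guard penalty
    dZ <- sign(Z) * (abs(Z) > 50)
    return(c(as.vector(t(dZ) %*% Xs), colSums(dZ),
             rep(0, q * h), rep(0, q)))
  }
  act <- .activations[[act_h]]
  H <- act$f(Z)
  Y <- sweep(H %*% t(w$W2), 2, w$b2, "+")
  dY <- 2 * (Y - Ts)
  dW2 <- t(dY) %*% H
  db2 <- colSums(dY)
  dZ <- (dY %*% w$W2) * act$df(Z, H)
  dW1 <- t(dZ) %*% Xs
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}

.fit_once <- function(Xs, Ts, h, act_h, maxit, decay) {
  p <- ncol(Xs); q <- ncol(Ts)
  W1_0 <- matrix(stats::runif(h * p, -0.5, 0.5), h, p)
  if (p == 2) {
    # complementary blend shares scale to exactly opposite inputs, which
    # makes per-input weights non-identifiable; an antisymmetric start is
    # preserved by the gradient flow and keeps the attribution meaningful
    W1_0[, 1] <- -W1_0[, 2]
  }
  par <- c(as.vector(W1_0), stats::runif(h, -0.1, 0.1),
           stats::runif(q * h, -0.5, 0.5) / h, rep(0, q))
  fit <- tryCatch(
    stats::optim(par,
                 function(p_) .mlp_sos(p_, Xs, Ts, h, act_h) +
                   decay * sum(p_^2),
                 function(p_) .mlp_sos_grad(p_, Xs, Ts, h, act_h) +
                   2 * decay * p_,
                 method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  fit$sos <- .mlp_sos(fit$par, Xs, Ts, h, act_h)
  fit
}

#' Train the blend-share surrogate
#'
#' Fits single-hidden-layer perceptrons (exponential hidden units, identity
#' outputs) mapping the two blend shares to the measured output
#' characteristics, by quasi-Newton (BFGS) minimization of the
#' sum-of-squares loss on min-max scaled data. The samples are split
#' 60/20/20 into training, validation and test sets (the control sample is
#' always excluded); for every candidate hidden-layer size the best of
#' `n_restarts` random initializations (by training SOS) is kept, and the
#' hidden size with the smallest validation SOS wins.
#'
#' @param samples A `blend_samples` object containing the outputs for every
#'   non-control sample.
#' @param hidden Integer vector of candidate hidden-layer sizes.
#' @param seed Integer seed; the split and every initialization derive from
#'   it, so the result is fully reproducible.
#' @param n_restarts Random restarts per hidden size.
#' @param outputs Modelled outputs (default [blend_variables()], the 28
#'   characteristics).
#' @param maxit BFGS iteration cap per restart.
#' @param decay Ridge (weight-decay) coefficient added to the training
#'   objective as `decay * sum(w^2)`. The default `1e-4` is far below the
#'   data term yet regularizes the over-parameterized network: it removes
#'   the inactive-unit weight drift that destabilizes weight-based
#'   sensitivity analysis and conditions the optimization. Reported SOS
#'   values always refer to the data term alone.
#' @param split Train/validation/test fractions (must sum to 1).
#' @return A list with elements `model` (the winning [mlp_surrogate()]) and
#'   `report` (a `fit_report`, see [residual_analysis()]).
#' @export
train_surrogate <- function(samples, hidden = 1:8, seed = 1, n_restarts = 20,
                            outputs = blend_variables(), maxit = 600,
                            decay = 1e-4, split = c(0.6, 0.2, 0.2)) {
  stopifnot(abs(sum(split) - 1) < 1e-9, length(split) == 3)
  Y <- blend_matrix(samples, outputs, include_control = FALSE)
  shares <- blend_shares(rownames(Y))
  X <- cbind(s_share = shares$s_share, f_share = shares$f_share)
  n <- nrow(Y)
  if (n < 5) stop("need at least 5 non-control samples", call. = FALSE)
  if (anyNA(Y)) stop("samples are missing modelled outputs", call. = FALSE)

  set.seed(seed %% .Machine$integer.max)
  n_train <- max(1, round(split[1] * n))
  n_val <- max(1, round(split[2] * n))
  perm <- sample(n)
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[-seq_len(n_train + n_val)])

  x_scaler <- minmax_scaler(X)
  y_scaler <- minmax_scaler(Y)
  Xs <- scale_minmax(X, x_scaler)
  Ys <- scale_minmax(Y, y_scaler)

  best <- NULL
  history <- data.frame()
  for (h in hidden) {
    fit_h <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .fit_once(Xs[idx$train, , drop = FALSE],
                       Ys[idx$train, , drop = FALSE], h, "exponential",
                       maxit, decay)
      if (!is.null(fit) && (is.null(fit_h) || fit$value < fit_h$value)) {
        fit_h <- fit
      }
    }
    if (is.null(fit_h)) next
    w <- .par_split(fit_h$par, h, ncol(Xs), ncol(Ys))
    m <- mlp_surrogate(w$W1, w$b1, w$W2, w$b2, "exponential", "identity",
                       x_scaler, y_scaler, outputs)
    val_sos <- sum((.mlp_forward_scaled(m, Xs[idx$validation, , drop = FALSE]) -
                      Ys[idx$validation, , drop = FALSE])^2)
    history <- rbind(history, data.frame(hidden = h, train_sos = fit_h$sos,
                                         validation_sos = val_sos))
    if (is.null(best) || val_sos < best$val_sos) {
      best <- list(model = m, val_sos = val_sos)
    }
  }
  if (is.null(best)) {
    stop("no restart converged for any hidden size; last diagnostics:\n",
         paste(utils::capture.output(print(history)), collapse = "\n"),
         call. = FALSE)
  }
  report <- .fit_report(best$model, X, Y, idx, history)
  list(model = best$model, report = report)
}

#' Fit a surrogate to all samples with a fixed architecture
#'
#' Used for final production fits (and ensemble members): no splitting, the
#' best of `n_restarts` BFGS runs on all provided samples is returned.
#'
#' @inheritParams train_surrogate
#' @param hidden Hidden-layer size (scalar).
#' @return An [mlp_surrogate()].
#' @export
fit_surrogate <- function(samples, hidden = 6, seed = 1, n_restarts = 8,
                          outputs = blend_variables(), maxit = 600,
                          decay = 1e-4) {
  Y <- blend_matrix(samples, outputs, include_control = FALSE)
  shares <- blend_shares(rownames(Y))
  X <- cbind(s_share = shares$s_share, f_share = shares$f_share)
  if (anyNA(Y)) stop("samples are missing modelled outputs", call. = FALSE)
  x_scaler <- minmax_scaler(X)
  y_scaler <- minmax_scaler(Y)
  Xs <- scale_minmax(X, x_scaler)
  Ys <- scale_minmax(Y, y_scaler)
  set.seed(seed %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .fit_once(Xs, Ys, hidden, "exponential", maxit, decay)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("no restart converged", call. = FALSE)
  w <- .par_split(best$par, hidden, ncol(Xs), ncol(Ys))
  mlp_surrogate(w$W1, w$b1, w$W2, w$b2, "exponential", "identity",
                x_scaler, y_scaler, outputs)
}

# ---- accuracy metrics ------------------------------------------------------

#' Model accuracy metrics
#'
#' The standard validation set for small regression surrogates: coefficient
#' of determination r2 (squared Pearson correlation of predicted vs
#' experimental), reduced chi-square `sum((exp - pred)^2) / (N - n)`, root
#' mean square error, mean bias error `mean(pred - exp)`, and the signed
#' mean percentage error `100/N * sum((pred - exp)/exp)`.
#'
#' @param pred,exp Equal-length numeric vectors of predicted and
#'   experimental values.
#' @param n_params Number of fitted constants (for the reduced chi-square);
#'   must be smaller than the number of observations.
#' @return Named numeric vector `r2`, `chi2`, `RMSE`, `MBE`, `MPE`.
#' @export
#' @examples
#' fit_metrics(c(2, 2, 2), c(1, 2, 3), n_params = 1)
fit_metrics <- function(pred, exp, n_params = 0) {
  stopifnot(length(pred) == length(exp))
  N <- length(pred)
  if (N <= n_params) {
    stop("reduced chi-square needs more observations than parameters",
         call. = FALSE)
  }
  if (any(exp == 0)) {
    stop("mean percentage error undefined: experimental value of 0",
         call. = FALSE)
  }
  res <- pred - exp
  r2 <- if (stats::sd(pred) == 0 || stats::sd(exp) == 0) NA_real_
        else stats::cor(pred, exp)^2
  c(r2 = r2,
    chi2 = sum(res^2) / (N - n_params),
    RMSE = sqrt(mean(res^2)),
    MBE = mean(res),
    MPE = 100 * mean(res / exp))
}

# metrics that tolerate zeros / degenerate vectors (NA instead of error),
# for building reports over all outputs; outputs constant up to floating-
# point noise have no meaningful correlation
.near_constant <- function(x) {
  if (length(x) < 2) return(TRUE)
  s <- stats::sd(x)
  !is.finite(s) || s <= 1e-10 * max(1, abs(mean(x)))
}

.safe_metrics <- function(pred, exp, n_params = 0) {
  N <- length(pred)
  res <- pred - exp
  c(r2 = if (!.near_constant(pred) && !.near_constant(exp))
      stats::cor(pred, exp)^2 else NA_real_,
    chi2 = if (N > n_params) sum(res^2) / (N - n_params) else NA_real_,
    RMSE = sqrt(mean(res^2)),
    MBE = mean(res),
    MPE = if (all(exp != 0)) 100 * mean(res / exp) else NA_real_)
}

.fit_report <- function(model, X, Y, idx, history) {
  pred <- mlp_forward(model, X)
  per_output <- list()
  aggregate <- list()
  Ys <- scale_minmax(Y, model$y_scaler)
  Ps <- scale_minmax(pred, model$y_scaler)
  for (split in names(idx)) {
    i <- idx[[split]]
    per_output[[split]] <- t(vapply(model$outputs, function(v) {
      .safe_metrics(pred[i, v], Y[i, v])
    }, numeric(5)))
    keep <- apply(Ys[i, , drop = FALSE], 2, function(col) !.near_constant(col))
    pooled_p <- as.vector(Ps[i, keep, drop = FALSE])
    pooled_e <- as.vector(Ys[i, keep, drop = FALSE])
    aggregate[[split]] <- c(
      r2 = if (length(pooled_p) > 2) stats::cor(pooled_p, pooled_e)^2
           else NA_real_,
      sos = sum((Ps[i, , drop = FALSE] - Ys[i, , drop = FALSE])^2))
  }
  residuals <- pred - Y
  structure(list(model = model, split = idx,
                 per_output = per_output, aggregate = aggregate,
                 residuals = residuals, history = history,
                 hidden = nrow(model$W1)),
            class = "fit_report")
}

#' Residual analysis of a surrogate fit
#'
#' Per-output residual mean and standard deviation over all fitted samples,
#' the fraction of residuals inside mean +/- 2 SD, and a flag for outputs
#' whose fraction falls below 0.9 (a symptom of heavy-tailed or structured
#' residuals).
#'
#' @param report A `fit_report` from [train_surrogate()].
#' @return Data frame with columns `output`, `mean`, `sd`, `frac_within_2sd`,
#'   `flagged`.
#' @export
residual_analysis <- function(report) {
  stopifnot(inherits(report, "fit_report"))
  res <- report$residuals
  out <- data.frame(
    output = colnames(res),
    mean = colMeans(res),
    sd = apply(res, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  out$frac_within_2sd <- vapply(seq_len(ncol(res)), function(j) {
    r <- res[, j]
    if (out$sd[j] == 0) return(1)
    mean(abs(r - out$mean[j]) <= 2 * out$sd[j])
  }, numeric(1))
  out$flagged <- out$frac_within_2sd < 0.9
  rownames(out) <- NULL
  out
}

# ---- serialization ---------------------------------------------------------

#' Save / load a surrogate as JSON
#'
#' The JSON carries explicit matrix shapes, activation names, scaler
#' parameters and the output-name order, so saved models are diffable and
#' forward-compatible.
#'
#' @param m An [mlp_surrogate()].
#' @param path JSON file path.
#' @return `write_surrogate()` returns `path` invisibly; `read_surrogate()`
#'   returns the reconstructed [mlp_surrogate()].
#' @export
write_surrogate <- function(m, path) {
  stopifnot(inherits(m, "mlp_surrogate"))
  ser_scaler <- function(s) if (is.null(s)) NULL else
    list(min = as.numeric(s$min), max = as.numeric(s$max))
  payload <- list(
    W1 = list(dim = dim(m$W1), values = as.numeric(m$W1)),
    b1 = as.numeric(m$b1),
    W2 = list(dim = dim(m$W2), values = as.numeric(m$W2)),
    b2 = as.numeric(m$b2),
    hidden_activation = m$hidden_activation,
    output_activation = m$output_activation,
    x_scaler = ser_scaler(m$x_scaler),
    y_scaler = ser_scaler(m$y_scaler),
    outputs = m$outputs,
    inputs = m$inputs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_scaler <- function(s) if (is.null(s)) NULL else
    structure(list(min = s$min, max = s$max), class = "minmax_scaler")
  mlp_surrogate(
    W1 = matrix(p$W1$values, p$W1$dim[1], p$W1$dim[2]),
    b1 = p$b1,
    W2 = matrix(p$W2$values, p$W2$dim[1], p$W2$dim[2]),
    b2 = p$b2,
    hidden_activation = p$hidden_activation,
    output_activation = p$output_activation,
    x_scaler = de_scaler(p$x_scaler),
    y_scaler = de_scaler(p$y_scaler),
    outputs = p$outputs,
    inputs = p$inputs
  )
}
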