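#' Fit an ensemble of independently seeded surrogates
#'
#' Small perceptrons trained on eleven blends are strongly over-
#' parameterized, so a single fit carries initialization-dependent wiggles
#' between the training compositions. Averaging the predictions of several
#' independently seeded fits removes most of that variance and is the
#' recommended model for optimization.
#'
#' @inheritParams fit_surrogate
#' @param n_members Number of ensemble members (default 10).
#' @param seed Base seed; member `k` uses `seed + k`.
#' @return An object of class `mlp_ensemble` (a list of
#'   [mlp_surrogate()]s sharing outputs and scalers).
#' @export
surrogate_ensemble <- function(samples, n_members = 10, hidden = 6, seed = 1,
                               n_restarts = 8, outputs = blend_variables(),
                               maxit = 600, decay = 1e-4) {
  stopifnot(n_members >= 1)
  members <- lapply(seq_len(n_members), function(k) {
    fit_surrogate(samples, hidden = hidden, seed = seed + k,
                  n_restarts = n_restarts, outputs = outputs, maxit = maxit,
                  decay = decay)
  })
  structure(list(members = members, outputs = members[[1]]$outputs),
            class = "mlp_ensemble")
}

#' Ensemble-averaged forward pass
#'
#' @param m An `mlp_ensemble`.
#' @param x Input matrix or vector of blend shares (see [mlp_forward()]).
#' @return Matrix of member-averaged predictions.
#' @export
ensemble_forward <- function(m, x) {
  stopifnot(inherits(m, "mlp_ensemble"))
  preds <- lapply(m$members, mlp_forward, x = x)
  Reduce(`+`, preds) / length(preds)
}

#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  ensemble_forward(object, newdata)
}
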