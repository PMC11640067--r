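#' Yoon weight-based relative influence of the network inputs
#'
#' Yoon's interpretation method attributes each output's behaviour to the
#' inputs through the product of the connection weights: the raw effect of
#' input `i` on output `k` is `e_ik = sum_j W1[j, i] * W2[k, j]`, and the
#' signed relative influence is `RI(i, k) = 100 * e_ik / sum_i |e_ik|`, so
#' that the absolute influences of all inputs sum to 100 % for every
#' output. Activations and biases are ignored, as in the standard
#' formulation.
#'
#' @param m An [mlp_surrogate()] with finite weights.
#' @return Matrix of signed influences in percent, outputs in rows, inputs
#'   in columns, of class `yoon_sensitivity`.
#' @export
#' @examples
#' m <- mlp_surrogate(W1 = matrix(c(1, 1), 1), b1 = 0,
#'                    W2 = matrix(0.5), b2 = 0)
#' yoon_relative_influence(m)  # +50 % / +50 %
yoon_relative_influence <- function(m) {
  stopifnot(inherits(m, "mlp_surrogate"))
  if (!all(is.finite(m$W1)) || !all(is.finite(m$W2))) {
    stop("model weights must be finite", call. = FALSE)
  }
  e <- m$W2 %*% m$W1
  denom <- rowSums(abs(e))
  zero <- denom == 0
  if (any(zero)) {
    stop("relative influence undefined (all-zero weight products) for: ",
         paste(m$outputs[zero], collapse = ", "), call. = FALSE)
  }
  ri <- 100 * e / denom
  dimnames(ri) <- list(m$outputs, m$inputs)
  class(ri) <- c("yoon_sensitivity", class(ri))
  ri
}
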