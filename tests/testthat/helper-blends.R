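# small builders shared across the suite

# fatty-acid profile of a pure-sunflower-like oil (mass %)
sunflower_profile <- function() {
  c("C16:0" = 5.97, "C16:1" = 0.08, "C18:0" = 2.76, "C18:1" = 30.25,
    "C18:2n6" = 59.71, "C18:3n6" = 0, "C18:3n3" = 0.07, "C20:0" = 0.19,
    "C20:1" = 0.11, "C22:0" = 0.60, "C24:0" = 0.21, "C14:0" = 0)
}

# flaxseed-like profile
flaxseed_profile <- function() {
  c("C16:0" = 5.00, "C16:1" = 0.04, "C18:0" = 4.28, "C18:1" = 17.02,
    "C18:2n6" = 18.17, "C18:3n6" = 0.14, "C18:3n3" = 54.84, "C20:0" = 0.12,
    "C20:1" = 0.09, "C22:0" = 0.15, "C24:0" = 0.16, "C14:0" = 0)
}

# a full-variable noiseless mixing scenario built from the packaged pure oils
noiseless_scenario <- function(n_points = 11, seed = 3) {
  d <- blend_dataset()
  mixing_scenario(sample_values(d, "100S/0F", blend_variables()),
                  sample_values(d, "0S/100F", blend_variables()),
                  n_points = n_points, noise_sd = 0, taste_slope = -1.5,
                  seed = seed)
}

# identity-activation surrogate predicting, per output, an affine function
# a_k + b_k * f of the flaxseed fraction (inputs are shares in percent)
affine_surrogate <- function(intercepts, slopes, outputs = names(intercepts)) {
  q <- length(intercepts)
  # hidden unit = (f_share - s_share)/100 = 2f - 1
  mlp_surrogate(W1 = matrix(c(-0.01, 0.01), 1), b1 = 0,
                W2 = matrix(slopes / 2, ncol = 1),
                b2 = intercepts + slopes / 2,
                hidden_activation = "identity",
                output_activation = "identity",
                outputs = outputs)
}

# random small network for property checks
random_mlp <- function(h = 3, p = 2, q = 4,
                       hidden_activation = "identity") {
  mlp_surrogate(W1 = matrix(stats::runif(h * p, -1, 1), h),
                b1 = stats::runif(h, -1, 1),
                W2 = matrix(stats::runif(q * h, -1, 1), q),
                b2 = stats::runif(q, -1, 1),
                hidden_activation = hidden_activation,
                output_activation = "identity")
}
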