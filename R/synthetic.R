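#' Ideal binary mixing of a property
#'
#' Value of a property in a binary blend under ideal (gravimetric linear)
#' mixing: `(1 - f) * p_S + f * p_F`, where `f` is the flaxseed mass
#' fraction.
#'
#' @param f Flaxseed fraction in \[0, 1\] (vectorized).
#' @param p_S,p_F Property value of the pure sunflower and pure flaxseed
#'   parent oil.
#' @return The mixed property value.
#' @export
#' @examples
#' mix_property(0.2, 59.71, 18.17)
mix_property <- function(f, p_S, p_F) {
  if (any(f < 0 | f > 1)) {
    stop("flaxseed fraction must lie in [0, 1]", call. = FALSE)
  }
  (1 - f) * p_S + f * p_F
}

#' Define a synthetic binary-mixing scenario
#'
#' A scenario fixes the two parent-oil property sets, the number of blend
#' levels, per-variable additive noise, and an affine taste-decline model.
#' All chemistry and colour variables mix linearly; the taste score instead
#' follows `taste_S + taste_slope * f`, clipped to the 0--5 scale, because
#' sensory decline in bitter-tasting component oils is not compositional.
#'
#' @param parent_S,parent_F Named numeric vectors: property values of the
#'   pure sunflower-like and flaxseed-like parent oils (same names).
#' @param n_points Number of equally spaced blend levels spanning f = 0 to
#'   1 (at least 2).
#' @param noise_sd Per-variable additive noise SD, in the variable's units:
#'   a single value or a named vector matching `parent_S` (default 0).
#' @param taste_slope Taste change per unit flaxseed fraction, in score
#'   units (non-positive). Ignored when the parents have no `taste_score`.
#' @param seed Integer seed making the generated series reproducible.
#' @return An object of class `mixing_scenario`.
#' @export
mixing_scenario <- function(parent_S, parent_F, n_points = 11,
                            noise_sd = 0, taste_slope = -1.5, seed = 1) {
  stopifnot(is.numeric(parent_S), is.numeric(parent_F),
            !is.null(names(parent_S)),
            setequal(names(parent_S), names(parent_F)))
  parent_F <- parent_F[names(parent_S)]
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  if (length(noise_sd) == 1) {
    noise_sd <- stats::setNames(rep(noise_sd, length(parent_S)),
                                names(parent_S))
  }
  noise_sd <- noise_sd[names(parent_S)]
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (taste_slope > 0) stop("taste_slope must be non-positive", call. = FALSE)
  structure(list(parent_S = parent_S, parent_F = parent_F,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 taste_slope = taste_slope, seed = as.integer(seed)),
            class = "mixing_scenario")
}

# stable per-variable seed stream: adding a variable to a scenario must not
# shift the draws of the existing ones
.variable_seed <- function(seed, variable) {
  h <- sum(utf8ToInt(variable) * seq_along(utf8ToInt(variable)) * 131)
  (as.integer(seed) * 7919 + h) %% .Machine$integer.max
}

# physical bounds applied to noisy draws
.variable_bounds <- function(variable) {
  if (variable %in% .blend_groups$sensory) return(c(0, 5))
  if (variable == "L") return(c(0, 100))
  if (variable %in% c(.fa_codes, .fa_optional)) return(c(0, 100))
  if (variable %in% c(.blend_groups$quality, .blend_groups$stability)) {
    return(c(0, Inf))
  }
  c(-Inf, Inf)
}

#' Simulate a binary blend measurement series
#'
#' Generates `n_points` samples at equally spaced flaxseed fractions in
#' \[0, 1\]. Every property follows [mix_property()] plus independent
#' Gaussian noise with the configured SD, truncated at its physical bounds;
#' the taste score follows the scenario's affine decline, clipped to
#' \[0, 5\]. Each variable draws from its own seeded stream, so the series
#' is reproducible and stable under adding variables.
#'
#' @param scenario A [mixing_scenario()].
#' @return A `blend_samples` object with `n_points` samples whose
#'   identifiers encode the shares (e.g. `"80S/20F"`).
#' @export
#' @examples
#' sc <- mixing_scenario(c(taste_score = 4.1, AnV = 15.12),
#'                       c(taste_score = 4.1, AnV = 0), n_points = 5)
#' simulate_blend_series(sc)
simulate_blend_series <- function(scenario) {
  stopifnot(inherits(scenario, "mixing_scenario"))
  f <- seq(0, 1, length.out = scenario$n_points)
  s_share <- round(100 * (1 - f), 6)
  ids <- sprintf("%gS/%gF", s_share, round(100 * f, 6))
  vars <- names(scenario$parent_S)
  rows <- lapply(vars, function(v) {
    if (v == "taste_score") {
      base <- scenario$parent_S[[v]] + scenario$taste_slope * f
    } else {
      base <- mix_property(f, scenario$parent_S[[v]], scenario$parent_F[[v]])
    }
    sd <- scenario$noise_sd[[v]]
    if (sd > 0) {
      old <- globalenv()$.Random.seed
      set.seed(.variable_seed(scenario$seed, v))
      base <- base + stats::rnorm(length(f), 0, sd)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    bounds <- .variable_bounds(v)
    base <- pmin(pmax(base, bounds[1]), bounds[2])
    if (v == "taste_score") base <- pmin(pmax(base, 0), 5)
    data.frame(sample_id = ids, variable = v, mean = base,
               sd = sd, n = 1, detected = TRUE, stringsAsFactors = FALSE)
  })
  blend_samples(do.call(rbind, rows))
}
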