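#' Canonical measurement variables of a blend sample
#'
#' Every blend sample is characterized by 28 modelled outputs organized in
#' four groups, plus two accelerated-stability measurements that are recorded
#' but not modelled:
#'
#' * `fatty_acids` (12): mass percentages of the individual fatty acids,
#'   from myristic (C14:0) to lignoceric (C24:0) acid.
#' * `quality` (7): acid value `AV` (mg KOH/g), peroxide value `PV`
#'   (mmol/kg), p-anisidine value `AnV`, total oxidation index `TOTOX`,
#'   conjugated dienes `CD`, conjugated trienes `CT`, and their ratio
#'   `CD_CT`.
#' * `color` (4): CIELab lightness `L`, redness `a`, yellowness `b`, and the
#'   total colour difference `deltaE` relative to the control oil.
#' * `sensory` (5): panel scores on the 0--5 scale for colour, odour and
#'   taste, their unweighted `average_rating`, and the weighted
#'   `total_acceptability`.
#'
#' @param group Optional group name (one of `"fatty_acids"`, `"quality"`,
#'   `"color"`, `"sensory"`, `"stability"`); when `NULL` the 28 modelled
#'   variables are returned in canonical order.
#' @return Character vector of variable names.
#' @export
#' @examples
#' blend_variables()
#' blend_variables("sensory")
blend_variables <- function(group = NULL) {
  if (is.null(group)) {
    return(unlist(.blend_groups[c("sensory", "color", "quality", "fatty_acids")],
                  use.names = FALSE))
  }
  group <- match.arg(group, names(.blend_groups))
  .blend_groups[[group]]
}

.fa_codes <- c("C14:0", "C16:0", "C16:1", "C18:0", "C18:1", "C18:2n6",
               "C18:3n6", "C18:3n3", "C20:0", "C20:1", "C22:0", "C24:0")

# fatty-acid codes that are representable but were never detected in the
# study oils; they default to 0 so the nutritional-index formulas that cite
# them stay complete
.fa_optional <- c("C12:0", "C20:4n6", "C20:5n3", "C22:5n3", "C22:6n3")

.blend_groups <- list(
  fatty_acids = .fa_codes,
  quality     = c("AV", "PV", "AnV", "TOTOX", "CD", "CT", "CD_CT"),
  color       = c("L", "a", "b", "deltaE"),
  sensory     = c("color_score", "odor_score", "taste_score",
                  "average_rating", "total_acceptability"),
  stability   = c("rancimat_ip", "rapidoxy_ip")
)

# printed nutrient-index columns carried along with the fatty-acid table
.fa_indices <- c("omega_ratio", "IA", "IT", "HH")

#' Variable group membership for the 28 modelled outputs
#'
#' @return Named character vector mapping each of the 28 modelled variables
#'   to its group (`sensory`, `color`, `quality` or `fatty_acids`).
#' @export
variable_groups <- function() {
  groups <- c("sensory", "color", "quality", "fatty_acids")
  stats::setNames(rep(groups, lengths(.blend_groups[groups])),
                  unlist(.blend_groups[groups], use.names = FALSE))
}

# schema (table kind) -> admissible variables in a long-format CSV
.schema_variables <- list(
  fatty_acids = c(.fa_codes, .fa_indices),
  quality     = .blend_groups$quality,
  stability   = .blend_groups$stability,
  color       = .blend_groups$color,
  sensory     = .blend_groups$sensory
)
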