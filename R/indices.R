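#' Fatty-acid group sums
#'
#' Sums the individual fatty-acid mass percentages into the conventional
#' groups: saturated (SFA), monounsaturated (MUFA), omega-6 and omega-3
#' polyunsaturated, and total PUFA (= omega-6 + omega-3).
#'
#' @param profile Named numeric vector of fatty-acid mass percentages using
#'   the `C<chain>:<double bonds>` codes (e.g. `"C18:2n6"`). Codes that are
#'   absent are treated as 0, so profiles from studies that never detected
#'   e.g. C12:0 or the long-chain omega-3 acids remain usable.
#' @return Named numeric vector with elements `SFA`, `MUFA`, `PUFA`,
#'   `omega6`, `omega3`.
#' @export
#' @examples
#' p <- c("C16:0" = 5, "C18:1" = 17, "C18:2n6" = 18.2, "C18:3n3" = 54.8)
#' fatty_acid_sums(p)
fatty_acid_sums <- function(profile) {
  g <- function(code) if (code %in% names(profile)) unname(profile[code]) else 0
  sfa <- g("C12:0") + g("C14:0") + g("C16:0") + g("C18:0") + g("C20:0") +
    g("C22:0") + g("C24:0")
  mufa <- g("C16:1") + g("C18:1") + g("C20:1")
  omega6 <- g("C18:2n6") + g("C18:3n6") + g("C20:4n6")
  omega3 <- g("C18:3n3") + g("C20:5n3") + g("C22:5n3") + g("C22:6n3")
  c(SFA = sfa, MUFA = mufa, PUFA = omega6 + omega3,
    omega6 = omega6, omega3 = omega3)
}

#' Omega-6 / omega-3 fatty-acid ratio
#'
#' The ratio of the omega-6 family (linoleic and gamma-linolenic acid) to
#' the omega-3 family (alpha-linolenic acid and any long-chain omega-3
#' acids). Dietary guidance favours ratios between roughly 1 and 10.
#'
#' @inheritParams fatty_acid_sums
#' @return The dimensionless ratio.
#' @export
omega_ratio <- function(profile) {
  s <- fatty_acid_sums(profile)
  if (s["omega3"] <= 0) {
    stop("omega-6/omega-3 ratio undefined: omega-3 content is zero",
         call. = FALSE)
  }
  unname(s["omega6"] / s["omega3"])
}

#' Index of atherogenicity (IA)
#'
#' Ratio of the principal atherogenic saturated acids (lauric, 4 x myristic,
#' palmitic) to the unsaturated acids:
#' `(C12:0 + 4 C14:0 + C16:0) / (MUFA + omega6 + omega3)`. Lower is
#' nutritionally better.
#'
#' @inheritParams fatty_acid_sums
#' @return The dimensionless index.
#' @export
atherogenicity_index <- function(profile) {
  g <- function(code) if (code %in% names(profile)) unname(profile[code]) else 0
  s <- fatty_acid_sums(profile)
  den <- s["MUFA"] + s["omega6"] + s["omega3"]
  if (den <= 0) stop("atherogenicity index undefined: no unsaturated acids",
                     call. = FALSE)
  unname((g("C12:0") + 4 * g("C14:0") + g("C16:0")) / den)
}

#' Index of thrombogenicity (IT)
#'
#' Ratio of the pro-thrombogenic saturates to the anti-thrombogenic
#' unsaturates:
#' `(C14:0 + C16:0 + C18:0) / (0.5 MUFA + 0.5 omega6 + 3 omega3)`.
#' Lower is nutritionally better.
#'
#' @inheritParams fatty_acid_sums
#' @return The dimensionless index.
#' @export
thrombogenicity_index <- function(profile) {
  g <- function(code) if (code %in% names(profile)) unname(profile[code]) else 0
  s <- fatty_acid_sums(profile)
  den <- 0.5 * s["MUFA"] + 0.5 * s["omega6"] + 3 * s["omega3"]
  if (den <= 0) stop("thrombogenicity index undefined: zero denominator",
                     call. = FALSE)
  unname((g("C14:0") + g("C16:0") + g("C18:0")) / den)
}

#' Hypocholesterolaemic/hypercholesterolaemic (HH) ratio
#'
#' `(C18:1 + C18:2n6 + C20:4n6 + C18:3n3 + C20:5n3 + C22:5n3 + C22:6n3) /
#' (C14:0 + C16:0)`. Higher is nutritionally better. The numerator
#' nominally uses only the cis-9 isomer of oleic acid; GC tables usually
#' report total C18:1, and that total is used here. Published HH values
#' computed from unrounded cis-9-only chromatogram areas therefore differ
#' slightly from values recomputed from rounded totals.
#'
#' @inheritParams fatty_acid_sums
#' @return The dimensionless ratio.
#' @export
hh_ratio <- function(profile) {
  g <- function(code) if (code %in% names(profile)) unname(profile[code]) else 0
  den <- g("C14:0") + g("C16:0")
  if (den <= 0) stop("HH ratio undefined: C14:0 + C16:0 is zero", call. = FALSE)
  num <- g("C18:1") + g("C18:2n6") + g("C20:4n6") + g("C18:3n3") +
    g("C20:5n3") + g("C22:5n3") + g("C22:6n3")
  num / den
}

#' Total oxidation index (TOTOX)
#'
#' `TOTOX = 2 PV + AnV`, combining primary (hydroperoxide) and secondary
#' (aldehyde) oxidation products into a single oxidation-status figure.
#'
#' @param pv Peroxide value (mmol/kg), non-negative.
#' @param anv p-Anisidine value (dimensionless), non-negative.
#' @return The TOTOX value.
#' @export
#' @examples
#' totox(1.60, 15.12)
totox <- function(pv, anv) {
  stopifnot(all(pv >= 0), all(anv >= 0))
  2 * pv + anv
}

#' CIE76 total colour difference
#'
#' Euclidean distance between two colours in CIELab space:
#' `sqrt((L1-L2)^2 + (a1-a2)^2 + (b1-b2)^2)`.
#'
#' @param lab,ref Numeric vectors `c(L, a, b)` of the colour and the
#'   reference colour.
#' @return The colour difference Delta E.
#' @export
#' @examples
#' delta_e(c(26.50, -1.00, 3.50), c(25.48, -1.18, 4.25))
delta_e <- function(lab, ref) {
  stopifnot(length(lab) == 3, length(ref) == 3)
  sqrt(sum((as.numeric(lab) - as.numeric(ref))^2))
}

#' Average sensory rating
#'
#' Unweighted mean of the colour, odour and taste panel scores (0--5 scale).
#'
#' @param color,odor,taste Scores on the 0--5 scale.
#' @return The average rating.
#' @export
average_rating <- function(color, odor, taste) {
  .check_scores(color, odor, taste)
  (color + odor + taste) / 3
}

#' Total sensory acceptability
#'
#' Weighted acceptability score
#' `(colour x 0.6 + odour x 0.8 + taste x 1.0) x 5/12`, which maps the
#' maximal panel scores (5, 5, 5) back onto 5.
#'
#' @inheritParams average_rating
#' @return The total acceptability on the 0--5 scale.
#' @export
#' @examples
#' total_acceptability(3.6, 4.1, 3.9)
total_acceptability <- function(color, odor, taste) {
  .check_scores(color, odor, taste)
  (color * 0.6 + odor * 0.8 + taste * 1.0) * 5 / 12
}

.check_scores <- function(color, odor, taste) {
  s <- c(color, odor, taste)
  if (any(s < 0 | s > 5)) {
    stop("sensory scores must lie in [0, 5]", call. = FALSE)
  }
  invisible(NULL)
}

#' Compute all closed-form indices for every sample
#'
#' For each sample with the required measurements this computes the
#' fatty-acid group sums, the omega-6/omega-3 ratio, IA, IT, HH, TOTOX, the
#' colour difference against a reference, the average rating and the total
#' acceptability.
#'
#' @param samples A `blend_samples` object.
#' @param reference_id Sample whose colour is the Delta E reference
#'   (default `"Control"`). Undefined ratios yield `NA` with a warning
#'   suppressed; use the scalar functions for strict error behaviour.
#' @return Data frame with one row per sample.
#' @export
#' @examples
#' head(compute_indices(blend_dataset()))
compute_indices <- function(samples, reference_id = "Control") {
  ids <- unique(samples$sample_id)
  ref <- tryCatch(sample_values(samples, reference_id, c("L", "a", "b")),
                  error = function(e) NULL)
  rows <- lapply(ids, function(id) {
    val <- sample_values(samples, id)
    prof <- val[names(val) %in% c(.fa_codes, .fa_optional)]
    s <- fatty_acid_sums(prof)
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    data.frame(
      sample_id = id,
      SFA = s[["SFA"]], MUFA = s[["MUFA"]], PUFA = s[["PUFA"]],
      omega6 = s[["omega6"]], omega3 = s[["omega3"]],
      omega_ratio = safe(omega_ratio(prof)),
      IA = safe(atherogenicity_index(prof)),
      IT = safe(thrombogenicity_index(prof)),
      HH = safe(hh_ratio(prof)),
      TOTOX = if (all(c("PV", "AnV") %in% names(val)))
        totox(val[["PV"]], val[["AnV"]]) else NA_real_,
      deltaE = if (!is.null(ref) && all(c("L", "a", "b") %in% names(val)) &&
                   id != reference_id)
        delta_e(val[c("L", "a", "b")], ref) else NA_real_,
      average_rating = if (all(c("color_score", "odor_score", "taste_score")
                               %in% names(val)))
        average_rating(val[["color_score"]], val[["odor_score"]],
                       val[["taste_score"]]) else NA_real_,
      total_acceptability = if (all(c("color_score", "odor_score",
                                      "taste_score") %in% names(val)))
        total_acceptability(val[["color_score"]], val[["odor_score"]],
                            val[["taste_score"]]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
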