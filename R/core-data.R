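#' Read a long-format blend measurement table
#'
#' Measurement tables are long-format CSVs with columns
#' `sample_id, variable, mean, sd, n`, one row per sample/variable pair.
#' The string `"nd"` in the `mean` column marks a constituent that was not
#' detected; it is read as 0 with the detection flag cleared. Sample
#' identifiers follow the `"<S>S/<F>F"` convention (e.g. `"80S/20F"` for
#' 80 % sunflower, 20 % flaxseed by mass); the reference oil is `"Control"`.
#'
#' @param path Path to the CSV file.
#' @param schema Table kind, one of `"fatty_acids"`, `"quality"`,
#'   `"stability"`, `"color"`, `"sensory"`; fixes the set of admissible
#'   variable names.
#' @return A `blend_samples` data frame (see [blend_samples()]) holding the
#'   variables of this table.
#' @export
#' @examples
#' path <- system.file("extdata", "quality.csv", package = "blendopt")
#' head(load_blend_table(path, "quality"))
load_blend_table <- function(path, schema) {
  schema <- match.arg(schema, names(.schema_variables))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "variable", "mean", "sd", "n")
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    stop("unknown column in ", basename(path), ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing column in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(blend_samples(data.frame(sample_id = character(),
                                    variable = character(),
                                    mean = numeric(), sd = numeric(),
                                    n = numeric(), detected = logical())))
  }
  bad <- setdiff(unique(raw$variable), .schema_variables[[schema]])
  if (length(bad) > 0) {
    stop("variable not in the '", schema, "' schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(raw[c("sample_id", "variable")])
  if (any(dup)) {
    stop("duplicate sample/variable pair: ",
         paste(unique(raw$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  detected <- raw$mean != "nd"
  mean <- suppressWarnings(as.numeric(ifelse(detected, raw$mean, "0")))
  if (anyNA(mean) && any(is.na(mean) & raw$mean != "")) {
    stop("non-numeric mean value in ", basename(path), call. = FALSE)
  }
  if (any(mean < 0 & raw$variable %in% c(.fa_codes, .blend_groups$quality,
                                         .blend_groups$sensory,
                                         .blend_groups$stability), na.rm = TRUE)) {
    stop("negative value for a non-negative variable in ", basename(path),
         call. = FALSE)
  }
  blend_samples(data.frame(
    sample_id = raw$sample_id,
    variable = raw$variable,
    mean = mean,
    sd = suppressWarnings(as.numeric(raw$sd)),
    n = suppressWarnings(as.numeric(raw$n)),
    detected = detected,
    stringsAsFactors = FALSE
  ))
}

#' Construct a `blend_samples` object
#'
#' The canonical container is a long data frame with one row per
#' sample/variable pair and columns `sample_id`, `variable`, `mean`, `sd`,
#' `n`, `detected`. Sunflower/flaxseed mass shares are parsed from the
#' sample identifier and exposed through [blend_shares()].
#'
#' @param x Data frame with the columns listed above (`sd`, `n`, `detected`
#'   optional).
#' @return `x` with class `blend_samples`.
#' @export
blend_samples <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("sample_id", "variable", "mean") %in% names(x)))
  if (is.null(x$sd)) x$sd <- NA_real_
  if (is.null(x$n)) x$n <- NA_real_
  if (is.null(x$detected)) x$detected <- TRUE
  class(x) <- c("blend_samples", "data.frame")
  x
}

#' Combine measurement tables by sample
#'
#' @param ... `blend_samples` objects (e.g. from [load_blend_table()]).
#' @return A single `blend_samples` object.
#' @export
merge_blend_tables <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(unclass(p))))
  dup <- duplicated(out[c("sample_id", "variable")])
  if (any(dup)) {
    stop("duplicate sample/variable pair after merge: ",
         paste(unique(paste(out$sample_id[dup], out$variable[dup])),
               collapse = ", "), call. = FALSE)
  }
  blend_samples(out)
}

#' Write a blend measurement table
#'
#' Inverse of [load_blend_table()]: emits the long CSV dialect, writing
#' `"nd"` for values flagged as not detected. Loading the written file
#' reproduces the values exactly.
#'
#' @param samples A `blend_samples` object.
#' @param path Output CSV path.
#' @param schema Table kind; only variables of that schema are written.
#' @return `path`, invisibly.
#' @export
write_blend_table <- function(samples, path, schema) {
  schema <- match.arg(schema, names(.schema_variables))
  keep <- samples$variable %in% .schema_variables[[schema]]
  out <- as.data.frame(unclass(samples))[keep, , drop = FALSE]
  out$mean <- ifelse(out$detected, format(out$mean, trim = TRUE, digits = 15),
                     "nd")
  out <- out[c("sample_id", "variable", "mean", "sd", "n")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Sunflower/flaxseed shares encoded in sample identifiers
#'
#' @param ids Character vector of sample identifiers (`"80S/20F"` style;
#'   `"Control"` yields `NA` shares and `is_control = TRUE`).
#' @return Data frame with columns `sample_id`, `s_share`, `f_share`
#'   (mass %), `is_control`.
#' @export
#' @examples
#' blend_shares(c("80S/20F", "Control"))
blend_shares <- function(ids) {
  ids <- as.character(ids)
  m <- regmatches(ids, regexec("^([0-9.]+)S/([0-9.]+)F$", ids))
  s <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[2]) else NA_real_,
              numeric(1))
  f <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[3]) else NA_real_,
              numeric(1))
  data.frame(sample_id = ids, s_share = s, f_share = f,
             is_control = is.na(s), stringsAsFactors = FALSE)
}

#' The packaged sunflower/flaxseed blending dataset
#'
#' All measured characteristics of the eleven sunflower/flaxseed blends
#' (100S/0F down to 0S/100F in 10-point steps) and of the commercial control
#' oil: fatty-acid composition (mass %), chemical quality, accelerated
#' oxidative-stability induction periods, CIELab colour, and sensory panel
#' scores, together with the published means, standard deviations and
#' replicate counts. The control oil is a commercial three-oil blend of
#' undisclosed recipe, so it carries no shares; its colour difference
#' `deltaE` is undefined (it is the reference) and myristic acid (C14:0) is
#' recorded as not detected throughout because no quantified value was
#' published (trace amounts were reported in pure flaxseed oil).
#'
#' @return A `blend_samples` object with 12 samples.
#' @export
#' @examples
#' d <- blend_dataset()
#' subset(d, variable == "rancimat_ip")
blend_dataset <- function() {
  dir <- system.file("extdata", package = "blendopt")
  merge_blend_tables(
    load_blend_table(file.path(dir, "fatty_acids.csv"), "fatty_acids"),
    load_blend_table(file.path(dir, "quality.csv"), "quality"),
    load_blend_table(file.path(dir, "stability.csv"), "stability"),
    load_blend_table(file.path(dir, "color.csv"), "color"),
    load_blend_table(file.path(dir, "sensory.csv"), "sensory")
  )
}

#' Extract one sample's values as a named vector
#'
#' @param samples A `blend_samples` object.
#' @param id Sample identifier.
#' @param variables Variables to extract (default: all present for the
#'   sample).
#' @return Named numeric vector of means.
#' @export
sample_values <- function(samples, id, variables = NULL) {
  rows <- samples$sample_id == id
  if (!any(rows)) stop("unknown sample id: ", id, call. = FALSE)
  sub <- samples[rows, , drop = FALSE]
  if (!is.null(variables)) {
    sub <- sub[match(variables, sub$variable), , drop = FALSE]
    if (anyNA(sub$variable)) {
      stop("sample ", id, " lacks variables: ",
           paste(setdiff(variables, samples$variable[rows]), collapse = ", "),
           call. = FALSE)
    }
  }
  stats::setNames(sub$mean, sub$variable)
}

#' Wide sample-by-variable matrix of measured means
#'
#' @param samples A `blend_samples` object.
#' @param variables Columns to include (default [blend_variables()], the 28
#'   modelled outputs).
#' @param include_control Keep the control sample? Default `TRUE`.
#' @return Numeric matrix with sample identifiers as row names.
#' @export
blend_matrix <- function(samples, variables = blend_variables(),
                         include_control = TRUE) {
  ids <- unique(samples$sample_id)
  if (!include_control) {
    ids <- ids[!blend_shares(ids)$is_control]
  }
  out <- matrix(NA_real_, length(ids), length(variables),
                dimnames = list(ids, variables))
  for (id in ids) {
    rows <- samples$sample_id == id
    idx <- match(variables, samples$variable[rows])
    out[id, ] <- samples$mean[rows][idx]
  }
  out
}

#' Validate blend samples against the data-model invariants
#'
#' Checks, per sample: fatty-acid percentages in \[0, 100\] and their total
#' in (90, 100.5\] for complete profiles; chemical quality values
#' non-negative; `CD_CT` only meaningful with `CT > 0`; lightness in
#' \[0, 100\]; sensory scores in \[0, 5\]; stability induction periods
#' positive; and, for non-control samples, sunflower + flaxseed shares
#' summing to 100.
#'
#' @param samples A `blend_samples` object.
#' @return Data frame of violations with columns `sample_id`, `field`,
#'   `rule`; zero rows when all invariants hold.
#' @export
#' @examples
#' nrow(validate_samples(blend_dataset()))  # 0
validate_samples <- function(samples) {
  v <- list()
  flag <- function(id, field, rule) {
    v[[length(v) + 1]] <<- data.frame(sample_id = id, field = field,
                                      rule = rule, stringsAsFactors = FALSE)
  }
  shares <- blend_shares(unique(samples$sample_id))
  for (i in seq_len(nrow(shares))) {
    id <- shares$sample_id[i]
    if (!shares$is_control[i]) {
      if (abs(shares$s_share[i] + shares$f_share[i] - 100) > 1e-9) {
        flag(id, "shares", "s_share + f_share must equal 100")
      }
      if (shares$s_share[i] < 0 || shares$s_share[i] > 100 ||
          shares$f_share[i] < 0 || shares$f_share[i] > 100) {
        flag(id, "shares", "shares must lie in [0, 100]")
      }
    }
    rows <- samples$sample_id == id
    val <- stats::setNames(samples$mean[rows], samples$variable[rows])
    fa <- val[names(val) %in% .fa_codes]
    if (length(fa) > 0) {
      if (any(fa < 0 | fa > 100)) {
        flag(id, "fatty_acids", "each fatty acid must lie in [0, 100]")
      }
      if (length(fa) == length(.fa_codes)) {
        tot <- sum(fa)
        if (tot <= 90 || tot > 100.5) {
          flag(id, "fatty_acids", "profile total must lie in (90, 100.5]")
        }
      }
    }
    for (q in intersect(names(val), .blend_groups$quality)) {
      if (!is.na(val[q]) && val[q] < 0) {
        flag(id, q, "quality values must be non-negative")
      }
    }
    if (all(c("CT", "CD_CT") %in% names(val)) &&
        !is.na(val["CT"]) && val["CT"] == 0 && !is.na(val["CD_CT"])) {
      flag(id, "CD_CT", "CD/CT is defined only when CT > 0")
    }
    if ("L" %in% names(val) && !is.na(val["L"]) &&
        (val["L"] < 0 || val["L"] > 100)) {
      flag(id, "L", "lightness must lie in [0, 100]")
    }
    for (s in intersect(names(val), .blend_groups$sensory)) {
      if (!is.na(val[s]) && (val[s] < 0 || val[s] > 5)) {
        flag(id, s, "sensory scores must lie in [0, 5]")
      }
    }
    for (s in intersect(names(val), .blend_groups$stability)) {
      if (!is.na(val[s]) && val[s] <= 0) {
        flag(id, s, "induction periods must be positive")
      }
    }
  }
  if (length(v) == 0) {
    return(data.frame(sample_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
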