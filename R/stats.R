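#' Tukey HSD compact letter display from summary statistics
#'
#' One-way ANOVA with Tukey's honestly-significant-difference test run
#' directly from per-group means, standard deviations and replicate counts.
#' For groups with n = 3 the replicates are reconstructed exactly as
#' `{m - s, m, m + s}` (which has mean `m` and sample SD `s`) and passed
#' through `aov()`/`TukeyHSD()`; for other replicate counts the pairwise
#' studentized-range statistics are computed from the summary formulas
#' (pooled within-group mean square, `q = |m_i - m_j| / sqrt(MSE/2 (1/n_i +
#' 1/n_j))`). Letters are assigned by the insert-and-absorb algorithm so
#' that two groups share a letter exactly when they are not significantly
#' different; letter order follows descending group means.
#'
#' @param means,sds Numeric vectors of group means and standard deviations.
#' @param n Replicates per group (scalar or vector, each >= 2).
#' @param labels Group labels (default names of `means` or `g1, g2, ...`).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Data frame with columns `label`, `mean`, `letters`, ordered as
#'   the input.
#' @export
#' @examples
#' tukey_letters(c(1, 10), c(0.1, 0.1), n = 3)
tukey_letters <- function(means, sds, n, labels = NULL, alpha = 0.05) {
  k <- length(means)
  stopifnot(length(sds) == k, k >= 2, all(sds >= 0))
  if (length(n) == 1) n <- rep(n, k)
  stopifnot(length(n) == k, all(n >= 2))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (!is.null(names(means))) names(means)
              else paste0("g", seq_len(k))
  }

  if (all(n == 3)) {
    # exact replicate reconstruction: {m - s, m, m + s}
    y <- as.vector(vapply(seq_len(k),
                          function(i) means[i] + c(-1, 0, 1) * sds[i],
                          numeric(3)))
    g <- factor(rep(labels, each = 3), levels = labels)
    if (all(sds == 0)) {
      # zero within-group variance: distinct means are trivially separated
      p <- outer(means, means, function(a, b) as.numeric(a == b))
    } else {
      hsd <- stats::TukeyHSD(stats::aov(y ~ g),
                             conf.level = 1 - alpha)$g
      p <- matrix(1, k, k)
      pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
      for (r in seq_len(nrow(hsd))) {
        i <- match(pairs[[r]][1], labels)
        j <- match(pairs[[r]][2], labels)
        p[i, j] <- p[j, i] <- hsd[r, "p adj"]
      }
    }
  } else {
    df_w <- sum(n) - k
    mse <- sum((n - 1) * sds^2) / df_w
    p <- matrix(1, k, k)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (mse == 0) {
          p[i, j] <- p[j, i] <- as.numeric(means[i] == means[j])
        } else {
          q <- abs(means[i] - means[j]) /
            sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
          p[i, j] <- p[j, i] <- stats::ptukey(q, k, df_w,
                                              lower.tail = FALSE)
        }
      }
    }
  }

  sig <- p < alpha
  letters_idx <- .insert_absorb(sig, order(means, decreasing = TRUE))
  data.frame(label = labels, mean = means,
             letters = vapply(seq_len(k), function(i) {
               paste(letters[sort(letters_idx[[i]])], collapse = "")
             }, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# insert-and-absorb compact letter display. sig: k x k logical matrix of
# significant pairs; rank: group indices in display order (descending mean).
# Returns, per group, the set of letter columns it belongs to.
.insert_absorb <- function(sig, rank) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        if (all(c(i, j) %in% cols[[ci]])) {
          cols[[length(cols) + 1]] <- setdiff(cols[[ci]], i)
          cols[[ci]] <- setdiff(cols[[ci]], j)
        }
      }
      # absorb columns that became subsets of others
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] %in% cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order letter columns by the best (highest-mean) group they contain
  pos <- match(seq_len(k), rank)
  ord <- order(vapply(cols, function(cl) min(pos[cl]), numeric(1)))
  cols <- cols[ord]
  lapply(seq_len(k), function(i) {
    which(vapply(cols, function(cl) i %in% cl, logical(1)))
  })
}

#' Principal component analysis with variance and contribution summaries
#'
#' Standardized (correlation-matrix) PCA of a samples-by-variables table,
#' reporting eigenvalues, percent variance explained, loadings under a fixed
#' sign convention (the largest-magnitude loading of every component is
#' positive), and each variable's percent contribution to each component
#' (squared loading, normalized to 100 per component).
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @param standardize Scale columns to unit variance (default `TRUE`;
#'   variables with mixed units should always be standardized).
#' @return An object of class `pca_explained`: list with `eigenvalues`,
#'   `variance_pct`, `loadings`, `contributions_pct`, `scores`.
#' @export
#' @examples
#' p <- pca_explained(matrix(rnorm(40), 10, 4))
#' sum(p$variance_pct)  # 100
pca_explained <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  if (anyNA(x)) stop("missing values in the PCA table", call. = FALSE)
  if (standardize) {
    const <- apply(x, 2, stats::sd) == 0
    if (any(const)) {
      stop("constant column cannot be standardized: ",
           paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(
    eigenvalues = ev,
    variance_pct = 100 * ev / sum(ev),
    loadings = rot,
    contributions_pct = 100 * rot^2,
    scores = scores
  ), class = "pca_explained")
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation with explicit validation, as used for
#' relating PUFA content to oxidative-stability induction periods.
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with non-zero
#'   variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' PUFA vs induction-period correlations for a blend dataset
#'
#' Convenience wrapper: computes the total PUFA content of every sample
#' from its fatty-acid profile and correlates it with the Rancimat and
#' RapidOxy induction periods. The control sample is included by default;
#' although it lies off the sunflower/flaxseed mixing line, its PUFA
#' content and stability follow the same inverse relationship.
#'
#' @param samples A `blend_samples` object.
#' @param include_control Include the control sample (default `TRUE`).
#' @return Named vector with elements `rancimat` and `rapidoxy`.
#' @export
#' @examples
#' stability_correlations(blend_dataset())
stability_correlations <- function(samples, include_control = TRUE) {
  ids <- unique(samples$sample_id)
  if (!include_control) ids <- ids[!blend_shares(ids)$is_control]
  pufa <- vapply(ids, function(id) {
    val <- sample_values(samples, id)
    fatty_acid_sums(val[names(val) %in% c(.fa_codes, .fa_optional)])[["PUFA"]]
  }, numeric(1))
  ip <- blend_matrix(samples, blend_variables("stability"))[ids, ]
  c(rancimat = pearson_r(pufa, ip[, "rancimat_ip"]),
    rapidoxy = pearson_r(pufa, ip[, "rapidoxy_ip"]))
}
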