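# Community statistics: marginal-mean biomass per habitat element x
# territory, Bray-Curtis dissimilarity, PERMANOVA, and composition PCA.

#' Marginal-mean biomass per territory x habitat element cell
#'
#' Estimates the mean of the (optionally log1p-transformed) per-sample biomass
#' for every (territory, habitat element, stratum, taxon) cell.
#'
#' The default estimator (`method = "cellmeans"`) is the balanced-design cell
#' mean: the arithmetic mean of the transformed response over all blocks and
#' time blocks observed in the cell, with its standard error. Under a
#' full-interaction fixed structure with balanced data this equals the
#' mixed-model estimated marginal mean, which is the estimator contract.
#' `method = "lmm"` refits per stratum x taxon as a linear mixed model with
#' habitat element x territory fixed effects and random intercepts for time
#' block and block-in-territory, dropping random terms whose estimated
#' variance is zero, then extracts estimated marginal means (requires the
#' `lme4` and `emmeans` packages).
#'
#' @param samples Per-sample cell table from
#'   `aggregate_cells(..., block_mean = FALSE)`: one row per (territory,
#'   habitat element, stratum, taxon, time block, block) with `biomass_mg`.
#' @param transform `"log1p"` (analysis scale, default) or `"raw"`.
#' @param method `"cellmeans"` (default) or `"lmm"`.
#' @return Data.frame `territory`, `habitat_element`, `stratum`, `taxon`,
#'   `mean`, `se`, `n` with attribute `transform_scale`.
#' @export
marginal_means <- function(samples, transform = c("log1p", "raw"),
                           method = c("cellmeans", "lmm")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  assert_columns(samples, c("territory", "habitat_element", "stratum",
                            "taxon", "biomass_mg"), "sample table")
  y <- if (transform == "log1p") log1p(samples$biomass_mg) else
    samples$biomass_mg
  samples$y <- y
  if (method == "cellmeans") {
    mm <- stats::aggregate(y ~ territory + habitat_element + stratum + taxon,
                           data = samples, FUN = mean)
    sem <- stats::aggregate(y ~ territory + habitat_element + stratum + taxon,
                            data = samples, FUN = std_err)
    nn <- stats::aggregate(y ~ territory + habitat_element + stratum + taxon,
                           data = samples, FUN = length)
    out <- mm
    names(out)[names(out) == "y"] <- "mean"
    out$se <- sem$y
    out$n <- nn$y
  } else {
    if (!requireNamespace("lme4", quietly = TRUE) ||
          !requireNamespace("emmeans", quietly = TRUE)) {
      stop_wrenlink("method = 'lmm' requires the lme4 and emmeans packages",
                    "wrenlink_dependency_error")
    }
    out <- do.call(rbind, lapply(
      split(samples, list(samples$stratum, samples$taxon), drop = TRUE),
      fit_lmm_cell
    ))
  }
  ord <- do.call(base::order, out[c("territory", "habitat_element",
                                    "stratum", "taxon")])
  out <- out[ord, c("territory", "habitat_element", "stratum", "taxon",
                    "mean", "se", "n")]
  rownames(out) <- NULL
  structure(out, transform_scale = transform)
}

# One LMM per stratum x taxon: full habitat element x territory interaction,
# random intercepts for time block and block-in-territory; random terms with
# zero estimated variance are dropped and the model refitted.
fit_lmm_cell <- function(d) {
  d$territory <- factor(d$territory)
  d$habitat_element <- factor(d$habitat_element)
  d$time_f <- factor(d$time_block)
  d$block_f <- factor(paste(d$territory, d$block))
  rterms <- c("(1 | time_f)", "(1 | block_f)")
  repeat {
    form <- stats::as.formula(paste(
      "y ~ habitat_element * territory",
      if (length(rterms)) paste("+", paste(rterms, collapse = " + ")) else ""
    ))
    if (!length(rterms)) {
      fit <- stats::lm(form, data = d)
      break
    }
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE)
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    zero <- vc$grp[vc$vcov < 1e-10 & vc$grp != "Residual"]
    if (!length(zero)) break
    rterms <- rterms[!grepl(paste(sub("_f", "_f", zero), collapse = "|"),
                            rterms)]
  }
  em <- emmeans::emmeans(fit, ~ habitat_element * territory)
  es <- as.data.frame(em)
  data.frame(
    territory = as.character(es$territory),
    habitat_element = as.character(es$habitat_element),
    stratum = d$stratum[1], taxon = d$taxon[1],
    mean = es$emmean, se = es$SE,
    n = as.integer(table(interaction(d$habitat_element, d$territory))[
      interaction(es$habitat_element, es$territory)]),
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum(|x_i - y_i|) / sum(x_i + y_i)`, in `[0, 1]`; 0 iff the vectors
#' are equal, 1 for disjoint supports.
#'
#' @param x,y Nonnegative numeric vectors of equal length, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    stop_wrenlink("abundance vectors must have equal length",
                  "wrenlink_input_error")
  }
  if (any(x < 0) || any(y < 0)) {
    stop_wrenlink("abundances must be nonnegative", "wrenlink_input_error")
  }
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    stop_wrenlink("Bray-Curtis undefined for two all-zero vectors",
                  "wrenlink_undefined_distance_error")
  }
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param mat Numeric matrix or data.frame, rows = samples, columns = taxa.
#' @return A symmetric matrix of pairwise dissimilarities with zero diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  m <- as.matrix(mat)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  d
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-way PERMANOVA: partitions the total sum of squared dissimilarities
#' into among- and within-group components, forms the pseudo-F
#' `((SS_total - SS_within)/(a-1)) / (SS_within/(N-a))`, and estimates the
#' p-value by unrestricted random permutation of the group labels with the
#' one-sided upper tail: `p = (#{F* >= F} + 1) / (n_permutations + 1)`.
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @param groups Group labels, one per row of `d`; at least 2 groups with
#'   at least 2 members each.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Seed for the private permutation stream.
#' @return Object of class `permanova`: list with `pseudo_f`, `p_value`,
#'   `df`, `n_permutations`, `seed`, `ss_among`, `ss_within`, `ss_total`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
        any(abs(diag(d)) > 1e-12)) {
    stop_wrenlink("d must be a symmetric distance matrix with zero diagonal",
                  "wrenlink_input_error")
  }
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) {
    stop_wrenlink("one group label per row of d is required",
                  "wrenlink_input_error")
  }
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_wrenlink("PERMANOVA needs >= 2 groups with >= 2 members each",
                  "wrenlink_design_error")
  }
  a <- length(tab)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      f_stat(groups[sample.int(n)])
    }, numeric(1)) >= f_obs)
  })
  ssw <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  structure(list(
    pseudo_f = f_obs,
    p_value = (exceed + 1) / (n_permutations + 1),
    df = c(among = a - 1L, within = n - a),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    ss_among = ss_total - ssw, ss_within = ssw, ss_total = ss_total
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (one-way, unrestricted permutations)\n")
  cat(sprintf("  pseudo-F = %.4f on %d and %d df\n", x$pseudo_f,
              x$df["among"], x$df["within"]))
  cat(sprintf("  p = %.4g (%d permutations, seed %d)\n", x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

#' PCA of a relative-composition matrix
#'
#' Column-centred, unscaled principal component analysis of a matrix of
#' relative biomass (row proportions; proportions share a scale so no
#' variance scaling is applied). Axis signs are fixed so that each axis's
#' largest-magnitude loading is positive, making axis interpretation
#' reproducible.
#'
#' @param mat Numeric matrix/data.frame, rows = territories or samples,
#'   columns = taxa, rows summing to 1 (all-zero rows are rejected).
#' @param n_axes Number of axes to return (default all).
#' @return Object of class `composition_pca`: list with `scores`, `loadings`,
#'   `variance_fraction`, `sdev`.
#' @export
pca_composition <- function(mat, n_axes = NULL) {
  m <- as.matrix(mat)
  if (nrow(m) < 2L) {
    stop_wrenlink("PCA needs at least 2 rows", "wrenlink_input_error")
  }
  if (all(apply(m, 2, stats::sd) < 1e-12)) {
    stop_wrenlink("composition matrix has zero variance",
                  "wrenlink_zero_variance_error")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_axes %||% ncol(p$rotation), ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = load,
                 variance_fraction = vf[seq_len(k)],
                 variance_fraction_all = vf,
                 sdev = p$sdev[seq_len(k)]),
            class = "composition_pca")
}

#' @export
print.composition_pca <- function(x, ...) {
  cat(sprintf("Composition PCA: %d axes\n", ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert an abundance matrix to row-relative form
#'
#' @param mat Nonnegative matrix; rows are normalized to sum to 1. All-zero
#'   rows stay zero and are flagged in the `zero_rows` attribute.
#' @return Relative matrix with attribute `zero_rows`.
#' @export
relative_biomass <- function(mat) {
  m <- as.matrix(mat)
  rs <- rowSums(m)
  zero <- rs == 0
  rs[zero] <- 1
  structure(m / rs, zero_rows = which(zero))
}
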