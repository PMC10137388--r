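#' Log-transform a feature matrix with zero substitution
#'
#' Lipidomics abundance matrices are log-transformed before univariate
#' testing and ordination. Zeros (missing peaks) are replaced, per feature,
#' by half of that feature's smallest positive value; features that are zero
#' in every sample carry no information and are dropped with a warning.
#'
#' @param mat Numeric matrix, features x samples, non-negative.
#' @param base Logarithm base (default 10).
#' @return The transformed matrix (possibly with fewer rows).
#' @export
preprocess_log <- function(mat, base = 10) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0)) stop("negative entries cannot be log-transformed", call. = FALSE)
  all_zero <- rowSums(mat > 0) == 0
  if (any(all_zero)) {
    warning(sum(all_zero), " all-zero feature(s) dropped before log transform")
    mat <- mat[!all_zero, , drop = FALSE]
  }
  mat <- t(apply(mat, 1, substitute_zeros))
  log(mat, base = base)
}

# half the smallest positive value stands in for missing peaks
substitute_zeros <- function(x) {
  if (any(x == 0)) x[x == 0] <- min(x[x > 0]) / 2
  x
}

#' Choose the parametric or non-parametric test branch for one feature
#'
#' The parametric branch (ANOVA/Tukey) is used only when every group passes
#' the Shapiro-Wilk normality test at `alpha` and the groups pass a
#' median-centred Levene (Brown-Forsythe) homoscedasticity test at `alpha`;
#' otherwise the rank-based branch (Kruskal-Wallis/Dunn) is used. Degenerate
#' inputs -- a constant-valued group (Shapiro-Wilk undefined) or fewer than
#' three observations in some group -- fall back to the non-parametric
#' branch.
#'
#' @param values Numeric vector of one feature's values.
#' @param group Factor (or coercible) of group labels, same length.
#' @param alpha Significance level of the assumption tests (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
choose_test_branch <- function(values, group, alpha = 0.05) {
  group <- as.factor(group)
  split_vals <- split(values, group)
  ns <- lengths(split_vals)
  if (any(ns < 3)) {
    warning("fewer than 3 observations in some group; using the ",
            "non-parametric branch")
    return("nonparametric")
  }
  constant <- vapply(split_vals, function(v) diff(range(v)) == 0, logical(1))
  if (any(constant)) return("nonparametric")
  sw_p <- vapply(split_vals, function(v) stats::shapiro.test(v)$p.value,
                 numeric(1))
  if (any(sw_p <= alpha)) return("nonparametric")
  lev <- car::leveneTest(values ~ group, center = stats::median)
  if (lev[1, "Pr(>F)"] <= alpha) return("nonparametric")
  "parametric"
}

#' Dunn's rank-based post-hoc test
#'
#' All-pairs comparisons following a Kruskal-Wallis omnibus test, using the
#' standard large-sample z statistic on mean ranks with tie correction:
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` where
#' `T = sum(t^3 - t)` over tie groups. Two-sided p-values, adjusted across
#' the pairs with the chosen method.
#'
#' @param values Numeric vector.
#' @param group Factor of group labels.
#' @param p_adjust Adjustment across pairs (default `"BH"`).
#' @return A tibble with `group1`, `group2`, `z`, `p`, `q`.
#' @export
dunn_test <- function(values, group, p_adjust = "BH") {
  group <- as.factor(group)
  n_total <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_total - 1))
  sigma2 <- n_total * (n_total + 1) / 12 - tie_term
  combos <- utils::combn(levels(group), 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]
    g2 <- combos[2, k]
    se <- sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  }) |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = p_adjust))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment of a p-value vector (false discovery rate
#' control). A thin, validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-feature multi-group comparison with assumption gating
#'
#' Runs the univariate comparison workflow on every feature of a
#' (log-transformed) matrix: branch choice via [choose_test_branch()], then
#' one-way ANOVA with Tukey HSD pairwise tests (parametric branch) or
#' Kruskal-Wallis with Dunn pairwise tests (non-parametric branch). Omnibus
#' p-values are BH-adjusted across features into q-values; pairwise
#' p-values are BH-adjusted within each feature across the group pairs.
#'
#' @param mat Numeric matrix, features x samples (rownames = feature ids).
#' @param group Factor of group labels, one per column; at least two groups
#'   with two samples each.
#' @param alpha Assumption-test level passed to [choose_test_branch()].
#' @param pairwise Compute pairwise post-hoc tables (default `TRUE`; skip
#'   for large simulation screens where only omnibus q-values are needed).
#' @return A list with `results` (tibble: `feature`, `branch`, `p`, `q`) and
#'   `pairwise` (tibble: `feature`, `group1`, `group2`, `p`, `q`; `NULL`
#'   when `pairwise = FALSE`).
#' @export
compare_features <- function(mat, group, alpha = 0.05, pairwise = TRUE) {
  stopifnot(is.matrix(mat))
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("at least two groups are required", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("feature_", seq_len(nrow(mat)))

  per_feature <- purrr::map(rownames(mat), function(f) {
    v <- mat[f, ]
    branch <- suppressWarnings(choose_test_branch(v, group, alpha = alpha))
    if (branch == "parametric") {
      fit <- stats::aov(v ~ group)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      pw <- NULL
      if (pairwise) {
        tk <- stats::TukeyHSD(fit)$group
        pairs_split <- strsplit(rownames(tk), "-", fixed = TRUE)
        pw <- tibble::tibble(
          feature = f,
          group1 = vapply(pairs_split, `[`, character(1), 2),
          group2 = vapply(pairs_split, `[`, character(1), 1),
          p = tk[, "p adj"],
          q = stats::p.adjust(tk[, "p adj"], method = "BH")
        )
      }
    } else {
      p <- stats::kruskal.test(v, group)$p.value
      pw <- NULL
      if (pairwise) {
        pw <- dplyr::mutate(dunn_test(v, group), feature = f, .before = 1) |>
          dplyr::select(-"z")
      }
    }
    list(result = tibble::tibble(feature = f, branch = branch, p = p),
         pairwise = pw)
  })

  results <- purrr::map_dfr(per_feature, "result")
  results$q <- adjust_bh(results$p)
  list(
    results = results,
    pairwise = if (pairwise) purrr::map_dfr(per_feature, "pairwise") else NULL
  )
}

#' Most discriminant features by q-value
#'
#' Features with `q < q_max`, sorted by ascending q (ties broken by feature
#' id for determinism) and truncated to the top `k`. May return fewer than
#' `k` features.
#'
#' @param results The `results` tibble from [compare_features()].
#' @param k Maximum number of features to keep (default 50).
#' @param q_max q-value cut-off (default 0.05).
#' @return Character vector of feature ids.
#' @export
top_discriminant <- function(results, k = 50, q_max = 0.05) {
  results |>
    dplyr::filter(.data$q < q_max) |>
    dplyr::arrange(.data$q, .data$feature) |>
    utils::head(k) |>
    dplyr::pull("feature")
}

#' Principal component analysis of a feature matrix
#'
#' PCA of samples on mean-centred (optionally unit-scaled) features, via the
#' singular value decomposition ([stats::prcomp()]). The sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making score plots reproducible across platforms.
#'
#' @param mat Numeric matrix, features x samples (typically log-transformed).
#' @param scale. Scale features to unit variance (default `FALSE`; the
#'   default analyses covariance as abundances are already on a common
#'   log scale).
#' @return A list with `scores` (tibble: `sample_id` + PC columns),
#'   `loadings` (features x PCs matrix) and `explained_variance`
#'   (fractions, non-increasing, summing to <= 1).
#' @export
pca_ordination <- function(mat, scale. = FALSE) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2) stop("at least two samples are required for PCA", call. = FALSE)
  fit <- stats::prcomp(t(mat), center = TRUE, scale. = scale.)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    load <- fit$rotation[, j]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  fit$rotation[, flip] <- -fit$rotation[, flip]
  fit$x[, flip] <- -fit$x[, flip]
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(
    scores = tibble::as_tibble(fit$x, rownames = "sample_id"),
    loadings = fit$rotation,
    explained_variance = expl[seq_len(ncol(fit$x))]
  )
}

#' Ward hierarchical clustering and fold-from-mean heatmap matrix
#'
#' Clusters samples and features by Ward's method on Euclidean distances
#' (the classic `"ward.D"` convention, i.e. on unsquared distances) and
#' computes the displayed heatmap matrix: each cell is the feature's value
#' divided by that feature's grand mean across all samples ("fold
#' difference from the mean"), shown on a log2 scale. Zeros are substituted
#' per feature (half minimum positive) before the fold computation. Both
#' dendrograms are computed on the log2 fold matrix, matching the displayed
#' values.
#'
#' @param mat Numeric non-negative matrix, features x samples (e.g. relative
#'   abundances).
#' @param features Optional character vector restricting the rows (e.g. the
#'   output of [top_discriminant()]).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"ward.D"`).
#' @return A list with `heatmap` (log2 fold-from-mean matrix),
#'   `sample_hclust` and `feature_hclust` (`hclust` objects; feature tree
#'   `NULL` for a single feature).
#' @export
hclust_heatmap <- function(mat, features = NULL, linkage = "ward.D") {
  stopifnot(is.matrix(mat))
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(mat))
    if (length(missing_f) > 0) {
      stop("features not in matrix: ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[features, , drop = FALSE]
  }
  if (any(mat < 0)) stop("fold-from-mean requires non-negative values", call. = FALSE)
  mat <- t(apply(mat, 1, substitute_zeros))
  fold <- sweep(mat, 1, rowMeans(mat), "/")
  heat <- log2(fold)
  list(
    heatmap = heat,
    sample_hclust = stats::hclust(stats::dist(t(heat)), method = linkage),
    feature_hclust = if (nrow(heat) > 1) {
      stats::hclust(stats::dist(heat), method = linkage)
    }
  )
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
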