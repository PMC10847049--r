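#' Minimum-count feature filter
#'
#' Removes features whose total count across samples is strictly below
#' `min_total` (the default excludes taxa with a minimal count of < 5).
#'
#' @param counts An [abundance_matrix()] on the count scale.
#' @param min_total Minimum total count retained (default 5).
#' @return The filtered abundance matrix.
#' @export
min_count_filter <- function(counts, min_total = 5) {
  if (!inherits(counts, "abundance_matrix") || counts$scale != "count")
    stopf("counts must be a count-scale abundance_matrix")
  keep <- rowSums(counts$values) >= min_total
  abundance_matrix(counts$values[keep, , drop = FALSE], scale = "count",
                   feature_lengths = counts$feature_lengths)
}

#' Prevalence feature filter
#'
#' Removes features detected (nonzero) in strictly less than
#' `min_prevalence` of the samples; a feature present in exactly half the
#' samples is kept. Applied to phage features, where absence in about half
#' the samples inflates the risk of spurious associations.
#'
#' @param counts An [abundance_matrix()] (any nonnegative scale).
#' @param min_prevalence Minimum detection fraction retained (default 0.5).
#' @return The filtered abundance matrix.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.5) {
  if (!inherits(counts, "abundance_matrix"))
    stopf("counts must be an abundance_matrix")
  nnz <- rowSums(counts$values > 0)
  keep <- frac_ge(nnz, ncol(counts$values), min_prevalence)
  abundance_matrix(counts$values[keep, , drop = FALSE], scale = counts$scale,
                   feature_lengths = counts$feature_lengths)
}

#' 'const' zero replacement
#'
#' Replaces every zero by `factor` times the smallest positive value in the
#' matrix; nonzero values are untouched. Performed after the feature
#' filters and before the centred log-ratio transform.
#'
#' @param counts An [abundance_matrix()] or plain numeric matrix with at
#'   least one positive value.
#' @param factor Multiplier of the minimum positive value (default 0.65).
#' @return Object of the same kind with strictly positive values.
#' @export
zero_replace_const <- function(counts, factor = 0.65) {
  v <- if (inherits(counts, "abundance_matrix")) counts$values else counts
  pos <- v[v > 0]
  if (length(pos) == 0L) stopf("zero_replace_const: all-zero matrix")
  v[v == 0] <- factor * min(pos)
  if (inherits(counts, "abundance_matrix")) {
    counts$values <- v
    counts
  } else v
}

#' Centred log-ratio transform
#'
#' `clr_ij = ln(x_ij / g_j)` with `g_j` the geometric mean of sample `j`;
#' every sample column of the result sums to zero. Input must be strictly
#' positive (apply [zero_replace_const()] first). The transform is
#' invariant to per-sample scaling of the input.
#'
#' @param x An [abundance_matrix()] or strictly positive numeric matrix
#'   (features x samples).
#' @return An [abundance_matrix()] on the clr scale.
#' @export
clr_transform <- function(x) {
  v <- if (inherits(x, "abundance_matrix")) x$values else x
  if (any(v <= 0)) stopf("clr_transform requires strictly positive values")
  lv <- log(v)
  clr <- sweep(lv, 2L, colMeans(lv), "-")
  abundance_matrix(clr, scale = "clr")
}

#' Aitchison distances between samples
#'
#' Pairwise Euclidean distance between the CLR vectors of the samples --
#' the Aitchison distance of the underlying compositions.
#'
#' @param clr An [abundance_matrix()] on the clr scale.
#' @return A [stats::dist] object over samples.
#' @export
aitchison_distances <- function(clr) {
  if (!inherits(clr, "abundance_matrix") || clr$scale != "clr")
    stopf("clr must be a clr-scale abundance_matrix")
  if (ncol(clr$values) < 2L) stopf("need at least 2 samples")
  stats::dist(t(clr$values), method = "euclidean")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of a single grouping
#' factor, computed with \code{vegan::adonis2}. R-squared is
#' SS_between/SS_total from the Gower-centred squared distances; the
#' p-value is `(1 + #[F_perm >= F_obs]) / (1 + n_permutations)` over free
#' label permutations, so it is never 0.
#'
#' @param d A [stats::dist] object or symmetric distance matrix with sample
#'   labels.
#' @param group Grouping vector aligned with the distance labels (or a
#'   design data frame with `sample_id` and `group`).
#' @param n_permutations Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class `permanova_result`: `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, group, n_permutations = 999, seed = NULL) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12)))
      stopf("distance matrix is not symmetric")
    d <- stats::as.dist(m)
  }
  labs <- labels(d)
  if (is.data.frame(group)) {
    assert_cols(group, c("sample_id", "group"), "design")
    idx <- match(labs, group$sample_id)
    if (anyNA(idx)) stopf("design is missing sample '%s'", labs[is.na(idx)][1L])
    group <- group$group[idx]
  }
  group <- factor(group)
  n <- attr(d, "Size")
  if (length(group) != n) stopf("group length does not match the distance matrix")
  tab <- table(group)
  if (length(tab) < 2L) stopf("PERMANOVA needs at least 2 groups")
  if (any(tab < 2L)) stopf("every group needs at least 2 samples")
  if (sum(d^2) == 0) {
    warnf("permanova: total sum of squares is 0; p = 1")
    return(structure(list(r_squared = 0, pseudo_f = 0, p_value = 1,
                          n_permutations = n_permutations, seed = seed),
                     class = "permanova_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(group = group)
  fit <- vegan::adonis2(d ~ group, data = df, permutations = n_permutations)
  structure(list(
    r_squared = fit$R2[1L],
    pseudo_f = fit$F[1L],
    p_value = fit$`Pr(>F)`[1L],
    n_permutations = n_permutations,
    seed = seed
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Principal component analysis of CLR data
#'
#' PCA of the samples on the feature-centred covariance of the CLR matrix.
#' The sign of each component is fixed by forcing its largest-magnitude
#' loading positive, so scores are deterministic.
#'
#' @param clr An [abundance_matrix()] on the clr scale.
#' @return List with `scores` (samples x components), `loadings`,
#'   `explained_variance` (fractions summing to 1).
#' @export
pca_on_clr <- function(clr) {
  if (!inherits(clr, "abundance_matrix") || clr$scale != "clr")
    stopf("clr must be a clr-scale abundance_matrix")
  if (ncol(clr$values) < 2L) stopf("need at least 2 samples")
  pc <- stats::prcomp(t(clr$values), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, "*")
  loadings <- sweep(pc$rotation, 2L, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, explained_variance = ev)
}

#' Hill-number alpha diversity
#'
#' Effective number of features of order `q` computed on the relative
#' proportions of one sample: `q = 0` richness, `q = 1` the exponential of
#' Shannon entropy, `q = 2` the inverse Simpson index.
#'
#' @param counts Nonnegative abundance vector for one sample with a
#'   positive total.
#' @param q Diversity order (nonnegative real; 0, 1 and 2 are the usual
#'   choices).
#' @return The Hill number (effective feature count).
#' @export
hill_alpha <- function(counts, q = 1) {
  if (any(counts < 0)) stopf("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stopf("hill_alpha: zero total count")
  p <- counts[counts > 0] / total
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}
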