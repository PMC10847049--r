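#' Exclude statistical outliers by the 2.5-SD rule
#'
#' Values more than `sd_limit` standard deviations from their group mean
#' are flagged in a single pass (means and SDs are not recomputed after
#' removal) and at most `max_exclusions` values are excluded per test (the
#' largest deviations first). Intended for assay endpoints, never for
#' sequencing count matrices.
#'
#' @param values Numeric vector of measurements.
#' @param groups Optional grouping vector (default: one group). Every group
#'   needs at least 3 values.
#' @param sd_limit Exclusion threshold in SD units (default 2.5).
#' @param max_exclusions Cap on exclusions per test (default 2).
#' @return List with `values` and `groups` (retained) and `excluded` (data
#'   frame of index, value, group, z).
#' @export
exclude_outliers <- function(values, groups = NULL, sd_limit = 2.5,
                             max_exclusions = 2L) {
  if (is.null(groups)) groups <- rep("all", length(values))
  groups <- as.character(groups)
  if (length(groups) != length(values))
    stopf("groups must match values in length")
  if (any(table(groups) < 3L))
    stopf("every group needs at least 3 values for outlier screening")
  z <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    m <- mean(values[idx])
    s <- stats::sd(values[idx])
    z[idx] <- if (s == 0) 0 else abs(values[idx] - m) / s
  }
  cand <- which(z > sd_limit)
  if (length(cand) > max_exclusions)
    cand <- cand[order(-z[cand])][seq_len(max_exclusions)]
  excluded <- data.frame(index = cand, value = values[cand],
                         group = groups[cand], z = z[cand],
                         stringsAsFactors = FALSE)
  keep <- setdiff(seq_along(values), cand)
  list(values = values[keep], groups = groups[keep], excluded = excluded)
}

#' Variance pre-filter for expression matrices
#'
#' Removes features whose across-sample variance falls below an absolute
#' cut-off (default 0.5, on the log/CLR expression scale).
#'
#' @param x An [abundance_matrix()] (clr scale) or numeric matrix,
#'   features in rows.
#' @param cutoff Minimum variance retained (default 0.5).
#' @return The filtered object, same kind as the input.
#' @export
variance_prefilter <- function(x, cutoff = 0.5) {
  v <- if (inherits(x, "abundance_matrix")) x$values else x
  keep <- apply(v, 1L, stats::var) >= cutoff
  if (inherits(x, "abundance_matrix")) {
    x$values <- v[keep, , drop = FALSE]
    x
  } else v[keep, , drop = FALSE]
}

restoration_groups <- c("Ctr", "CtrStress", "FVTStress")

check_restoration_design <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), restoration_groups)
  if (length(bad) > 0L)
    stopf("unknown group '%s' (expected %s)", bad[1L],
          paste(restoration_groups, collapse = ", "))
  miss <- setdiff(restoration_groups, unique(group))
  if (length(miss) > 0L)
    stopf("missing group '%s' in the design", miss[1L])
  tab <- table(group)
  if (any(tab < 2L)) stopf("every group needs at least 2 samples")
  factor(group, levels = restoration_groups)
}

#' Restoration effect by planned orthogonal contrast
#'
#' One-way fixed-effects model on the three study groups with the
#' restoration contrast weighing Ctr and FVT Stress against Ctr Stress
#' (weights +0.5, -1, +0.5 on the group means; rescaling the weights by a
#' positive constant leaves t and p unchanged). The estimate is
#' `L = 0.5 m_Ctr - m_CtrStress + 0.5 m_FVT`, its standard error
#' `s_pooled * sqrt(sum(w^2 / n))`, and `t = L / SE` on `N - 3` degrees of
#' freedom with a two-sided p-value.
#'
#' @param values Numeric vector of per-sample measurements (CLR abundance
#'   or log expression) for one feature.
#' @param group Group labels (`Ctr`, `CtrStress`, `FVTStress`) aligned with
#'   `values`, or a design data frame with a `group` column.
#' @param weights Contrast weights on the group means in the order Ctr,
#'   CtrStress, FVTStress.
#' @return One-row data frame: `contrast_estimate`, `t_statistic`, `df`,
#'   `p_restoration`, `direction` (sign of the stress shift).
#' @export
restoration_contrast <- function(values, group,
                                 weights = c(0.5, -1, 0.5)) {
  if (is.data.frame(group)) group <- group$group
  group <- check_restoration_design(group)
  if (length(values) != length(group))
    stopf("values and group lengths differ")
  n <- tapply(values, group, length)
  m <- tapply(values, group, mean)
  ss <- tapply(values, group, function(v) sum((v - mean(v))^2))
  N <- length(values)
  df <- N - 3L
  s2 <- sum(ss) / df
  L <- sum(weights * m)
  se <- sqrt(s2 * sum(weights^2 / n))
  direction <- sign(m["CtrStress"] - (m["Ctr"] + m["FVTStress"]) / 2)
  if (se == 0) {
    warnf("restoration_contrast: zero pooled variance")
    p <- if (L != 0) 0 else 1
    t <- if (L != 0) Inf * sign(L) else 0
  } else {
    t <- L / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(contrast_estimate = unname(L), t_statistic = unname(t),
             df = df, p_restoration = unname(p),
             direction = unname(direction))
}

#' Tukey post hoc pairwise comparisons
#'
#' Studentized-range adjusted p-values for the pairwise comparisons
#' Ctr vs Ctr Stress and Ctr Stress vs FVT Stress, with `k = 3` means and
#' `N - 3` error degrees of freedom (tail probabilities from
#' \code{stats::ptukey}). Two-sided by default; `one_sided = TRUE` halves
#' the adjusted p-value (directional reading of the same statistic).
#'
#' @inheritParams restoration_contrast
#' @param pairs List of 2-vectors of group names to compare.
#' @param one_sided Halve the adjusted p-values (default FALSE).
#' @return Data frame with `group_a`, `group_b`, `estimate`, `p_adjusted`.
#' @export
tukey_pairwise <- function(values, group,
                           pairs = list(c("Ctr", "CtrStress"),
                                        c("CtrStress", "FVTStress")),
                           one_sided = FALSE) {
  if (is.data.frame(group)) group <- group$group
  group <- check_restoration_design(group)
  n <- tapply(values, group, length)
  m <- tapply(values, group, mean)
  ss <- tapply(values, group, function(v) sum((v - mean(v))^2))
  N <- length(values)
  df <- N - 3L
  s <- sqrt(sum(ss) / df)
  out <- lapply(pairs, function(pr) {
    est <- m[pr[1L]] - m[pr[2L]]
    if (s == 0) {
      p <- if (est != 0) 0 else 1
    } else {
      q <- abs(est) / (s * sqrt(0.5 * (1 / n[pr[1L]] + 1 / n[pr[2L]])))
      p <- stats::ptukey(q, nmeans = 3, df = df, lower.tail = FALSE)
    }
    if (one_sided) p <- p / 2
    data.frame(group_a = pr[1L], group_b = pr[2L], estimate = unname(est),
               p_adjusted = unname(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min over j >= i of p_(j) * m / j`,
#' reported in the original order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Feature-wise restoration testing with FDR control
#'
#' Applies [restoration_contrast()] and [tukey_pairwise()] to every feature
#' (row) of a CLR abundance or log-expression matrix, then adjusts the
#' restoration p-values across features by [bh_fdr()]. A feature is called
#' restored when its contrast p-value passes `alpha` and its q-value passes
#' `q_cutoff`.
#'
#' @param x An [abundance_matrix()] on the clr scale or a numeric matrix,
#'   features in rows, samples in columns.
#' @param design Data frame with `sample_id` and `group`, or a group vector
#'   aligned with the columns.
#' @param weights Contrast weights (see [restoration_contrast()]).
#' @param alpha Contrast p-value threshold for a restoration call
#'   (default 0.05).
#' @param q_cutoff BH-FDR q-value threshold (default 0.2).
#' @param one_sided Passed to [tukey_pairwise()].
#' @return Data frame with one row per feature: contrast statistics,
#'   `q_value`, the two Tukey-adjusted pairwise p-values and the
#'   `restored_call` flag.
#' @export
restoration_test <- function(x, design, weights = c(0.5, -1, 0.5),
                             alpha = 0.05, q_cutoff = 0.2,
                             one_sided = FALSE) {
  v <- if (inherits(x, "abundance_matrix")) x$values else x
  group <- resolve_group(design, colnames(v))
  rows <- lapply(seq_len(nrow(v)), function(i) {
    rc <- restoration_contrast(v[i, ], group, weights)
    tk <- tukey_pairwise(v[i, ], group, one_sided = one_sided)
    cbind(data.frame(feature_id = rownames(v)[i], stringsAsFactors = FALSE),
          rc,
          data.frame(p_ctr_vs_stress = tk$p_adjusted[1L],
                     p_stress_vs_fvt = tk$p_adjusted[2L]))
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_restoration)
  res$restored_call <- res$p_restoration < alpha & res$q_value < q_cutoff
  res
}

resolve_group <- function(design, sample_ids) {
  if (is.data.frame(design)) {
    assert_cols(design, c("sample_id", "group"), "design")
    idx <- match(sample_ids, design$sample_id)
    if (anyNA(idx))
      stopf("design is missing sample '%s'", sample_ids[is.na(idx)][1L])
    design$group[idx]
  } else design
}

#' Longitudinal restoration by a random-intercept mixed model
#'
#' Compound-symmetry linear mixed model for complete repeated-measures
#' designs: fixed group, timepoint and group-by-timepoint effects (the cell
#' means) plus a random intercept per subject. Variance components come
#' from the split-plot decomposition -- `MS_subject` (between subjects
#' within groups) estimates `T * sigma_s^2 + sigma_e^2` and `MS_residual`
#' (within-subject) estimates `sigma_e^2` -- so the variance of one
#' observation is estimated by `(MS_subject + (T - 1) MS_residual) / T`.
#' The restoration contrast is evaluated on the final-timepoint group
#' means, with Satterthwaite degrees of freedom. With a single timepoint,
#' or when the within-subject mean square vanishes, the result reduces
#' exactly to the cross-sectional [restoration_contrast()].
#'
#' @param values Numeric vector of measurements for one feature, one per
#'   (subject, timepoint) observation.
#' @param design Data frame aligned with `values`, with columns `group`,
#'   `subject_id` and `timepoint` (ordered by sort order or factor levels);
#'   every subject must be observed at every timepoint exactly once.
#' @param weights Contrast weights on the final-timepoint group means.
#' @return One-row data frame: `contrast_estimate`, `t_statistic`, `df`,
#'   `p_restoration`, `direction`, plus the variance components
#'   `sigma_subject` and `sigma_residual`.
#' @export
longitudinal_restoration <- function(values, design,
                                     weights = c(0.5, -1, 0.5)) {
  assert_cols(design, c("group", "subject_id", "timepoint"), "design")
  if (length(values) != nrow(design))
    stopf("values and design lengths differ")
  subj_group <- unique(design[, c("subject_id", "group")])
  if (anyDuplicated(subj_group$subject_id))
    stopf("subject '%s' appears in more than one group",
          subj_group$subject_id[duplicated(subj_group$subject_id)][1L])
  tp <- if (is.factor(design$timepoint)) design$timepoint
        else factor(design$timepoint, levels = sort(unique(design$timepoint)))
  subj <- factor(design$subject_id)
  tab <- table(subj, tp)
  if (any(tab != 1L))
    stopf("design must be complete: every subject observed once per timepoint")
  Tn <- nlevels(tp)
  group <- check_restoration_design(design$group)
  if (Tn == 1L) {
    rc <- restoration_contrast(values, group, weights)
    rc$sigma_subject <- NA_real_
    rc$sigma_residual <- sqrt(sum(tapply(values, group,
      function(v) sum((v - mean(v))^2))) / rc$df)
    return(rc)
  }
  subj_mean <- tapply(values, subj, mean)
  subj_grp <- subj_group$group[match(levels(subj), subj_group$subject_id)]
  grp_mean <- tapply(subj_mean, subj_grp, mean)
  n_g <- table(factor(subj_grp, levels = restoration_groups))
  N <- nlevels(subj)
  k <- 3L
  ss_subj <- Tn * sum((subj_mean - grp_mean[subj_grp])^2)
  df_subj <- N - k
  cell_mean <- tapply(values, list(group, tp), mean)
  resid <- values - cell_mean[cbind(as.character(group), as.character(tp))] -
    (subj_mean[as.character(subj)] - grp_mean[as.character(subj_grp[match(subj, levels(subj))])])
  ss_res <- sum(resid^2)
  df_res <- (N - k) * (Tn - 1L)
  ms_subj <- ss_subj / df_subj
  ms_res <- ss_res / df_res
  s2_obs <- (ms_subj + (Tn - 1L) * ms_res) / Tn
  sigma_e2 <- ms_res
  sigma_s2 <- max((ms_subj - ms_res) / Tn, 0)
  final <- levels(tp)[Tn]
  m_final <- cell_mean[restoration_groups, final]
  L <- sum(weights * m_final)
  var_L <- s2_obs * sum(weights^2 / as.numeric(n_g))
  a <- ms_subj / Tn
  b <- (Tn - 1L) / Tn * ms_res
  df_sat <- if (s2_obs == 0) df_subj else
    s2_obs^2 / (a^2 / df_subj + if (df_res > 0) b^2 / df_res else 0)
  direction <- sign(m_final["CtrStress"] -
                      (m_final["Ctr"] + m_final["FVTStress"]) / 2)
  if (var_L == 0) {
    warnf("longitudinal_restoration: zero variance estimate")
    p <- if (L != 0) 0 else 1
    t <- if (L != 0) Inf * sign(L) else 0
  } else {
    t <- L / sqrt(var_L)
    p <- 2 * stats::pt(-abs(t), df_sat)
  }
  data.frame(contrast_estimate = unname(L), t_statistic = unname(t),
             df = unname(df_sat), p_restoration = unname(p),
             direction = unname(direction),
             sigma_subject = sqrt(sigma_s2), sigma_residual = sqrt(sigma_e2))
}

#' Feature-wise longitudinal restoration testing
#'
#' Applies [longitudinal_restoration()] to every feature (row) and adjusts
#' the p-values across features by [bh_fdr()].
#'
#' @param x An [abundance_matrix()] (clr scale) or numeric matrix, columns
#'   matching `design$sample_id`.
#' @param design Data frame with `sample_id`, `group`, `subject_id`,
#'   `timepoint`.
#' @inheritParams restoration_test
#' @return Data frame with one row per feature, including `q_value` and
#'   `restored_call`.
#' @export
longitudinal_restoration_test <- function(x, design,
                                          weights = c(0.5, -1, 0.5),
                                          alpha = 0.05, q_cutoff = 0.2) {
  v <- if (inherits(x, "abundance_matrix")) x$values else x
  assert_cols(design, c("sample_id", "group", "subject_id", "timepoint"),
              "design")
  idx <- match(colnames(v), design$sample_id)
  if (anyNA(idx))
    stopf("design is missing sample '%s'", colnames(v)[is.na(idx)][1L])
  design <- design[idx, , drop = FALSE]
  rows <- lapply(seq_len(nrow(v)), function(i) {
    cbind(data.frame(feature_id = rownames(v)[i], stringsAsFactors = FALSE),
          longitudinal_restoration(v[i, ], design, weights))
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_restoration)
  res$restored_call <- res$p_restoration < alpha & res$q_value < q_cutoff
  res
}

#' Hypergeometric enrichment test
#'
#' Upper-tail (inclusive) hypergeometric probability of observing at least
#' the overlap between a query gene set and a term's gene set within a
#' universe, via \code{stats::phyper}.
#'
#' @param query Character vector of query feature ids.
#' @param term Character vector of the term's feature ids.
#' @param universe Universe size (single integer) or character vector of
#'   universe feature ids (then query and term must be subsets).
#' @param term_id Optional term label carried into the result.
#' @return One-row data frame: `term_id`, `overlap`, `term_size`,
#'   `query_size`, `universe_size`, `p_value`.
#' @export
hypergeometric_enrichment <- function(query, term, universe,
                                      term_id = NA_character_) {
  query <- unique(query)
  term <- unique(term)
  if (length(universe) == 1L && is.numeric(universe)) {
    universe_size <- as.integer(universe)
  } else {
    universe <- unique(universe)
    if (length(setdiff(query, universe)) > 0L)
      stopf("query contains ids outside the universe")
    if (length(setdiff(term, universe)) > 0L)
      stopf("term contains ids outside the universe")
    universe_size <- length(universe)
  }
  if (length(term) > universe_size || length(query) > universe_size)
    stopf("term/query larger than the universe")
  overlap <- length(intersect(query, term))
  p <- stats::phyper(overlap - 1L, m = length(term),
                     n = universe_size - length(term),
                     k = length(query), lower.tail = FALSE)
  data.frame(term_id = term_id, overlap = overlap,
             term_size = length(term), query_size = length(query),
             universe_size = universe_size, p_value = p,
             stringsAsFactors = FALSE)
}
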