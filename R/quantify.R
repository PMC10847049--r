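#' Abundance matrix container
#'
#' A features-by-samples numeric matrix tagged with its scale. Relative
#' columns must sum to 1 (or 0 for an all-zero sample); CLR columns must
#' sum to 0.
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param scale One of `"count"`, `"relative"`, `"absolute"`, `"clr"`.
#' @param feature_lengths Optional named vector of feature lengths (bp),
#'   carried for count/relative scales.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values,
                             scale = c("count", "relative", "absolute", "clr"),
                             feature_lengths = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must have feature rownames and sample colnames")
  if (scale %in% c("count", "relative", "absolute") && any(values < 0, na.rm = TRUE))
    stopf("%s-scale values must be nonnegative", scale)
  if (scale == "relative") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-12 & cs != 0))
      stopf("relative-scale columns must sum to 1 (or 0 for empty samples)")
  }
  if (scale == "clr") {
    cs <- colSums(values)
    if (any(abs(cs) > 1e-9, na.rm = TRUE))
      stopf("clr-scale columns must sum to 0")
  }
  if (!is.null(feature_lengths)) {
    feature_lengths <- feature_lengths[rownames(values)]
    if (anyNA(feature_lengths))
      stopf("feature_lengths missing for some features")
  }
  structure(list(values = values, scale = scale,
                 feature_lengths = feature_lengths),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s scale]: %d features x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' Zero out spurious mapping counts by breadth of coverage
#'
#' Mapped read counts are set to 0 for any record whose breadth (fraction
#' of contig positions with depth >= 1) is strictly below `min_breadth`;
#' records at or above the threshold are untouched. Idempotent and monotone
#' in the threshold.
#'
#' @param mapping Mapping records as [read_mapping()].
#' @param min_breadth Minimum breadth (default 0.75).
#' @return The mapping records with filtered counts (breadth of zeroed
#'   records is also set to 0 to preserve the zero-count invariant).
#' @export
apply_breadth_filter <- function(mapping, min_breadth = 0.75) {
  zero <- mapping$breadth < min_breadth & mapping$mapped_reads > 0
  mapping$mapped_reads[zero] <- 0L
  mapping$breadth[mapping$mapped_reads == 0] <- 0
  msgf("apply_breadth_filter: zeroed %d of %d records with breadth < %g",
       sum(zero), nrow(mapping), min_breadth)
  mapping
}

#' Relative abundance by length normalisation and total-sum scaling
#'
#' Each count is divided by its contig length and by the sample's total
#' mapped reads, then every sample column is rescaled to sum to 1
#' (total-sum scaling). All-zero samples stay zero with a warning.
#'
#' @param mapping Mapping records (after [apply_breadth_filter()]),
#'   restricted by the caller to quantitatively included features.
#' @param features Data frame with `feature_id` and `length` (bp) of the
#'   features to quantify; mapping records for other contigs are ignored.
#' @param design Sample design with `sample_id` and `total_mapped_reads`.
#' @return An [abundance_matrix()] on the relative scale.
#' @export
relative_abundance <- function(mapping, features, design) {
  assert_cols(features, c("feature_id", "length"), "feature table")
  assert_cols(design, c("sample_id", "total_mapped_reads"), "design table")
  if (any(design$total_mapped_reads <= 0))
    stopf("total_mapped_reads must be positive")
  mapping <- mapping[mapping$contig_id %in% features$feature_id, , drop = FALSE]
  unknown <- setdiff(unique(mapping$sample_id), design$sample_id)
  if (length(unknown) > 0L)
    stopf("mapping references sample '%s' absent from the design", unknown[1L])
  if (anyDuplicated(mapping[, c("contig_id", "sample_id")]))
    stopf("mapping has more than one record per (contig, sample) pair")
  len <- stats::setNames(features$length, features$feature_id)
  mat <- matrix(0, nrow = nrow(features), ncol = nrow(design),
                dimnames = list(features$feature_id, design$sample_id))
  mat[cbind(mapping$contig_id, mapping$sample_id)] <- mapping$mapped_reads
  v <- mat / len[rownames(mat)]
  v <- sweep(v, 2L, design$total_mapped_reads, "/")
  cs <- colSums(v)
  zero_cols <- cs == 0
  if (any(zero_cols))
    warnf("relative_abundance: all-zero sample(s): %s",
          paste(colnames(v)[zero_cols], collapse = ", "))
  cs[zero_cols] <- 1
  v <- sweep(v, 2L, cs, "/")
  abundance_matrix(v, scale = "relative", feature_lengths = len)
}

#' Spike-in anchored absolute abundance
#'
#' Converts relative abundances to absolute units by proportionality to a
#' spiked feature of known amount: `abs = rel / rel_spike * spike_amount`.
#' The spike row of the result equals `spike_amount` in every sample.
#' Samples in which the spike has zero relative abundance are flagged and
#' their absolute values set to missing (never silently zero).
#'
#' @param rel An [abundance_matrix()] on the relative scale.
#' @param spike_feature_id Feature id of the spike (e.g. the Q33 contig).
#' @param spike_amount Known spike amount per sample (default 1e6 units,
#'   from a 10 ul spike of 1e8 pfu/ml).
#' @return An [abundance_matrix()] on the absolute scale.
#' @export
spike_absolute <- function(rel, spike_feature_id, spike_amount = 1e6) {
  if (!inherits(rel, "abundance_matrix") || rel$scale != "relative")
    stopf("rel must be a relative-scale abundance_matrix")
  v <- rel$values
  if (!spike_feature_id %in% rownames(v))
    stopf("spike feature '%s' not present in the matrix", spike_feature_id)
  spike <- v[spike_feature_id, ]
  bad <- spike == 0
  if (any(bad))
    warnf("spike_absolute: spike absent in sample(s) %s; absolute values set to NA",
          paste(colnames(v)[bad], collapse = ", "))
  spike[bad] <- NA_real_
  out <- sweep(v, 2L, spike, "/") * spike_amount
  abundance_matrix(out, scale = "absolute")
}
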