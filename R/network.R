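#' Phage-bacteria cross-layer correlations
#'
#' Pearson correlation of every (phage, bacterium) feature pair across the
#' shared samples of two CLR matrices, with a two-sided p-value from the
#' t transform on `n - 2` degrees of freedom and BH-FDR adjustment across
#' all tested pairs. Edges are retained when `q < q_cutoff` (strict).
#' Zero-variance features are skipped with a warning.
#'
#' @param phage_clr,bact_clr [abundance_matrix()] objects on the clr scale
#'   with identical, identically ordered sample columns.
#' @param q_cutoff BH-FDR retention threshold (default 0.1).
#' @param keep_all Return all tested pairs instead of only retained edges.
#' @return Data frame of network edges: `phage_id`, `bacterium_id`,
#'   `pearson_r`, `p_value`, `q_value` (plus `retained` when
#'   `keep_all = TRUE`).
#' @export
crosslayer_correlations <- function(phage_clr, bact_clr, q_cutoff = 0.1,
                                    keep_all = FALSE) {
  pv <- if (inherits(phage_clr, "abundance_matrix")) phage_clr$values else phage_clr
  bv <- if (inherits(bact_clr, "abundance_matrix")) bact_clr$values else bact_clr
  if (!identical(colnames(pv), colnames(bv)))
    stopf("phage and bacterial matrices must share identically ordered samples")
  n <- ncol(pv)
  if (n < 4L) stopf("need at least 4 shared samples")
  pvar <- apply(pv, 1L, stats::var)
  bvar <- apply(bv, 1L, stats::var)
  if (any(pvar == 0) || any(bvar == 0)) {
    warnf("crosslayer_correlations: skipping %d zero-variance feature(s)",
          sum(pvar == 0) + sum(bvar == 0))
    pv <- pv[pvar > 0, , drop = FALSE]
    bv <- bv[bvar > 0, , drop = FALSE]
  }
  r <- stats::cor(t(pv), t(bv))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  edges <- data.frame(
    phage_id = rep(rownames(pv), times = ncol(r)),
    bacterium_id = rep(colnames(r), each = nrow(r)),
    pearson_r = as.vector(r),
    p_value = as.vector(p),
    stringsAsFactors = FALSE
  )
  edges$q_value <- bh_fdr(edges$p_value)
  edges$retained <- edges$q_value < q_cutoff
  if (!keep_all) {
    edges <- edges[edges$retained, , drop = FALSE]
    edges$retained <- NULL
  }
  rownames(edges) <- NULL
  edges
}

# Default synonym table for renamed bacterial phyla, applied (case-folded)
# before concordance matching.
phylum_synonyms <- data.frame(
  from = c("firmicutes", "bacteroidetes", "proteobacteria",
           "actinobacteria", "verrucomicrobia"),
  to = c("bacillota", "bacteroidota", "pseudomonadota",
         "actinomycetota", "verrucomicrobiota"),
  stringsAsFactors = FALSE
)

canon_taxon <- function(x, synonyms) {
  lx <- tolower(trimws(as.character(x)))
  idx <- match(lx, synonyms$from)
  lx[!is.na(idx)] <- synonyms$to[idx[!is.na(idx)]]
  lx[lx == "" | is.na(x)] <- NA_character_
  lx
}

#' Annotate network edges with host-prediction concordance
#'
#' For each edge, records the deepest taxonomic rank (family > order >
#' phylum) at which the phage's predicted host taxon equals the
#' bacterium's taxon, `"none"` when ranks disagree everywhere, and
#' `"unknown"` when the phage has no host prediction. Taxon names are
#' compared case-folded after applying a synonym table for renamed phyla.
#'
#' @param edges Data frame from [crosslayer_correlations()].
#' @param predictions Host predictions as [read_host_predictions()].
#' @param taxonomy Data frame with `bacterium_id`, `phylum`, `order`,
#'   `family` for the bacterial features.
#' @param synonyms Two-column data frame (`from`, `to`) of taxon renames.
#' @return The edges with a `predicted_host_match` column.
#' @export
annotate_host_concordance <- function(edges, predictions, taxonomy,
                                      synonyms = phylum_synonyms) {
  assert_cols(taxonomy, c("bacterium_id", "phylum", "order", "family"),
              "taxonomy table")
  pidx <- match(edges$phage_id, predictions$contig_id)
  bidx <- match(edges$bacterium_id, taxonomy$bacterium_id)
  if (anyNA(bidx))
    stopf("taxonomy is missing bacterium '%s'",
          edges$bacterium_id[is.na(bidx)][1L])
  match_level <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (is.na(pidx[i])) {
      match_level[i] <- "unknown"
      next
    }
    pred <- predictions[pidx[i], ]
    tax <- taxonomy[bidx[i], ]
    lvl <- "none"
    for (rank in c("phylum", "order", "family")) {
      p <- canon_taxon(pred[[paste0("host_", rank)]], synonyms)
      b <- canon_taxon(tax[[rank]], synonyms)
      if (!is.na(p) && !is.na(b) && p == b) lvl <- rank
    }
    match_level[i] <- lvl
  }
  edges$predicted_host_match <- match_level
  edges
}

#' Flag edges whose both endpoints show a restoration effect
#'
#' An edge is flagged when both its phage and its bacterium have a
#' restoration contrast p-value strictly below `p_cutoff`.
#'
#' @param edges Data frame of network edges.
#' @param phage_restoration,bact_restoration Restoration results (from
#'   [restoration_test()]) for the two layers, with `feature_id` and
#'   `p_restoration`.
#' @param p_cutoff Strict threshold on both endpoint p-values
#'   (default 0.05).
#' @return The edges with a `restoration_flagged` column.
#' @export
flag_restored_edges <- function(edges, phage_restoration, bact_restoration,
                                p_cutoff = 0.05) {
  pidx <- match(edges$phage_id, phage_restoration$feature_id)
  bidx <- match(edges$bacterium_id, bact_restoration$feature_id)
  if (anyNA(pidx))
    stopf("restoration results missing for phage '%s'",
          edges$phage_id[is.na(pidx)][1L])
  if (anyNA(bidx))
    stopf("restoration results missing for bacterium '%s'",
          edges$bacterium_id[is.na(bidx)][1L])
  edges$restoration_flagged <-
    phage_restoration$p_restoration[pidx] < p_cutoff &
    bact_restoration$p_restoration[bidx] < p_cutoff
  edges
}
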