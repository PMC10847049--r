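#' Merged-interval coverage fraction of a contig
#'
#' Fraction of a contig's length covered by the union of query intervals of
#' hits whose percent identity is at least `min_identity`. Used by the
#' nucleotide evidence route, where a contig qualifies when any combination
#' of database hits at >= 50% identity covers >= 85% of its length.
#'
#' @param hits Data frame of hits on one contig (columns `q_start`,
#'   `q_end`, `pct_identity`); may be empty.
#' @param contig_length Contig length in bp (>= 1).
#' @param min_identity Minimum percent identity for a hit to contribute.
#' @return Covered fraction in \[0, 1\].
#' @export
merged_coverage_fraction <- function(hits, contig_length, min_identity = 50) {
  if (contig_length < 1L) stopf("contig_length must be >= 1")
  if (nrow(hits) == 0L) return(0)
  if (any(hits$q_start < 1L) || any(hits$q_end > contig_length))
    stopf("hit interval outside [1, %d]", contig_length)
  h <- hits[hits$pct_identity >= min_identity, , drop = FALSE]
  if (nrow(h) == 0L) return(0)
  interval_union_length(h$q_start, h$q_end) / contig_length
}

#' Nucleotide evidence route
#'
#' TRUE when hits at >= `min_identity` percent identity jointly cover at
#' least `min_coverage` of the contig length (both boundaries inclusive).
#' Hits are expected to be pre-filtered to the e-value cut-off (1e-10).
#'
#' @inheritParams merged_coverage_fraction
#' @param min_coverage Minimum covered fraction (default 0.85).
#' @return Logical.
#' @export
nucleotide_rule <- function(hits, contig_length, min_identity = 50,
                            min_coverage = 0.85) {
  cov <- merged_coverage_fraction(hits, contig_length, min_identity)
  frac_ge(cov * contig_length, contig_length, min_coverage)
}

#' Protein evidence route
#'
#' TRUE when at least `min_orfs` distinct ORFs of the contig are hit by any
#' protein database and those hit ORFs account for at least `min_fraction`
#' of the contig's ORF count. An ORF hit in several databases counts once.
#'
#' @param orfs Data frame of the contig's ORF calls (column `orf_id`).
#' @param hits Data frame of protein hits (column `orf_id`), restricted to
#'   this contig's ORFs.
#' @param min_orfs Minimum number of distinct hit ORFs (default 2).
#' @param min_fraction Minimum hit fraction of the ORF count (default 0.5).
#' @return Logical.
#' @export
protein_rule <- function(orfs, hits, min_orfs = 2L, min_fraction = 0.5) {
  total <- length(unique(orfs$orf_id))
  hit_orfs <- unique(hits$orf_id)
  if (total == 0L) {
    if (length(hit_orfs) > 0L)
      stopf("protein hits present but the contig has no ORF calls")
    return(FALSE)
  }
  stray <- setdiff(hit_orfs, orfs$orf_id)
  if (length(stray) > 0L)
    stopf("protein hit references unknown ORF '%s'", stray[1L])
  h <- length(hit_orfs)
  h >= min_orfs && frac_ge(h, total, min_fraction)
}

#' Triage contigs through the five viral evidence routes
#'
#' A contig is putatively viral when it passes any of: the nucleotide
#' homology route (>= 85% of its length covered by >= 50% identity hits),
#' the protein route (>= 2 hit ORFs making up >= 50% of the ORF count), a
#' positive VirSorter2 call, a positive DeepVirFinder call, or circularity
#' (VRCA). Any rRNA hit vetoes the call. `effective_length` is initialised
#' to the contig length; provirus trimming and the length re-filter are
#' applied by [refine_and_filter()].
#'
#' @param contigs Data frame with `id` and `length`.
#' @param nuc_hits Nucleotide hits (pre-filtered to e <= 1e-10), columns as
#'   [read_nuc_hits()].
#' @param orfs ORF calls as [read_orfs()].
#' @param protein_hits Protein hits as [read_protein_hits()], with a
#'   `contig_id` column or ORF ids resolvable through `orfs`.
#' @param tool_calls Stand-alone classifier calls as [read_tool_calls()].
#' @param rrna_hits rRNA hits as [read_rrna_hits()].
#' @param min_identity,min_coverage Nucleotide route thresholds.
#' @param min_orfs,min_fraction Protein route thresholds.
#' @return Data frame of triage decisions, one row per input contig.
#' @export
triage_contigs <- function(contigs, nuc_hits, orfs, protein_hits, tool_calls,
                           rrna_hits, min_identity = 50, min_coverage = 0.85,
                           min_orfs = 2L, min_fraction = 0.5) {
  if (anyDuplicated(contigs$id))
    stopf("duplicate contig id '%s'", contigs$id[duplicated(contigs$id)][1L])
  known <- contigs$id
  for (tab in list(nuc_hits = nuc_hits$query_id, orfs = orfs$contig_id,
                   tool_calls = tool_calls$contig_id,
                   rrna_hits = rrna_hits$contig_id)) {
    unknown <- setdiff(unique(tab), known)
    if (length(unknown) > 0L)
      stopf("evidence references unknown contig '%s'", unknown[1L])
  }
  if (!"contig_id" %in% names(protein_hits)) {
    idx <- match(protein_hits$orf_id, orfs$orf_id)
    if (anyNA(idx))
      stopf("protein hit references unknown ORF '%s'",
            protein_hits$orf_id[is.na(idx)][1L])
    protein_hits$contig_id <- orfs$contig_id[idx]
  }
  tool_pos <- function(tool) {
    pos <- tool_calls$contig_id[tool_calls$tool == tool & tool_calls$positive]
    known %in% pos
  }
  nuc_by <- split(seq_len(nrow(nuc_hits)), nuc_hits$query_id)
  orf_by <- split(seq_len(nrow(orfs)), orfs$contig_id)
  ph_by <- split(seq_len(nrow(protein_hits)), protein_hits$contig_id)
  nuc_flag <- vapply(seq_along(known), function(i) {
    idx <- nuc_by[[known[i]]]
    if (is.null(idx)) return(FALSE)
    nucleotide_rule(nuc_hits[idx, , drop = FALSE], contigs$length[i],
                    min_identity, min_coverage)
  }, logical(1))
  prot_flag <- vapply(known, function(id) {
    oidx <- orf_by[[id]]
    pidx <- ph_by[[id]]
    protein_rule(orfs[oidx %||% integer(0), , drop = FALSE],
                 protein_hits[pidx %||% integer(0), , drop = FALSE],
                 min_orfs, min_fraction)
  }, logical(1), USE.NAMES = FALSE)
  dec <- data.frame(
    contig_id = known,
    nucleotide_route = nuc_flag,
    protein_route = prot_flag,
    virsorter2_route = tool_pos("virsorter2"),
    deepvirfinder_route = tool_pos("deepvirfinder"),
    circular_route = tool_pos("vrca_circular"),
    rrna_excluded = known %in% rrna_hits$contig_id,
    stringsAsFactors = FALSE
  )
  any_route <- dec$nucleotide_route | dec$protein_route |
    dec$virsorter2_route | dec$deepvirfinder_route | dec$circular_route
  dec$viral <- any_route & !dec$rrna_excluded
  dec$effective_length <- contigs$length
  dec$quant_included <- NA
  dec
}

#' Provirus refinement and length re-filter
#'
#' Contigs flagged as proviral in the quality table are trimmed to the
#' predicted viral region (`effective_length = region_end - region_start +
#' 1`), and contigs whose effective length falls below `min_length` lose
#' their viral flag (the keep rule is inclusive: length >= 3000 bp is
#' retained). Contigs without a quality record are left untrimmed.
#'
#' @param decisions Output of [triage_contigs()].
#' @param quality Quality records as [read_quality_table()].
#' @param min_length Minimum effective length in bp (default 3000).
#' @return The decisions with updated `effective_length` and `viral`.
#' @export
refine_and_filter <- function(decisions, quality, min_length = 3000L) {
  idx <- match(decisions$contig_id, quality$contig_id)
  pro <- !is.na(idx) & quality$provirus[replace(idx, is.na(idx), 1L)]
  qi <- idx[pro]
  if (any(quality$region_end[qi] > decisions$effective_length[pro]))
    stopf("provirus trim region extends beyond contig end for '%s'",
          decisions$contig_id[pro][
            quality$region_end[qi] > decisions$effective_length[pro]][1L])
  if (any(quality$region_start[qi] < 1L))
    stopf("provirus trim region starts before position 1")
  decisions$effective_length[pro] <-
    quality$region_end[qi] - quality$region_start[qi] + 1L
  decisions$viral <- decisions$viral & decisions$effective_length >= min_length
  decisions
}

#' Quantitative-inclusion quality filter
#'
#' A viral contig enters quantitative analysis only if its estimated
#' completeness is at least 50%, it has at least one gene classified viral,
#' and viral genes make up at least 10% of its gene count (all boundaries
#' inclusive). Missing completeness is unknown and fails the threshold; a
#' zero gene count fails with a warning.
#'
#' @param decisions Decisions after [refine_and_filter()].
#' @param quality Quality records as [read_quality_table()].
#' @param min_completeness,min_viral_genes,min_viral_fraction Thresholds.
#' @return The decisions with `quant_included` filled in (FALSE for
#'   non-viral contigs).
#' @export
quant_inclusion <- function(decisions, quality, min_completeness = 50,
                            min_viral_genes = 1L, min_viral_fraction = 0.10) {
  idx <- match(decisions$contig_id, quality$contig_id)
  ok <- logical(nrow(decisions))
  for (i in seq_len(nrow(decisions))) {
    if (!decisions$viral[i] || is.na(idx[i])) next
    q <- quality[idx[i], ]
    if (q$gene_count == 0L) {
      if (q$viral_genes == 0L)
        warnf("contig '%s': gene count is 0, viral gene fraction undefined; excluded",
              decisions$contig_id[i])
      next
    }
    ok[i] <- !is.na(q$completeness) &&
      q$completeness >= min_completeness &&
      q$viral_genes >= min_viral_genes &&
      frac_ge(q$viral_genes, q$gene_count, min_viral_fraction)
  }
  decisions$quant_included <- ok
  decisions
}
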