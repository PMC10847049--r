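#' Find redundant contig pairs from all-vs-all nucleotide hits
#'
#' Two contigs are redundant when they share at least `min_identity`
#' percent identity over at least `min_cover` of the shorter contig's
#' length. Coverage is the merged-interval fraction of the shorter contig
#' covered by hits whose percent identity individually passes
#' `min_identity` (each HSP qualifies on its own; identities are not
#' length-averaged). Only hits whose query is the shorter member carry
#' usable query intervals, so those are the hits counted. Self-hits are
#' ignored. For equal-length pairs the lexicographically smaller id is the
#' keeper.
#'
#' @param contigs Data frame with columns `id` and `length` (bp).
#' @param hits Nucleotide hits as returned by [read_nuc_hits()], already
#'   filtered to the dereplication e-value cut-off.
#' @param min_identity Minimum percent identity per hit (default 90).
#' @param min_cover Minimum merged coverage of the shorter contig
#'   (default 0.9).
#' @return Data frame of redundancy pairs: `keep_id`, `drop_id`,
#'   `shorter_len`, `covered_fraction`.
#' @export
find_redundancy_pairs <- function(contigs, hits, min_identity = 90,
                                  min_cover = 0.9) {
  if (anyDuplicated(contigs$id))
    stopf("duplicate contig id '%s'", contigs$id[duplicated(contigs$id)][1L])
  len <- stats::setNames(contigs$length, contigs$id)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(len))
  if (length(unknown) > 0L)
    stopf("hit references unknown contig '%s'", unknown[1L])
  h <- hits[hits$query_id != hits$subject_id &
              hits$pct_identity >= min_identity, , drop = FALSE]
  empty <- data.frame(keep_id = character(), drop_id = character(),
                      shorter_len = integer(), covered_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(empty)
  if (any(h$q_end > len[h$query_id]))
    stopf("hit interval exceeds query contig length for '%s'",
          h$query_id[h$q_end > len[h$query_id]][1L])
  # designate the drop candidate of each unordered pair: shorter length,
  # ties broken towards the lexicographically larger id
  qlen <- len[h$query_id]; slen <- len[h$subject_id]
  q_is_shorter <- qlen < slen | (qlen == slen & h$query_id > h$subject_id)
  h <- h[q_is_shorter, , drop = FALSE]   # query intervals live on the shorter contig
  if (nrow(h) == 0L) return(empty)
  key <- paste(h$query_id, h$subject_id, sep = "\t")
  out <- lapply(split(seq_len(nrow(h)), key), function(idx) {
    drop_id <- h$query_id[idx[1L]]
    keep_id <- h$subject_id[idx[1L]]
    shorter_len <- unname(len[drop_id])
    covered <- interval_union_length(h$q_start[idx], h$q_end[idx])
    data.frame(keep_id = keep_id, drop_id = drop_id,
               shorter_len = shorter_len,
               covered_fraction = covered / shorter_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[frac_ge(out$covered_fraction * out$shorter_len, out$shorter_len,
                     min_cover), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$keep_id, out$drop_id), , drop = FALSE]
}

#' Remove redundant contigs (shortest of each pair)
#'
#' Deterministic greedy pass over contigs in descending length (ties by
#' ascending id): a contig is removed iff it is the drop member of a
#' redundancy pair whose keep member is still retained. The retained set is
#' a fixed point: re-detecting pairs among retained contigs finds none.
#'
#' @param contigs Data frame with columns `id` and `length`.
#' @param pairs Output of [find_redundancy_pairs()].
#' @return A list with `retained` (character vector of ids, input order)
#'   and `removed` (data frame `drop_id`, `keep_id`).
#' @export
deduplicate <- function(contigs, pairs) {
  ord <- order(-contigs$length, contigs$id)
  ids <- contigs$id[ord]
  retained <- logical(length(ids))
  names(retained) <- ids
  removed <- character(0)
  removed_by <- character(0)
  for (id in ids) {
    partners <- pairs$keep_id[pairs$drop_id == id]
    hit <- partners[retained[partners]]
    if (length(hit) > 0L) {
      removed <- c(removed, id)
      removed_by <- c(removed_by, hit[1L])
    } else {
      retained[id] <- TRUE
    }
  }
  list(
    retained = contigs$id[contigs$id %in% names(retained)[retained]],
    removed = data.frame(drop_id = removed, keep_id = removed_by,
                         stringsAsFactors = FALSE)
  )
}
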