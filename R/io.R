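#' Read a tabular nucleotide hit file (BLAST outfmt-6)
#'
#' Reads the standard 12-column tab-separated BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, no header) and applies an e-value cut-off. Hits with
#' `qstart > qend` (minus-strand convention of some producers) are
#' normalised by swapping, since downstream triage only uses query-interval
#' coverage.
#'
#' @param path Path to the tab-separated hit file.
#' @param evalue_max Maximum e-value retained; rows above it are dropped
#'   and the number of kept/dropped rows is reported. The viral nucleotide
#'   comparison uses 1e-10; the all-vs-all dereplication comparison uses
#'   1e-20.
#' @return A data frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `q_start`, `q_end`, `e_value`, `bitscore`.
#' @export
read_nuc_hits <- function(path, evalue_max = Inf) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    msgf("read_nuc_hits: 0 hits kept, 0 dropped (%s)", path)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), q_start = integer(),
                      q_end = integer(), e_value = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stopf("malformed hit row at line %d: expected 12 tab-separated columns, got %d",
          line_no[which(nf != 12L)[1L]], nf[nf != 12L][1L])
  m <- do.call(rbind, fields)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stopf("malformed hit row at line %d: non-numeric %s '%s'",
            line_no[which(is.na(v))[1L]], name, m[which(is.na(v))[1L], col])
    v
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "percent identity"),
    q_start = as.integer(num(7L, "query start")),
    q_end = as.integer(num(8L, "query end")),
    e_value = num(11L, "e-value"),
    bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stopf("malformed hit row at line %d: percent identity outside [0,100]",
          line_no[which(hits$pct_identity < 0 | hits$pct_identity > 100)[1L]])
  # normalise minus-strand query intervals
  rev_idx <- hits$q_start > hits$q_end
  if (any(rev_idx)) {
    tmp <- hits$q_start[rev_idx]
    hits$q_start[rev_idx] <- hits$q_end[rev_idx]
    hits$q_end[rev_idx] <- tmp
  }
  kept <- hits$e_value <= evalue_max
  msgf("read_nuc_hits: %d hits kept, %d dropped at e-value <= %g (%s)",
       sum(kept), sum(!kept), evalue_max, path)
  hits[kept, , drop = FALSE]
}

#' Read ORF calls from a GFF3 file
#'
#' Extracts CDS features (1-based inclusive coordinates per the GFF3
#' standard); the ORF identifier is taken from the `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `contig_id`, `orf_id`, `start`, `end`,
#'   `strand`.
#' @export
read_orfs <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stopf("GFF3 parse error in %s: %s", path, conditionMessage(e))
  )
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L)
    return(data.frame(contig_id = character(), orf_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    stopf("GFF3 parse error in %s: CDS feature without an ID attribute", path)
  orfs <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    orf_id = as.character(ids),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(orfs$start > orfs$end))
    stopf("GFF3 parse error in %s: CDS with start > end", path)
  dup <- duplicated(orfs[, c("contig_id", "orf_id")])
  if (any(dup))
    stopf("GFF3 parse error in %s: duplicated ORF id '%s' on contig '%s'",
          path, orfs$orf_id[dup][1L], orfs$contig_id[dup][1L])
  orfs
}

#' Read a contig quality summary table
#'
#' Reads a CheckV-style quality summary (tab-separated, header row) with
#' columns `contig_id`, `completeness`, `gene_count`, `viral_genes`,
#' `provirus` and, for proviruses, `region_start`/`region_end` trim
#' coordinates. A missing completeness (`NA`) is kept as unknown, never
#' coerced to zero; unknown completeness later fails any threshold test.
#'
#' @param path Path to the TSV file.
#' @return A data frame of quality records.
#' @export
read_quality_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  q <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(q, c("contig_id", "completeness", "gene_count", "viral_genes",
                   "provirus"), "quality table")
  if (!"region_start" %in% names(q)) q$region_start <- NA_integer_
  if (!"region_end" %in% names(q)) q$region_end <- NA_integer_
  q$completeness <- suppressWarnings(as.numeric(q$completeness))
  q$provirus <- parse_flag(q$provirus)
  bad <- which(q$viral_genes > q$gene_count)
  if (length(bad) > 0L)
    stopf("quality table: viral_genes (%d) exceeds gene_count (%d) for contig '%s'",
          q$viral_genes[bad[1L]], q$gene_count[bad[1L]], q$contig_id[bad[1L]])
  if (any(q$provirus & (is.na(q$region_start) | is.na(q$region_end))))
    stopf("quality table: provirus record without trim coordinates")
  if (any(q$provirus & q$region_start > q$region_end, na.rm = TRUE))
    stopf("quality table: provirus region_start > region_end")
  q[, c("contig_id", "completeness", "gene_count", "viral_genes",
        "provirus", "region_start", "region_end")]
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- lx %in% c("yes", "true", "1")
  bad <- !lx %in% c("yes", "true", "1", "no", "false", "0")
  if (any(bad)) stopf("cannot parse boolean flag value '%s'", x[bad][1L])
  out
}

#' Read a count matrix and its sample design table
#'
#' The count matrix is tab-separated with a header row of sample ids and a
#' first column of feature ids. The design table carries `sample_id`,
#' `group`, `subject_id`, `timepoint` and `total_mapped_reads`. Matrix
#' columns are reordered to follow the design; design rows without a
#' matching matrix column are reported.
#'
#' @param counts_path,design_path Paths to the two TSV files.
#' @return A list with `counts` (an [abundance_matrix()] on the count
#'   scale) and `design` (a data frame restricted to the matrix samples,
#'   in matrix column order).
#' @export
read_counts_and_design <- function(counts_path, design_path) {
  mat <- utils::read.delim(counts_path, row.names = 1L, check.names = FALSE)
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stopf("count matrix contains non-numeric values")
  if (any(mat < 0)) stopf("count matrix contains negative values")
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE,
                              colClasses = c(sample_id = "character"))
  assert_cols(design, c("sample_id", "group"), "design table")
  if (anyDuplicated(design$sample_id))
    stopf("design table: duplicated sample_id '%s'",
          design$sample_id[duplicated(design$sample_id)][1L])
  missing_samples <- setdiff(colnames(mat), design$sample_id)
  if (length(missing_samples) > 0L)
    stopf("sample(s) in count matrix absent from design: %s",
          paste(missing_samples, collapse = ", "))
  extra <- setdiff(design$sample_id, colnames(mat))
  if (length(extra) > 0L)
    msgf("read_counts_and_design: %d design sample(s) without matrix columns: %s",
         length(extra), paste(extra, collapse = ", "))
  design <- design[design$sample_id %in% colnames(mat), , drop = FALSE]
  mat <- mat[, design$sample_id, drop = FALSE]
  list(counts = abundance_matrix(mat, scale = "count"), design = design)
}

#' Read per-contig per-sample mapping records
#'
#' @param path TSV with columns `contig_id`, `sample_id`, `mapped_reads`,
#'   `breadth` (fraction of contig positions with depth >= 1).
#' @return A data frame of mapping records.
#' @export
read_mapping <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  assert_cols(m, c("contig_id", "sample_id", "mapped_reads", "breadth"),
              "mapping table")
  if (any(m$breadth < 0 | m$breadth > 1))
    stopf("mapping table: breadth outside [0,1]")
  if (any(m$mapped_reads < 0))
    stopf("mapping table: negative mapped_reads")
  if (any(m$mapped_reads == 0 & m$breadth > 0))
    stopf("mapping table: zero mapped_reads with nonzero breadth")
  m
}

#' Derive breadth of coverage from a per-base depth table
#'
#' Optional alternative to supplying breadth directly: given a long table of
#' per-position depths, breadth is the fraction of contig positions with
#' depth >= 1. Positions absent from the table are taken as depth 0.
#'
#' @param path TSV with columns `contig_id`, `sample_id`, `pos`, `depth`.
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @return A data frame with `contig_id`, `sample_id`, `breadth`.
#' @export
breadth_from_depth <- function(path, contig_lengths) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  assert_cols(d, c("contig_id", "sample_id", "pos", "depth"), "depth table")
  unknown <- setdiff(unique(d$contig_id), names(contig_lengths))
  if (length(unknown) > 0L)
    stopf("depth table references unknown contig '%s'", unknown[1L])
  if (any(d$pos < 1L | d$pos > contig_lengths[d$contig_id]))
    stopf("depth table: position outside contig bounds")
  d <- d[d$depth >= 1L, , drop = FALSE]
  key <- paste(d$contig_id, d$sample_id, sep = "\t")
  cov <- tapply(d$pos, key, function(p) length(unique(p)))
  parts <- strsplit(names(cov), "\t", fixed = TRUE)
  out <- data.frame(
    contig_id = vapply(parts, `[`, "", 1L),
    sample_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  out$breadth <- as.numeric(cov) / contig_lengths[out$contig_id]
  rownames(out) <- NULL
  out
}

#' Read contigs from a FASTA file
#'
#' @param path FASTA file of assembled contigs. Contigs whose header
#'   contains the token `circular` are flagged circular.
#' @param keep_sequence Keep the nucleotide sequence in the returned table.
#' @return A data frame with `id`, `length`, `circular` and optionally
#'   `sequence`.
#' @export
read_contigs <- function(path, keep_sequence = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("duplicate contig id '%s' in %s", ids[duplicated(ids)][1L], path)
  out <- data.frame(
    id = ids,
    length = Biostrings::width(ss),
    circular = grepl("\\bcircular\\b", headers),
    stringsAsFactors = FALSE
  )
  if (keep_sequence) out$sequence <- as.character(ss)
  out
}

#' Read stand-alone classifier calls
#'
#' @param path TSV with columns `contig_id`, `tool` (one of `virsorter2`,
#'   `deepvirfinder`, `vrca_circular`), `positive`, and optionally `score`.
#' @return A data frame of tool calls.
#' @export
read_tool_calls <- function(path) {
  tc <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(tc, c("contig_id", "tool", "positive"), "tool-call table")
  bad <- setdiff(unique(tc$tool), c("virsorter2", "deepvirfinder", "vrca_circular"))
  if (length(bad) > 0L) stopf("unknown tool '%s' in tool-call table", bad[1L])
  tc$positive <- parse_flag(tc$positive)
  if (anyDuplicated(tc[, c("contig_id", "tool")]))
    stopf("tool-call table: more than one record for a (contig, tool) pair")
  tc
}

#' Read rRNA screen hits
#'
#' @param path TSV with columns `contig_id` and `rrna_type`.
#' @return A data frame of rRNA hits.
#' @export
read_rrna_hits <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(r, c("contig_id", "rrna_type"), "rRNA table")
  if (any(!nzchar(r$contig_id))) stopf("rRNA table: empty contig_id")
  r
}

#' Read protein hit records
#'
#' Each row records that an ORF was hit in one protein database at an
#' e-value passing that database's cut-off (1e-10 for `refseq_viral`
#' BLASTp, 1e-5 for the `phrogs`/`ipf` HMM searches).
#'
#' @param path TSV with columns `orf_id`, `database`, `e_value`.
#' @return A data frame of protein hits.
#' @export
read_protein_hits <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(ph, c("orf_id", "database", "e_value"), "protein-hit table")
  cutoffs <- c(refseq_viral = 1e-10, phrogs = 1e-5, ipf = 1e-5)
  bad <- setdiff(unique(ph$database), names(cutoffs))
  if (length(bad) > 0L) stopf("unknown protein database '%s'", bad[1L])
  over <- ph$e_value > cutoffs[ph$database]
  if (any(over))
    stopf("protein hit on '%s' exceeds the %s e-value cut-off",
          ph$orf_id[over][1L], ph$database[over][1L])
  ph
}

#' Read phage host predictions
#'
#' @param path TSV with columns `contig_id`, `host_phylum`, `host_order`,
#'   `host_family` (any may be empty/NA) and optionally `confidence`.
#' @return A data frame of host predictions.
#' @export
read_host_predictions <- function(path) {
  hp <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  assert_cols(hp, c("contig_id", "host_phylum", "host_order", "host_family"),
              "host-prediction table")
  none <- is.na(hp$host_phylum) & is.na(hp$host_order) & is.na(hp$host_family)
  if (any(none))
    stopf("host prediction for '%s' has no taxon at any rank",
          hp$contig_id[none][1L])
  hp
}

#' Write a result table to TSV
#'
#' Writes any homogeneous record collection (data frame) as a tab-separated
#' UTF-8 file with a header row, '.' decimal, and floats at full (15
#' significant digit) precision so that a round-trip read returns equal
#' records.
#'
#' @param records A data frame.
#' @param path Output path; its directory must exist.
#' @return Invisibly, the path.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) stopf("records must be a data frame")
  if (!dir.exists(dirname(path)))
    stopf("cannot write '%s': directory does not exist", path)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with column types inferred.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
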