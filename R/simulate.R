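#' Simulate a viral-evidence bundle with planted triage truth
#'
#' Generates contigs and every evidence table the triage stage consumes --
#' nucleotide hits, ORF calls, protein hits, stand-alone classifier calls,
#' rRNA hits and quality records -- such that each planted-viral contig
#' satisfies exactly its planted evidence route, negatives sit strictly
#' below every threshold, and a configurable fraction of positives sit
#' exactly at a threshold boundary (coverage 0.85, 2 of 4 ORFs,
#' completeness 50.0, viral-gene fraction 10%, effective length 3000 bp).
#' A further two small sets of contigs carry route evidence but are
#' planted to be vetoed: rRNA carriers, and proviruses whose trimmed
#' region falls below the length filter. All draws are deterministic given
#' the seed.
#'
#' @param n_contigs Total number of contigs.
#' @param viral_fraction Fraction planted viral (surviving all vetoes).
#' @param boundary_fraction Fraction of the viral contigs planted exactly
#'   at their route/quality threshold.
#' @param rrna_fraction Fraction planted with route evidence plus an rRNA
#'   hit (vetoed).
#' @param trim_short_fraction Fraction planted as proviruses trimmed below
#'   3 kbp (vetoed).
#' @param seed Integer seed.
#' @param sequences Also generate random nucleotide sequences (needed to
#'   write a FASTA fixture).
#' @return List with `contigs`, `nuc_hits`, `orfs`, `protein_hits`,
#'   `tool_calls`, `rrna_hits`, `quality`, `truth` and `params`.
#' @export
simulate_evidence_bundle <- function(n_contigs = 200, viral_fraction = 0.3,
                                     boundary_fraction = 0.1,
                                     rrna_fraction = 0.05,
                                     trim_short_fraction = 0.05,
                                     seed = 1, sequences = FALSE) {
  stopifnot(viral_fraction >= 0, viral_fraction <= 1,
            boundary_fraction >= 0, boundary_fraction <= 1)
  set.seed(seed)
  n_viral <- round(n_contigs * viral_fraction)
  n_rrna <- round(n_contigs * rrna_fraction)
  n_trim <- round(n_contigs * trim_short_fraction)
  if (n_viral + n_rrna + n_trim > n_contigs)
    stopf("fractions sum to more than 1")
  ids <- sprintf("c%04d", seq_len(n_contigs))
  # lengths in multiples of 100 bp so that 85% of a length is integral
  lengths <- sample(40:100, n_contigs, replace = TRUE) * 100L
  routes <- c("nucleotide", "protein", "virsorter2", "deepvirfinder",
              "circular")
  kind <- rep("negative", n_contigs)
  kind[seq_len(n_viral)] <- "viral"
  if (n_rrna > 0) kind[n_viral + seq_len(n_rrna)] <- "rrna_veto"
  if (n_trim > 0) kind[n_viral + n_rrna + seq_len(n_trim)] <- "trim_short"
  kind <- sample(kind)                       # shuffle positions
  planted_route <- rep("none", n_contigs)
  with_route <- kind != "negative"
  planted_route[with_route] <- sample(routes, sum(with_route), replace = TRUE)
  boundary <- rep(FALSE, n_contigs)
  vidx <- which(kind == "viral")
  boundary[sample(vidx, round(length(vidx) * boundary_fraction))] <- TRUE

  nuc <- list(); orfs <- list(); phits <- list(); tools <- list()
  rrna <- list(); quality <- list()
  circ <- rep(FALSE, n_contigs)
  quant_truth <- rep(FALSE, n_contigs)
  is_viral <- kind == "viral"

  for (i in seq_len(n_contigs)) {
    id <- ids[i]; L <- lengths[i]; route <- planted_route[i]
    bnd <- boundary[i]

    # --- ORF calls (every contig) and protein hits
    n_orf <- if (route == "protein" && bnd) 4L else sample(4:12, 1L)
    orf_len <- (L %/% n_orf)
    starts <- (seq_len(n_orf) - 1L) * orf_len + 1L
    ends <- pmin(starts + orf_len - 10L, L)
    orf_ids <- sprintf("%s_orf%d", id, seq_len(n_orf))
    orfs[[i]] <- data.frame(contig_id = id, orf_id = orf_ids,
                            start = starts, end = ends,
                            strand = sample(c("+", "-"), n_orf, TRUE),
                            stringsAsFactors = FALSE)
    n_hit <- if (route == "protein") {
      if (bnd) 2L else max(2L, ceiling(n_orf / 2))
    } else sample(0:1, 1L)                   # below both protein thresholds
    if (n_hit > 0L) {
      hit_orfs <- sample(orf_ids, n_hit)
      dbs <- sample(c("refseq_viral", "phrogs", "ipf"), n_hit, TRUE)
      phits[[i]] <- data.frame(
        orf_id = hit_orfs, database = dbs,
        e_value = ifelse(dbs == "refseq_viral",
                         10^stats::runif(n_hit, -40, -11),
                         10^stats::runif(n_hit, -40, -6)),
        stringsAsFactors = FALSE)
    }

    # --- nucleotide hits
    if (route == "nucleotide") {
      target <- if (bnd) as.integer(round(0.85 * L)) else
        as.integer(ceiling(stats::runif(1, 0.86, 0.99) * L))
      # two abutting intervals whose union is exactly `target` bp
      cut <- sample(seq_len(target - 1L), 1L)
      iv <- rbind(c(1L, cut), c(cut + 1L, target))
      nuc[[i]] <- data.frame(
        query_id = id, subject_id = sprintf("db|%s", id),
        pct_identity = round(stats::runif(2, 50, 100), 1),
        q_start = iv[, 1L], q_end = iv[, 2L],
        e_value = 10^stats::runif(2, -60, -11),
        bitscore = round(stats::runif(2, 200, 2000), 1),
        stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.4) {
      # sub-threshold distractor hits: low coverage or low identity
      low_id <- stats::runif(1) < 0.5
      span <- as.integer(stats::runif(1, 0.1, if (low_id) 0.95 else 0.45) * L)
      nuc[[i]] <- data.frame(
        query_id = id, subject_id = sprintf("db|%s", id),
        pct_identity = if (low_id) round(stats::runif(1, 30, 49.9), 1)
                       else round(stats::runif(1, 50, 100), 1),
        q_start = 1L, q_end = max(span, 1L),
        e_value = 10^stats::runif(1, -60, -11),
        bitscore = round(stats::runif(1, 200, 2000), 1),
        stringsAsFactors = FALSE)
    }

    # --- stand-alone classifier calls (one record per contig and tool)
    circ[i] <- route == "circular"
    tools[[i]] <- data.frame(
      contig_id = id,
      tool = c("virsorter2", "deepvirfinder", "vrca_circular"),
      positive = c(route == "virsorter2", route == "deepvirfinder",
                   route == "circular"),
      score = round(stats::runif(3), 3),
      stringsAsFactors = FALSE)

    # --- rRNA veto
    if (kind[i] == "rrna_veto")
      rrna[[i]] <- data.frame(contig_id = id, rrna_type = "16S_rRNA",
                              stringsAsFactors = FALSE)

    # --- quality record
    provirus <- FALSE; rs <- NA_integer_; re <- NA_integer_
    if (kind[i] == "trim_short") {
      provirus <- TRUE
      eff <- 2999L                            # just below the length filter
      rs <- sample.int(L - eff + 1L, 1L); re <- rs + eff - 1L
    } else if (kind[i] == "viral" && !bnd && stats::runif(1) < 0.15 &&
               L >= 4000L) {
      provirus <- TRUE
      eff <- sample(3000:(L - 500L), 1L)
      rs <- sample.int(L - eff + 1L, 1L); re <- rs + eff - 1L
    } else if (kind[i] == "viral" && bnd && L >= 4000L &&
               stats::runif(1) < 0.5) {
      provirus <- TRUE                        # trimmed to exactly 3000 bp
      eff <- 3000L
      rs <- sample.int(L - eff + 1L, 1L); re <- rs + eff - 1L
    }
    if (kind[i] == "viral") {
      quant_pass <- bnd || stats::runif(1) < 0.7
      if (quant_pass) {
        if (bnd) {
          completeness <- 50.0                # boundary: all three inclusive
          gene_count <- 10L; viral_genes <- 1L
        } else {
          completeness <- round(stats::runif(1, 50, 100), 1)
          gene_count <- n_orf
          viral_genes <- max(1L, ceiling(gene_count * stats::runif(1, 0.10, 0.9)))
        }
        quant_truth[i] <- TRUE
      } else {
        fail_mode <- sample(3L, 1L)
        completeness <- if (fail_mode == 1L)
          round(stats::runif(1, 0, 49.9), 1) else round(stats::runif(1, 50, 100), 1)
        if (fail_mode == 3L) completeness <- NA_real_
        gene_count <- max(n_orf, 11L)
        viral_genes <- if (fail_mode == 1L) max(2L, gene_count %/% 5L)
                       else max(0L, (gene_count - 1L) %/% 10L)  # < 10% of genes
        if (fail_mode == 2L && viral_genes == 0L) viral_genes <- 0L
      }
    } else {
      completeness <- round(stats::runif(1, 0, 40), 1)
      gene_count <- n_orf
      viral_genes <- 0L
    }
    quality[[i]] <- data.frame(contig_id = id, completeness = completeness,
                               gene_count = gene_count,
                               viral_genes = viral_genes,
                               provirus = provirus, region_start = rs,
                               region_end = re, stringsAsFactors = FALSE)
  }

  contigs <- data.frame(id = ids, length = lengths, circular = circ,
                        stringsAsFactors = FALSE)
  if (sequences)
    contigs$sequence <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  truth <- data.frame(
    contig_id = ids,
    is_viral = is_viral,
    planted_route = ifelse(is_viral, planted_route, "none"),
    boundary_case = boundary,
    rrna_planted = kind == "rrna_veto",
    trimmed_short = kind == "trim_short",
    quant_included = quant_truth,
    stringsAsFactors = FALSE)
  bind <- function(x) if (length(x) == 0L || all(vapply(x, is.null, TRUE)))
    NULL else do.call(rbind, x[!vapply(x, is.null, TRUE)])
  list(
    contigs = contigs,
    nuc_hits = bind(nuc) %||% data.frame(
      query_id = character(), subject_id = character(),
      pct_identity = numeric(), q_start = integer(), q_end = integer(),
      e_value = numeric(), bitscore = numeric()),
    orfs = bind(orfs),
    protein_hits = bind(phits) %||% data.frame(
      orf_id = character(), database = character(), e_value = numeric()),
    tool_calls = bind(tools),
    rrna_hits = bind(rrna) %||% data.frame(contig_id = character(),
                                           rrna_type = character()),
    quality = bind(quality),
    truth = truth,
    params = list(n_contigs = n_contigs, viral_fraction = viral_fraction,
                  boundary_fraction = boundary_fraction,
                  rrna_fraction = rrna_fraction,
                  trim_short_fraction = trim_short_fraction, seed = seed)
  )
}

#' Simulate a Gaussian CLR-scale study with planted restoration effects
#'
#' Direct CLR-scale generator for statistical calibration: feature values
#' are Gaussian with unit (configurable) residual SD, per-subject random
#' intercepts, and planted group shifts. Stress shifts Ctr Stress samples
#' on restored and stress-only features; FVT Stress samples are shifted
#' back to baseline on restored features only. With more than one
#' timepoint the shifts apply from the second timepoint onward (the first
#' is an unshifted baseline).
#'
#' @param n_features Number of features.
#' @param n_per_group Named vector of subjects per group
#'   (default `c(Ctr = 10, CtrStress = 10, FVTStress = 9)`, the study's
#'   group sizes).
#' @param n_restored,n_stress_only Planted feature class counts.
#' @param effect_size Stress shift in CLR units (default 1.5); sign drawn
#'   per feature.
#' @param sd Residual (within-subject) SD (default 1).
#' @param subject_sd SD of the per-subject random intercept (default 0).
#' @param timepoints Number of repeated timepoints (default 1).
#' @param seed Integer seed.
#' @return List with `x` (features x samples CLR-scale matrix), `design`
#'   and `truth`.
#' @export
simulate_clr_study <- function(n_features = 300,
                               n_per_group = c(Ctr = 10, CtrStress = 10,
                                               FVTStress = 9),
                               n_restored = 30, n_stress_only = 0,
                               effect_size = 1.5, sd = 1, subject_sd = 0,
                               timepoints = 1, seed = 1) {
  if (n_restored + n_stress_only > n_features)
    stopf("more planted features than features")
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  subjects <- sprintf("m%02d", seq_along(groups))
  design <- expand.grid(subject_idx = seq_along(subjects),
                        timepoint = seq_len(timepoints))
  design <- data.frame(
    sample_id = sprintf("%s_t%d", subjects[design$subject_idx],
                        design$timepoint),
    group = groups[design$subject_idx],
    subject_id = subjects[design$subject_idx],
    timepoint = design$timepoint,
    stringsAsFactors = FALSE)
  cls <- rep("null", n_features)
  cls[seq_len(n_restored)] <- "restored"
  if (n_stress_only > 0)
    cls[n_restored + seq_len(n_stress_only)] <- "stress_only"
  cls <- sample(cls)
  fid <- sprintf("f%04d", seq_len(n_features))
  stress_effect <- ifelse(cls == "null", 0,
                          effect_size * sample(c(-1, 1), n_features, TRUE))
  fvt_effect <- ifelse(cls == "restored", -stress_effect, 0)
  shifted_tp <- if (timepoints == 1) design$timepoint >= 1
                else design$timepoint >= 2
  base <- stats::rnorm(n_features, 0, 1)
  n_s <- nrow(design)
  x <- matrix(stats::rnorm(n_features * n_s, 0, sd), n_features, n_s,
              dimnames = list(fid, design$sample_id))
  x <- x + base
  if (subject_sd > 0) {
    b <- matrix(stats::rnorm(n_features * length(subjects), 0, subject_sd),
                n_features, length(subjects),
                dimnames = list(fid, subjects))
    x <- x + b[, design$subject_id]
  }
  shift <- outer(stress_effect,
                 as.numeric(design$group == "CtrStress" & shifted_tp))
  # stress-only features keep the shift under FVT; restored features revert
  shift <- shift + outer(stress_effect + fvt_effect,
                         as.numeric(design$group == "FVTStress" & shifted_tp))
  x <- x + shift
  truth <- data.frame(feature_id = fid, class = cls,
                      stress_effect = stress_effect,
                      fvt_effect = fvt_effect, stringsAsFactors = FALSE)
  list(x = x, design = design, truth = truth)
}

#' Simulate a count-scale virome study with spike-in and mapping records
#'
#' Logistic-normal multinomial generator: planted CLR-scale abundances
#' (as in [simulate_clr_study()]) are exponentiated into absolute
#' abundances in spike units, one designated spike feature is held at a
#' constant known amount, and per-sample read counts are drawn
#' multinomially with probabilities proportional to absolute abundance
#' times contig length. Breadth values are drawn from a high-breadth
#' component, with a configurable fraction of spurious low-breadth
#' (< 0.75) records to exercise the breadth filter.
#'
#' @inheritParams simulate_clr_study
#' @param subject_sd SD of per-subject intercepts (default 1, the study
#'   condition for the longitudinal analyses).
#' @param residual_sd Within-subject residual SD in CLR units
#'   (default 0.5).
#' @param library_size Reads per sample (default 1e5).
#' @param spike_amount Absolute spike amount per sample in spike units
#'   (default 1e6).
#' @param spike_share Approximate expected read share of the spike used to
#'   scale feature abundances (default 1/30).
#' @param low_breadth_fraction Fraction of nonzero mapping records drawn
#'   spuriously with breadth below 0.75 (default 0.05).
#' @return List with `counts` (matrix), `mapping` (records with breadth),
#'   `design`, `features` (ids and lengths), `truth`, `absolute` (planted
#'   absolute abundances) and `expected_reads`.
#' @export
simulate_count_study <- function(n_features = 300,
                                 n_per_group = c(Ctr = 10, CtrStress = 10,
                                                 FVTStress = 9),
                                 n_restored = 30, n_stress_only = 20,
                                 effect_size = 1.5, subject_sd = 1,
                                 residual_sd = 0.5, library_size = 1e5,
                                 timepoints = 1, spike_amount = 1e6,
                                 spike_share = 1 / 30,
                                 low_breadth_fraction = 0.05, seed = 1) {
  clr <- simulate_clr_study(n_features = n_features - 1L,
                            n_per_group = n_per_group,
                            n_restored = n_restored,
                            n_stress_only = n_stress_only,
                            effect_size = effect_size, sd = residual_sd,
                            subject_sd = subject_sd,
                            timepoints = timepoints, seed = seed)
  design <- clr$design
  n_samp <- nrow(design)
  if (library_size < 10 * n_features)
    warnf("library_size is small for %d features; expect many zeros",
          n_features)
  abs_feat <- exp(clr$x)
  # scale features so the spike takes roughly spike_share of the reads
  c0 <- spike_amount * (1 / spike_share - 1) / mean(colSums(abs_feat))
  abs_feat <- abs_feat * c0
  spike_id <- "Q33"
  absolute <- rbind(abs_feat,
                    matrix(spike_amount, 1L, n_samp,
                           dimnames = list(spike_id, design$sample_id)))
  feat_len <- c(sample(30:100, n_features - 1L, replace = TRUE) * 100L,
                31100L)                       # lactococcal phage scale
  names(feat_len) <- rownames(absolute)
  prob <- absolute * feat_len
  expected <- sweep(prob, 2L, colSums(prob), "/") * library_size
  counts <- apply(sweep(prob, 2L, colSums(prob), "/"), 2L, function(p)
    stats::rmultinom(1L, library_size, p))
  dimnames(counts) <- dimnames(absolute)
  mapping <- data.frame(
    contig_id = rep(rownames(counts), times = n_samp),
    sample_id = rep(colnames(counts), each = nrow(counts)),
    mapped_reads = as.vector(counts),
    stringsAsFactors = FALSE)
  nz <- mapping$mapped_reads > 0
  breadth <- numeric(nrow(mapping))
  spurious <- nz & mapping$contig_id != spike_id &
    stats::runif(nrow(mapping)) < low_breadth_fraction
  breadth[nz & !spurious] <- stats::runif(sum(nz & !spurious), 0.80, 1)
  breadth[spurious] <- stats::runif(sum(spurious), 0.20, 0.74)
  mapping$breadth <- breadth
  design$total_mapped_reads <- library_size
  truth <- rbind(clr$truth,
                 data.frame(feature_id = spike_id, class = "spike",
                            stress_effect = 0, fvt_effect = 0,
                            stringsAsFactors = FALSE))
  list(counts = counts, mapping = mapping, design = design,
       features = data.frame(feature_id = names(feat_len),
                             length = unname(feat_len),
                             stringsAsFactors = FALSE),
       truth = truth, absolute = absolute, expected_reads = expected,
       spike_id = spike_id,
       params = list(library_size = library_size,
                     spike_amount = spike_amount, seed = seed))
}

#' Write a simulated bundle to fixture files
#'
#' Writes an evidence bundle (FASTA, outfmt-6 TSV, GFF3, evidence and
#' quality TSVs, truth TSV) or a count-study bundle (counts, design,
#' mapping, feature and truth TSVs) in the formats the readers consume,
#' plus a JSON manifest recording the generator parameters and seed.
#'
#' @param bundle Output of [simulate_evidence_bundle()] (with
#'   `sequences = TRUE`) or [simulate_count_study()].
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the directory.
#' @export
write_fixture_bundle <- function(bundle, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0L && !force)
    stopf("directory '%s' is not empty (use force = TRUE to overwrite)", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write_results(df, file.path(dir, name))
  if (!is.null(bundle$contigs)) {            # evidence bundle
    if (is.null(bundle$contigs$sequence))
      stopf("bundle has no sequences; rerun the generator with sequences = TRUE")
    headers <- ifelse(bundle$contigs$circular,
                      paste(bundle$contigs$id, "circular"),
                      bundle$contigs$id)
    ss <- Biostrings::DNAStringSet(bundle$contigs$sequence)
    names(ss) <- headers
    Biostrings::writeXStringSet(ss, file.path(dir, "contigs.fasta"))
    h <- bundle$nuc_hits
    out6 <- data.frame(h$query_id, h$subject_id, h$pct_identity,
                       h$q_end - h$q_start + 1L, 0L, 0L, h$q_start, h$q_end,
                       1L, h$q_end - h$q_start + 1L,
                       formatC(h$e_value, digits = 3, format = "e"),
                       h$bitscore)
    utils::write.table(out6, file.path(dir, "nuc_hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    o <- bundle$orfs
    gff <- c("##gff-version 3",
             sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     o$contig_id, o$start, o$end, o$strand, o$orf_id))
    writeLines(gff, file.path(dir, "orfs.gff3"))
    tsv(bundle$protein_hits, "protein_hits.tsv")
    tsv(bundle$tool_calls, "tool_calls.tsv")
    tsv(bundle$rrna_hits, "rrna_hits.tsv")
    tsv(bundle$quality, "quality.tsv")
    tsv(bundle$truth, "truth_triage.tsv")
  } else {                                   # count-study bundle
    cnt <- data.frame(feature_id = rownames(bundle$counts), bundle$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    tsv(cnt, "counts.tsv")
    tsv(bundle$design, "design.tsv")
    tsv(bundle$mapping, "mapping.tsv")
    tsv(bundle$features, "features.tsv")
    tsv(bundle$truth, "truth_features.tsv")
  }
  jsonlite::write_json(bundle$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
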