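mkhits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(q_start = r[[1]], q_end = r[[2]], pct_identity = r[[3]])))
}

test_that("merged coverage unions qualifying intervals", {
  h <- mkhits(list(1, 500, 60), list(401, 900, 55))
  expect_equal(merged_coverage_fraction(h, 1000, 50), 0.9)
  expect_equal(merged_coverage_fraction(h[0, ], 1000, 50), 0)
  # sub-threshold identity contributes nothing
  expect_equal(merged_coverage_fraction(mkhits(list(1, 1000, 49.9)), 1000, 50), 0)
  expect_error(merged_coverage_fraction(mkhits(list(1, 1001, 90)), 1000, 50),
               "outside")
})

test_that("merged coverage equals the per-base oracle on random instances", {
  set.seed(77)
  for (i in 1:300) {
    len <- sample(100:10000, 1)
    h <- random_hits(len, sample(0:50, 1))
    expect_identical(merged_coverage_fraction(h, len, 50),
                     oracle_coverage(h, len, 50))
  }
})

test_that("adding a hit never decreases coverage", {
  set.seed(5)
  len <- 5000
  h <- random_hits(len, 20)
  base <- merged_coverage_fraction(h, len, 50)
  for (i in 1:20) {
    extra <- rbind(h, random_hits(len, 1))
    expect_gte(merged_coverage_fraction(extra, len, 50), base)
  }
})

test_that("nucleotide rule has an inclusive 85% boundary", {
  expect_true(nucleotide_rule(mkhits(list(1, 850, 60)), 1000))
  expect_false(nucleotide_rule(mkhits(list(1, 849, 60)), 1000))
  expect_false(nucleotide_rule(mkhits(list(1, 850, 60))[0, ], 1000))
})

test_that("protein rule needs >= 2 hit ORFs making up >= 50% of ORF count", {
  orfs <- function(n) data.frame(orf_id = sprintf("o%d", seq_len(n)))
  ph <- function(ids) data.frame(orf_id = ids)
  expect_true(protein_rule(orfs(4), ph(c("o1", "o3"))))          # 2/4
  expect_false(protein_rule(orfs(5), ph(c("o1", "o3"))))         # 2/5 < 0.5
  expect_false(protein_rule(orfs(1), ph("o1")))                  # < 2 ORFs hit
  # a multiply-hit ORF counts once
  expect_false(protein_rule(orfs(4), ph(c("o1", "o1", "o1"))))
  expect_error(protein_rule(orfs(0), ph("o1")), "no ORF calls")
  # adding a protein hit never flips TRUE -> FALSE
  expect_true(protein_rule(orfs(4), ph(c("o1", "o2", "o3"))))
})

test_that("triage ORs the routes and applies the rRNA veto", {
  contigs <- data.frame(id = c("c1", "c2", "c3"), length = c(5000L, 5000L, 5000L))
  tc <- expand.grid(contig_id = contigs$id,
                    tool = c("virsorter2", "deepvirfinder", "vrca_circular"),
                    stringsAsFactors = FALSE)
  tc$positive <- tc$contig_id == "c1" & tc$tool == "virsorter2"
  nuc <- data.frame(query_id = "c2", subject_id = "db", pct_identity = 95,
                    q_start = 1L, q_end = 5000L, e_value = 1e-30, bitscore = 1)
  orfs <- data.frame(contig_id = character(), orf_id = character(),
                     start = integer(), end = integer(), strand = character())
  ph <- data.frame(orf_id = character(), database = character(),
                   e_value = numeric(), contig_id = character())
  rr <- data.frame(contig_id = "c2", rrna_type = "16S")
  dec <- triage_contigs(contigs, nuc, orfs, ph, tc, rr)
  expect_true(dec$viral[dec$contig_id == "c1"])                 # tool alone suffices
  expect_true(dec$nucleotide_route[dec$contig_id == "c2"])
  expect_false(dec$viral[dec$contig_id == "c2"])                # rRNA veto
  expect_true(dec$rrna_excluded[dec$contig_id == "c2"])
  expect_false(dec$viral[dec$contig_id == "c3"])                # no evidence
  expect_error(triage_contigs(contigs[c(1, 1), ], nuc, orfs, ph, tc, rr),
               "duplicate")
})

test_that("route flags are independent evidence streams", {
  b <- simulate_evidence_bundle(n_contigs = 80, seed = 15)
  dec <- suppressMessages(triage_contigs(b$contigs, b$nuc_hits, b$orfs,
                                         b$protein_hits, b$tool_calls,
                                         b$rrna_hits))
  # zeroing the nucleotide stream changes only nucleotide flags
  dec0 <- suppressMessages(triage_contigs(b$contigs, b$nuc_hits[0, ], b$orfs,
                                          b$protein_hits, b$tool_calls,
                                          b$rrna_hits))
  expect_true(all(!dec0$nucleotide_route))
  for (col in c("protein_route", "virsorter2_route", "deepvirfinder_route",
                "circular_route", "rrna_excluded"))
    expect_identical(dec0[[col]], dec[[col]])
})

test_that("provirus refinement trims the effective length with an inclusive 3 kbp keep rule", {
  contigs <- data.frame(id = c("p1", "p2", "p3"), length = c(8000L, 8000L, 8000L))
  tc <- data.frame(contig_id = contigs$id, tool = "virsorter2", positive = TRUE)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), q_start = integer(),
                      q_end = integer(), e_value = numeric(), bitscore = numeric())
  orfs <- data.frame(contig_id = character(), orf_id = character(),
                     start = integer(), end = integer(), strand = character())
  ph <- data.frame(orf_id = character(), database = character(),
                   e_value = numeric(), contig_id = character())
  rr <- data.frame(contig_id = character(), rrna_type = character())
  dec <- triage_contigs(contigs, empty, orfs, ph, tc, rr)
  qual <- data.frame(contig_id = c("p1", "p2"),
                     completeness = c(90, 90), gene_count = c(10L, 10L),
                     viral_genes = c(5L, 5L), provirus = TRUE,
                     region_start = c(100L, 1L), region_end = c(3200L, 2999L))
  out <- refine_and_filter(dec, qual)
  expect_equal(out$effective_length[out$contig_id == "p1"], 3101L)
  expect_true(out$viral[out$contig_id == "p1"])
  expect_equal(out$effective_length[out$contig_id == "p2"], 2999L)
  expect_false(out$viral[out$contig_id == "p2"])               # below 3 kbp
  expect_equal(out$effective_length[out$contig_id == "p3"], 8000L)  # no record
  expect_true(out$viral[out$contig_id == "p3"])
  bad <- qual; bad$region_end[1] <- 9000L
  expect_error(refine_and_filter(dec, bad), "beyond")
})

test_that("quantitative inclusion applies the three CheckV thresholds inclusively", {
  dec <- data.frame(contig_id = sprintf("c%d", 1:5),
                    viral = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    effective_length = 5000L, quant_included = NA)
  qual <- data.frame(
    contig_id = sprintf("c%d", 1:5),
    completeness = c(50.0, 49.9, NA, 80, 99),
    gene_count = c(10L, 10L, 10L, 10L, 10L),
    viral_genes = c(1L, 5L, 5L, 0L, 9L),
    provirus = FALSE, region_start = NA_integer_, region_end = NA_integer_)
  out <- quant_inclusion(dec, qual)
  expect_true(out$quant_included[1])      # all three boundaries inclusive
  expect_false(out$quant_included[2])     # completeness 49.9
  expect_false(out$quant_included[3])     # unknown completeness fails
  expect_false(out$quant_included[4])     # no viral genes
  expect_false(out$quant_included[5])     # not viral
  # viral-gene fraction boundary: 1/10 passes, 1/11 does not
  qual2 <- qual[1, ]; qual2$gene_count <- 11L
  expect_false(quant_inclusion(dec[1, ], qual2)$quant_included)
  qual3 <- qual[1, ]; qual3$gene_count <- 0L; qual3$viral_genes <- 0L
  expect_warning(out3 <- quant_inclusion(dec[1, ], qual3), "undefined")
  expect_false(out3$quant_included)
})
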