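# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive per-base / enumeration algorithms and never
# call the code paths they check.

# Per-base boolean-array coverage of a contig by qualifying hits.
oracle_coverage <- function(hits, contig_length, min_identity) {
  covered <- logical(contig_length)
  h <- hits[hits$pct_identity >= min_identity, , drop = FALSE]
  for (i in seq_len(nrow(h)))
    covered[h$q_start[i]:h$q_end[i]] <- TRUE
  sum(covered) / contig_length
}

# Step-up BH adjustment computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# PERMANOVA R^2 for a grouping via the direct double-loop sums of squared
# distances (SS_total = sum_{i<j} d_ij^2 / n; SS_within analogous per group).
oracle_permanova_r2 <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  ss_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_total <- ss_total + m[i, j]^2
  ss_total <- ss_total / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    s <- 0
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx))
      s <- s + m[idx[a], idx[b]]^2
    ss_within <- ss_within + s / length(idx)
  }
  1 - ss_within / ss_total
}

# Upper-tail hypergeometric probability by pmf summation.
oracle_hyper_tail <- function(overlap, term_size, query_size, universe_size) {
  ks <- overlap:min(term_size, query_size)
  sum(stats::dhyper(ks, term_size, universe_size - term_size, query_size))
}

# Closed-form two-sided power of the restoration contrast from the
# noncentral t distribution.
power_nct <- function(effect, n, alpha = 0.05, weights = c(0.5, -1, 0.5)) {
  df <- sum(n) - 3
  ncp <- effect / sqrt(sum(weights^2 / n))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

# Contig set forming seeded homology clusters: within each cluster all
# pairs share >= 90% identity over >= 90% of the shorter member (hits are
# emitted with the shorter contig as query), across clusters nothing.
make_homology_clusters <- function(n_clusters = 8, max_size = 5, seed = 42) {
  set.seed(seed)
  contigs <- list(); hits <- list()
  for (cl in seq_len(n_clusters)) {
    size <- sample(2:max_size, 1)
    lens <- sort(sample(seq(3000, 20000, by = 100), size), decreasing = TRUE)
    ids <- sprintf("cl%02d_m%d", cl, seq_len(size))
    contigs[[cl]] <- data.frame(id = ids, length = lens,
                                stringsAsFactors = FALSE)
    for (a in seq_len(size - 1)) for (b in (a + 1):size) {
      short_len <- lens[b]
      span <- as.integer(ceiling(stats::runif(1, 0.9, 1.0) * short_len))
      hits[[length(hits) + 1]] <- data.frame(
        query_id = ids[b], subject_id = ids[a],
        pct_identity = round(stats::runif(1, 90, 100), 1),
        q_start = 1L, q_end = min(span, short_len),
        e_value = 1e-30, bitscore = 500,
        stringsAsFactors = FALSE)
    }
  }
  # singleton contigs with no partners
  singles <- data.frame(id = sprintf("solo%02d", 1:5),
                        length = sample(seq(3000, 20000, by = 100), 5),
                        stringsAsFactors = FALSE)
  list(contigs = rbind(do.call(rbind, contigs), singles),
       hits = do.call(rbind, hits))
}

# Random hit tables for coverage fuzzing.
random_hits <- function(contig_length, n_hits) {
  if (n_hits == 0)
    return(data.frame(q_start = integer(), q_end = integer(),
                      pct_identity = numeric()))
  s <- sample.int(contig_length, n_hits, replace = TRUE)
  e <- pmin(s + stats::rgeom(n_hits, 1 / 500), contig_length)
  data.frame(q_start = s, q_end = e,
             pct_identity = round(stats::runif(n_hits, 20, 100), 1))
}

expect_all_equal <- function(x, y, tol = 1e-12) {
  expect_true(max(abs(x - y)) <= tol)
}
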