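# Shared fixtures: a fixed synthetic cox1-like query and small builders.

fixture_query <- function() random_query(length = 1534L, gc = 0.38, seed = 2L)

# A tiny assembly with one exact plus-strand copy of query[qs, qe) placed
# at `at` (0-based) inside random background. The 12 background bases on
# each side of the copy are forced to mismatch the continuing query so the
# optimal alignment stops exactly at the planted boundary.
fixture_exact_copy <- function(query, qs, qe, at = 500L, pad = 2000L,
                               seed = 99L) {
  frag <- substr(query, qs + 1L, qe)
  bg1 <- generate_background(at, 0.4, seed = seed)
  bg2 <- generate_background(pad, 0.4, seed = seed + 1L)
  mism <- function(base) chartr("ACGT", "CATG", base)
  Lq <- nchar(query)
  for (o in 1:12) {
    if (qs - o >= 0 && at - o >= 0)
      substr(bg1, at - o + 1L, at - o + 1L) <-
        mism(substr(query, qs - o + 1L, qs - o + 1L))
    if (qe + o <= Lq && o <= nchar(bg2))
      substr(bg2, o, o) <- mism(substr(query, qe + o, qe + o))
  }
  stats::setNames(paste0(bg1, frag, bg2), "fix1")
}

# Build a minimal hit-table row for filter tests.
make_hit <- function(scaffold_id, ss, se, aln_len = se - ss, qs = 0L,
                     qe = min(aln_len, 1534L), strand = "+",
                     identity = 1, score = 2 * aln_len) {
  data.frame(query_id = "q", scaffold_id = scaffold_id, qs = qs, qe = qe,
             ss = ss, se = se, strand = strand, aln_len = aln_len,
             identity = identity, score = score,
             matches = as.integer(round(identity * aln_len)),
             gaps = 0L, cigar = NA_character_, evalue = NA_real_,
             stringsAsFactors = FALSE)
}

# Brute-force transitive-closure interval merging oracle (O(n^2)).
merge_oracle <- function(hits, merge_gap) {
  n <- nrow(hits)
  if (n == 0L) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same <- hits$scaffold_id[i] == hits$scaffold_id[j]
    gap <- max(hits$ss[i], hits$ss[j]) - min(hits$se[i], hits$se[j])
    adj[i, j] <- same && gap <= merge_gap
  }
  # transitive closure via repeated multiplication (small n)
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  length(unique(comp))
}
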