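test_that("each exclusion criterion fires exactly at its boundary", {
  assembly <- c(s1 = strrep("A", 10000), s2 = strrep("A", 1000),
                s3 = strrep("A", 5000))
  hits <- rbind(
    make_hit("s1", 4000L, 4099L, aln_len = 99L),    # too short (strict <)
    make_hit("s1", 4000L, 4100L, aln_len = 100L),   # boundary passes
    make_hit("s2", 0L, 950L),                       # spans 95% AND at edge
    make_hit("s3", 2000L, 2300L))                   # interior, kept
  rep <- filter_hits(hits, assembly)
  expect_equal(rep$records$kept, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(rep$records$reasons,
               c("min_length", "", "scaffold_span,edge", ""))
  expect_equal(unname(rep$tallies["kept"]), 2L)
  expect_equal(unname(rep$tallies["scaffold_span"]), 1L)
  expect_equal(unname(rep$tallies["edge"]), 1L)
})

test_that("edge tolerance and span fraction boundaries behave as documented", {
  assembly <- c(s1 = strrep("A", 1000))
  p <- filter_params(edge_tol = 10)
  # ss = 10 is within tolerance; ss = 11 is not
  expect_false(filter_hits(make_hit("s1", 10L, 210L), assembly, p)$records$kept)
  expect_true(filter_hits(make_hit("s1", 11L, 211L), assembly, p)$records$kept)
  # se within edge_tol of scaffold end
  expect_false(filter_hits(make_hit("s1", 700L, 990L), assembly, p)$records$kept)
  expect_true(filter_hits(make_hit("s1", 700L, 989L), assembly, p)$records$kept)
  # span fraction 0.94 kept, 0.95 removed (criterion targets mito scaffolds)
  p0 <- filter_params(edge_tol = 0)
  expect_true(filter_hits(make_hit("s1", 30L, 970L), assembly, p0)$records$kept)
  expect_false(filter_hits(make_hit("s1", 25L, 975L), assembly, p0)$records$kept)
  expect_error(filter_hits(make_hit("sX", 0L, 100L), assembly), "absent")
})

test_that("filtering partitions input, is idempotent and monotone in thresholds", {
  q <- fixture_query()
  ins <- rbind(
    insertion_spec("interior", n = 6, frag_len_range = c(60, 500),
                   divergence = 0.08),
    insertion_spec("edge_start", n = 1), insertion_spec("contamination", n = 1))
  sim <- plant_numts(q, sim_config(n_scaffolds = 4, insertions = ins,
                                   seed = 51))
  hits <- search_numts(q, sim$assembly)
  rep <- filter_hits(hits, sim$assembly)
  expect_equal(nrow(rep$records), nrow(hits))
  expect_equal(sum(rep$records$kept) + sum(!rep$records$kept), nrow(hits))
  expect_identical(rep$records$kept, rep$records$reasons == "")
  # idempotence
  rep2 <- filter_hits(rep$kept, sim$assembly)
  expect_equal(nrow(rep2$kept), nrow(rep$kept))
  # monotonicity
  kept_n <- function(p) unname(filter_hits(hits, sim$assembly, p)$tallies["kept"])
  base <- kept_n(filter_params())
  expect_lte(kept_n(filter_params(min_len = 200)), base)
  expect_lte(kept_n(filter_params(max_span_frac = 0.5)), base)
  expect_lte(kept_n(filter_params(edge_tol = 500)), base)
})

test_that("insertion-site merging follows the gap rule and matches the brute-force oracle", {
  h <- rbind(make_hit("s1", 100L, 400L), make_hit("s1", 900L, 1200L))
  expect_equal(nrow(merge_insertion_sites(h, filter_params(merge_gap = 1000))), 1L)
  one <- merge_insertion_sites(h, filter_params(merge_gap = 1000))
  expect_equal(one$start, 100)
  expect_equal(one$end, 1200)
  expect_equal(nrow(merge_insertion_sites(h, filter_params(merge_gap = 100))), 2L)
  h2 <- rbind(make_hit("s1", 0L, 300L), make_hit("s2", 0L, 300L))
  expect_equal(nrow(merge_insertion_sites(h2, filter_params(merge_gap = 1e6))), 2L)
  # randomized comparison against O(n^2) transitive-closure oracle
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(2:25, 1)
    gap <- sample(c(0, 50, 500, 2000), 1)
    hh <- do.call(rbind, lapply(seq_len(n), function(i) {
      s <- sample(0:5000, 1)
      make_hit(sample(c("sA", "sB"), 1), s, s + sample(50:400, 1))
    }))
    got <- nrow(merge_insertion_sites(hh, filter_params(merge_gap = gap)))
    expect_equal(got, merge_oracle(hh, gap))
    # invariance to input order
    perm <- hh[sample(nrow(hh)), ]
    expect_equal(nrow(merge_insertion_sites(perm,
                                            filter_params(merge_gap = gap))),
                 got)
  }
})

test_that("merged loci are non-overlapping with gaps above merge_gap", {
  set.seed(53)
  hh <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample(0:20000, 1)
    make_hit("s1", s, s + sample(50:600, 1))
  }))
  loci <- merge_insertion_sites(hh, filter_params(merge_gap = 300))
  expect_true(all(diff(loci$start) > 0))
  gaps <- loci$start[-1] - loci$end[-nrow(loci)]
  expect_true(all(gaps > 300))
})

test_that("extraction returns query-oriented sequences and respects bounds", {
  q <- fixture_query()
  frag <- substr(unname(q), 101, 600)
  scaf <- c(s1 = paste0(generate_background(1000, 0.4, seed = 54),
                        revcomp(frag),
                        generate_background(1000, 0.4, seed = 55)))
  loci <- data.frame(scaffold_id = "s1", start = 1000, end = 1500,
                     strand = "-", name = "s1:1001-1500(-)",
                     identity = 1, score = 1000, n_members = 1L)
  got <- extract_numt_sequences(scaf, loci)
  expect_identical(unname(got), frag)
  # width-1 locus; plus strand slice
  loci1 <- data.frame(scaffold_id = "s1", start = 0, end = 1, strand = "+",
                      name = "w1", identity = 1, score = 2, n_members = 1L)
  expect_equal(unname(nchar(extract_numt_sequences(scaf, loci1))), 1L)
  bad <- data.frame(scaffold_id = "s1", start = 2400, end = 2600,
                    strand = "+", name = "x", identity = 1, score = 2,
                    n_members = 1L)
  expect_error(extract_numt_sequences(scaf, bad), "bounds")
})

test_that("site counting is order-invariant and tabulates per scaffold", {
  expect_equal(count_sites(merge_insertion_sites(empty <- make_hit("s", 0, 1)[0, ]))$total, 0L)
  h <- rbind(make_hit("sB", 0L, 200L), make_hit("sA", 0L, 200L),
             make_hit("sA", 5000L, 5200L))
  loci <- merge_insertion_sites(h, filter_params(merge_gap = 100))
  cs <- count_sites(loci)
  expect_equal(cs$total, 3L)
  expect_equal(cs$per_scaffold$scaffold_id, c("sA", "sB"))
  expect_equal(cs$per_scaffold$n_sites, c(2L, 1L))
  perm <- loci[rev(seq_len(nrow(loci))), ]
  expect_equal(count_sites(perm)$total, 3L)
})
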