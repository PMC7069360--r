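test_that("seed index enumerates exact k-mer positions on both strands", {
  idx <- build_seed_index("ACGTACGT", k = 4)
  expect_equal(idx$fwd[["ACGT"]], c(0L, 4L))
  # reverse complement of ACGTACGT is ACGTACGT (palindromic repeat)
  expect_equal(idx$rev[["ACGT"]], c(0L, 4L))
  # all-N query yields an empty index
  idxN <- build_seed_index(strrep("N", 20), k = 5)
  expect_length(idxN$fwd, 0L)
  expect_length(idxN$rev, 0L)
  expect_error(build_seed_index("ACGT", k = 11), "exceeds")
  # index size equals distinct N-free k-mers per strand
  set.seed(31)
  q <- generate_background(100, 0.5)
  idx2 <- build_seed_index(q, k = 6)
  kmers <- substring(q, 1:95, 6:100)
  expect_length(idx2$fwd, length(unique(kmers)))
  expect_equal(sum(lengths(idx2$fwd)), 95L)
})

test_that("Smith-Waterman reproduces hand-checked optima", {
  a <- "ACGTACGTACGTACGTACGT"
  h <- smith_waterman(a, a)
  expect_equal(h$score, 40)
  expect_equal(h$identity, 1)
  expect_equal(h$aln_len, 20L)
  # best local alignment of ACGT vs TTTT is a single T<->T match
  expect_equal(smith_waterman("ACGT", "TTTT")$score, 2)
  # gap arithmetic: deleting 2 bases from a 30-mer costs open + 2*extend
  b <- generate_background(30, 0.5, seed = 32)
  bdel <- paste0(substr(b, 1, 15), substr(b, 18, 30))
  expect_equal(smith_waterman(b, bdel)$score, 28 * 2 - (5 + 2 * 2))
  expect_error(smith_waterman(strrep("A", 4000), strrep("A", 4000)),
               "guard")
})

test_that("Smith-Waterman score is symmetric and N never matches", {
  for (i in 1:10) {
    a <- generate_background(150, 0.5, seed = 40 + i)
    b <- generate_background(120, 0.5, seed = 60 + i)
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
  expect_equal(nrow(smith_waterman(strrep("N", 30), strrep("N", 30))), 0L)
})

test_that("Smith-Waterman agrees with Biostrings local alignment scores", {
  for (i in 1:20) {
    a <- generate_background(300, 0.45, seed = 100 + i)
    mut <- mutate_fragment(substr(a, 50, 250), 0.1, 0.01)$seq
    b <- paste0(generate_background(50, 0.45, seed = 200 + i), mut)
    ours <- smith_waterman(a, b)$score
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = TRUE)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("seed extension recovers an exact planted copy in full", {
  q <- fixture_query()
  scaf <- fixture_exact_copy(q, 300L, 500L, at = 1000L)
  # seed at offset 50 into the planted copy
  h <- extend_seed(scaf, q, list(scaffold_pos = 1050L, query_pos = 350L,
                                 strand = "+"))
  expect_equal(h$qs, 300L)
  expect_equal(h$qe, 500L)
  expect_equal(h$ss, 1000L)
  expect_equal(h$se, 1200L)
  expect_equal(h$identity, 1)
  expect_equal(h$score, 400)
  expect_equal(h$cigar, "200M")
})

test_that("seed extension in random background reports nothing", {
  set.seed(33)
  none <- 0L
  for (i in 1:20) {
    q <- generate_background(500, 0.5)
    s <- generate_background(2000, 0.5)
    # force an exact 11-mer
    qp <- sample(0:(500 - 11), 1)
    sp <- sample(0:(2000 - 11), 1)
    substr(s, sp + 1, sp + 11) <- substr(q, qp + 1, qp + 11)
    h <- extend_seed(c(s = s), q, list(scaffold_pos = sp, query_pos = qp,
                                       strand = "+"))
    if (nrow(h) == 0L) none <- none + 1L
  }
  expect_equal(none, 20L)
})

test_that("search finds a single full-length exact copy with identity 1", {
  q <- random_query(1000, 0.4, seed = 34)
  scaf <- c(s1 = paste0(generate_background(3000, 0.4, seed = 35), q,
                        generate_background(3000, 0.4, seed = 36)))
  hits <- search_numts(q, scaf)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$qs, 0L)
  expect_equal(hits$qe, 1000L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$ss, 3000L)
})

test_that("search on random megabase background yields zero hits", {
  q <- fixture_query()
  scaf <- c(bg = generate_background(1e6, 0.4, seed = 37))
  expect_equal(nrow(search_numts(q, scaf)), 0L)
})

test_that("strand symmetry: reverse-complementing the assembly mirrors hits", {
  q <- fixture_query()
  mut <- mutate_fragment(substr(q, 201, 900), 0.08, 0.005, seed = 38)$seq
  scaf <- paste0(generate_background(1500, 0.4, seed = 39), mut,
                 generate_background(1500, 0.4, seed = 40))
  h1 <- search_numts(q, c(s = scaf))
  h2 <- search_numts(q, c(s = revcomp(scaf)))
  expect_equal(nrow(h1), 1L)
  expect_equal(nrow(h2), 1L)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$qs, h2$qs)
  expect_equal(h1$qe, h2$qe)
  expect_equal(h2$strand, "-")
  expect_equal(h2$ss, nchar(scaf) - h1$se)
  expect_equal(h2$se, nchar(scaf) - h1$ss)
})

test_that("lowering score_min never removes hits; output is deterministic", {
  q <- fixture_query()
  ins <- insertion_spec("interior", n = 4, frag_len_range = c(100, 400),
                        divergence = 0.1)
  sim <- plant_numts(q, sim_config(n_scaffolds = 2,
                                   scaffold_length_range = c(10000, 15000),
                                   insertions = ins, seed = 41))
  strict <- search_numts(q, sim$assembly, score_min = 120)
  loose <- search_numts(q, sim$assembly, score_min = 60)
  key <- function(h) paste(h$scaffold_id, h$ss, h$se, h$strand)
  expect_true(all(key(strict) %in% key(loose)))
  again <- search_numts(q, sim$assembly, score_min = 60)
  expect_identical(loose, again)
})

test_that("search best score equals the Smith-Waterman optimum on seeded instances", {
  # smaller companion to the 200-instance acceptance run
  q0 <- fixture_query()
  fails <- 0L
  for (i in 1:40) {
    with_seed <- function(s, e) numtscan:::with_seed(s, e)
    inst <- with_seed(500 + i, {
      Lq <- 700L
      q <- substr(q0, 1, Lq)
      len <- sample(150:500, 1)
      qs <- sample(0:(Lq - len), 1)
      div <- runif(1, 0, 0.15)
      mut <- mutate_fragment(substr(q, qs + 1, qs + len), div, 0.005)$seq
      pad <- sample(100:600, 1)
      scaf <- paste0(generate_background(pad, 0.4), mut,
                     generate_background(1800 - pad - nchar(mut), 0.4))
      list(q = q, scaf = scaf)
    })
    hits <- search_numts(inst$q, c(s = inst$scaf), score_min = 40)
    sw <- smith_waterman(inst$q, inst$scaf)
    best <- if (nrow(hits) > 0L) max(hits$score) else 0
    if (best != sw$score) fails <- fails + 1L
  }
  expect_equal(fails, 0L)
})
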