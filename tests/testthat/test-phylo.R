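test_that("reference-anchored rows are built correctly from column traces", {
  q <- c(q = "ACGTACGTACGTACGTACGT")          # 20 bp query
  # hit 1: exact copy of q[0,10) ; hit 2: exact copy of q[5,15)
  scafs <- c(n1 = unname(substr(q, 1, 10)), n2 = unname(substr(q, 6, 15)))
  hits <- rbind(
    data.frame(query_id = "q", scaffold_id = "n1", qs = 0L, qe = 10L,
               ss = 0L, se = 10L, strand = "+", aln_len = 10L, identity = 1,
               score = 20, matches = 10L, gaps = 0L, cigar = "10M",
               evalue = NA_real_),
    data.frame(query_id = "q", scaffold_id = "n2", qs = 5L, qe = 15L,
               ss = 0L, se = 10L, strand = "+", aln_len = 10L, identity = 1,
               score = 20, matches = 10L, gaps = 0L, cigar = "10M",
               evalue = NA_real_))
  msa <- induce_reference_msa(hits, scafs, q)
  expect_equal(nchar(msa$rows), c(20L, 20L), ignore_attr = TRUE)
  expect_equal(msa$rows[[1]], paste0(substr(q, 1, 10), strrep("-", 10)))
  expect_equal(msa$rows[[2]], paste0("-----", substr(q, 6, 15), "-----"))
  # columns 5..9 (0-based) covered by both
  expect_equal(substr(msa$rows[[1]], 6, 10), substr(msa$rows[[2]], 6, 10))
})

test_that("insertions in the NUMT are dropped; deletions leave gap columns", {
  q <- c(q = generate_background(60, 0.5, seed = 60))
  # NUMT = the whole query with a 3-bp insertion after position 30
  numt <- paste0(substr(q, 1, 30), "TTT", substr(q, 31, 60))
  h <- smith_waterman(q, numt)
  h$scaffold_id <- "ins3"
  expect_equal(h$gaps, 3L)
  msa <- induce_reference_msa(h, c(ins3 = numt), q)
  expect_equal(nchar(msa$rows[[1]]), 60L)
  expect_equal(msa$rows[[1]], unname(q))
  # full-coverage identical hit reproduces the query row
  h2 <- smith_waterman(q, unname(q))
  h2$scaffold_id <- "self"
  msa2 <- induce_reference_msa(h2, c(self = unname(q)), q)
  expect_equal(msa2$rows[[1]], unname(q))
  # inconsistent trace is rejected
  h3 <- h2
  h3$cigar <- "19M"
  expect_error(induce_reference_msa(h3, c(self = unname(q)), q),
               "inconsistent")
})

test_that("JC distance matches its closed form, saturation and overlap rules", {
  mk_msa <- function(rows) {
    structure(list(labels = names(rows), rows = rows,
                   Lq = nchar(rows[[1]]), query_id = "q"),
              class = "ref_msa")
  }
  a <- strrep("A", 400)
  expect_equal(jc_distance(mk_msa(c(r1 = a, r2 = a)))$d[1, 2], 0)
  # p = 0.25 -> d = -0.75 log(2/3)
  b <- paste0(strrep("A", 300), strrep("C", 100))
  D <- jc_distance(mk_msa(c(r1 = a, r2 = b)))
  expect_equal(D$p[1, 2], 0.25)
  expect_equal(D$d[1, 2], -0.75 * log(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(D$d[1, 2], 0.3041, tolerance = 1e-4)
  # p = 0.75 saturates
  c75 <- paste0(strrep("A", 100), strrep("C", 300))
  D2 <- jc_distance(mk_msa(c(r1 = a, r2 = c75, r3 = a)))
  expect_equal(D2$flag[1, 2], "saturated")
  expect_true(is.na(D2$d[1, 2]))
  expect_equal(D2$d[1, 3], 0)
  # insufficient overlap
  left <- paste0(strrep("A", 150), strrep("-", 250))
  right <- paste0(strrep("-", 250), strrep("A", 150))
  D3 <- jc_distance(mk_msa(c(r1 = left, r2 = right, r3 = a)))
  expect_equal(D3$flag[1, 2], "insufficient")
  expect_error(jc_distance(mk_msa(c(r1 = left, r2 = right))),
               "insufficient overlap")
  # monotone in p on [0, 0.75)
  ps <- seq(0, 0.74, by = 0.02)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(ds) > 0))
})

test_that("JC distances agree with ape::dist.dna on a simulated alignment", {
  q <- fixture_query()
  ms <- plant_multispecies(q, 2, 3, 0.12, 0.03, indel_rate = 0, seed = 61)
  nt <- numt_tree(ms$seqs, q)
  mat <- do.call(rbind, strsplit(unname(nt$msa$rows), ""))
  rownames(mat) <- nt$msa$labels
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(mat)),
                                 model = "JC69", pairwise.deletion = TRUE))
  expect_equal(nt$dist$d[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("neighbour joining: closed-form 3-taxon lengths and 2-taxon tree", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D3)
  pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[["A"]], 1, tolerance = 1e-9)
  expect_equal(pend[["B"]], 1, tolerance = 1e-9)
  expect_equal(pend[["C"]], 2, tolerance = 1e-9)
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- neighbor_joining(D2)
  expect_equal(sum(tr2$edge.length), 0.4)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("neighbour joining exactly recovers additive 4-taxon trees", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive matrix by path lengths
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- neighbor_joining(D)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  # recovered path lengths reproduce the matrix (additivity)
  paths <- ape::cophenetic.phylo(tr)
  expect_equal(paths[rownames(D), colnames(D)], D, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("monophyly on bipartitions: positive, negative and singleton cases", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_true(is_monophyletic(tr, c("a1", "a2")))
  expect_true(is_monophyletic(tr, c("b1", "b2")))
  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_false(is_monophyletic(mixed, c("a1", "a2")))
  expect_true(is_monophyletic(mixed, "a1"))
  expect_error(is_monophyletic(tr, c("a1", "zz")), "unknown")
  expect_error(is_monophyletic(tr, c("a1", "a2", "b1", "b2")), "proper")
})
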