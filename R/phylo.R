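#' Reference-anchored multiple alignment of NUMTs
#'
#' Builds a fixed-width alignment in query coordinates directly from each
#' hit's column trace: match/mismatch columns copy the (strand-oriented)
#' scaffold residue into the query position, scaffold-gap columns leave
#' `-`, and query-gap columns (insertions in the NUMT relative to the
#' query) are discarded. Positions outside a hit's query interval are `-`.
#' This replaces an external progressive aligner with a deterministic,
#' dependency-free construction; NUMT insertions relative to the query are
#' not represented.
#'
#' @param hits Hit `data.frame` rows with non-`NA` `cigar` traces (from
#'   [search_numts()] or [smith_waterman()]; outfmt-6 hits must be
#'   re-aligned first, see [align_to_query()]).
#' @param assembly The assembly (or any named sequence set) the hits'
#'   `scaffold_id`s refer to.
#' @param query The query sequence.
#' @param labels Optional row labels (default
#'   `scaffold:start-end(strand)`).
#' @return An object of class `ref_msa`: list with `labels`, `rows`
#'   (equal-length strings over `A,C,G,T,N,-`), `Lq`, `query_id`.
#' @export
induce_reference_msa <- function(hits, assembly, query, labels = NULL) {
  q <- as_query_chr(query)
  Lq <- nchar(q)
  seqs <- as_dna_chr(assembly)
  if (nrow(hits) == 0L) stop("no hits to align")
  if (any(is.na(hits$cigar)))
    stop("hit(s) without a column trace; re-align with smith_waterman ",
         "(see align_to_query) before building the alignment")
  if (is.null(labels))
    labels <- sprintf("%s:%d-%d(%s)", hits$scaffold_id, hits$ss + 1L,
                      hits$se, hits$strand)
  rows <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$qe > Lq) stop("hit query interval exceeds query length")
    slice <- substr(seqs[[h$scaffold_id]], h$ss + 1L, h$se)
    if (h$strand == "-") slice <- revcomp(slice)
    sres <- strsplit(slice, "")[[1]]
    ops <- expand_cigar(h$cigar)
    row <- rep("-", Lq)
    pq <- h$qs    # 0-based query cursor
    ps <- 0L      # cursor in oriented slice
    for (op in ops) {
      if (op == "M") {
        row[pq + 1L] <- sres[ps + 1L]
        pq <- pq + 1L; ps <- ps + 1L
      } else if (op == "I") {        # insertion in NUMT: drop the residue
        ps <- ps + 1L
      } else {                        # deletion in NUMT: query column stays -
        pq <- pq + 1L
      }
    }
    if (pq != h$qe || ps != length(sres))
      stop("column trace inconsistent with hit intervals (row ", i, ")")
    rows[i] <- paste(row, collapse = "")
  }
  structure(list(labels = labels, rows = setNames(rows, labels), Lq = Lq,
                 query_id = names(q)),
            class = "ref_msa")
}

#' Align free-standing NUMT sequences to the query
#'
#' Runs the exact local aligner ([smith_waterman()]) of each sequence
#' against the query (both orientations, keeping the better) and returns
#' a hit table with column traces, suitable for
#' [induce_reference_msa()].
#'
#' @param seqs Named character vector (or `DNAStringSet`) of NUMT
#'   sequences.
#' @param query The query sequence.
#' @param scoring A [scoring_scheme()].
#' @return A hit `data.frame` whose `scaffold_id` is the sequence label.
#' @export
align_to_query <- function(seqs, query, scoring = scoring_scheme()) {
  s <- as_dna_chr(seqs)
  q <- as_query_chr(query)
  rows <- lapply(names(s), function(lab) {
    fwd <- smith_waterman(q, s[[lab]], scoring)
    rcs <- revcomp(s[[lab]])
    rev <- smith_waterman(q, rcs, scoring)
    L <- nchar(s[[lab]])
    if (nrow(fwd) == 0L && nrow(rev) == 0L) return(NULL)
    use_rev <- nrow(fwd) == 0L ||
      (nrow(rev) > 0L && rev$score > fwd$score)
    h <- if (use_rev) rev else fwd
    # b-interval of the rc alignment maps back to the forward sequence
    if (use_rev) {
      ss <- L - h$se; se <- L - h$ss
      h$ss <- ss; h$se <- se
      h$strand <- "-"
      # trace is already along the forward query; residues come from the
      # reverse-complemented slice, which matches strand "-" handling
    }
    h$query_id <- names(q)
    h$scaffold_id <- lab
    h
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jukes-Cantor distance matrix from a reference-anchored alignment
#'
#' For each pair of rows, `p` is the mismatch fraction over columns where
#' both rows carry a resolved base (not `-`, not `N`), and
#' `d = -(3/4) ln(1 - (4/3) p)`. Pairs sharing fewer than
#' `min_shared_sites` columns are flagged `insufficient`; pairs with
#' `p >= 0.75` are flagged `saturated`. Both get `NA` distances and must
#' be excluded from tree building.
#'
#' @param msa A `ref_msa`.
#' @param min_shared_sites Minimum shared resolved columns (default 100,
#'   matching the hit-length filter).
#' @return A list of class `jc_dist`: `labels`, `d` (distance matrix),
#'   `p` (raw mismatch fractions), `n` (shared-site counts), `flag`
#'   (character matrix: `ok`, `saturated`, `insufficient`).
#' @export
jc_distance <- function(msa, min_shared_sites = 100L) {
  stopifnot(inherits(msa, "ref_msa"))
  m <- length(msa$rows)
  if (m < 2L) stop("need at least 2 rows")
  mat <- do.call(rbind, strsplit(unname(msa$rows), ""))
  resolved <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  d <- p <- matrix(0, m, m, dimnames = list(msa$labels, msa$labels))
  n <- matrix(0L, m, m, dimnames = list(msa$labels, msa$labels))
  flag <- matrix("ok", m, m, dimnames = list(msa$labels, msa$labels))
  diag(n) <- rowSums(resolved)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      sh <- resolved[i, ] & resolved[j, ]
      nij <- sum(sh)
      pij <- if (nij > 0L) sum(mat[i, sh] != mat[j, sh]) / nij else NA_real_
      fl <- "ok"
      dij <- NA_real_
      if (nij < min_shared_sites) {
        fl <- "insufficient"
      } else if (!is.na(pij) && pij >= 0.75) {
        fl <- "saturated"
      } else {
        dij <- -0.75 * log(1 - 4 * pij / 3)
      }
      n[i, j] <- n[j, i] <- nij
      p[i, j] <- p[j, i] <- if (is.na(pij)) NA_real_ else pij
      d[i, j] <- d[j, i] <- dij
      flag[i, j] <- flag[j, i] <- fl
    }
  }
  off <- upper.tri(d)
  if (all(is.na(d[off])))
    stop("insufficient overlap: all pairs excluded")
  structure(list(labels = msa$labels, d = d, p = p, n = n, flag = flag,
                 min_shared_sites = as.integer(min_shared_sites)),
            class = "jc_dist")
}

# Greedily drop the label with the most unusable (NA) pairwise distances
# until the remaining matrix is complete.
prune_incomplete <- function(D) {
  d <- if (inherits(D, "jc_dist")) D$d else as.matrix(D)
  dropped <- character(0)
  repeat {
    bad <- rowSums(is.na(d)) - 0L
    diag_na <- is.na(diag(d)); bad[diag_na] <- bad[diag_na] # diag is 0
    if (all(bad == 0L) || nrow(d) <= 2L) break
    worst <- which.max(bad)
    dropped <- c(dropped, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  list(d = d, dropped = dropped)
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (Studier-Keppler Q-matrix, as implemented
#' in [ape::nj()]); exact for additive distance matrices. Negative branch
#' lengths are clamped to zero and the total clamped deficit is recorded
#' in the `"clamped"` attribute. With two labels the trivial one-edge
#' tree is returned.
#'
#' @param D A `jc_dist`, `dist`, or symmetric numeric matrix with finite
#'   entries.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  d <- if (inherits(D, "jc_dist")) D$d else as.matrix(D)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (any(is.na(d)))
    stop("distance matrix contains NA; prune excluded pairs first")
  if (nrow(d) < 2L) stop("need at least 2 labels")
  if (nrow(d) == 2L) {
    tree <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
      tip.label = rownames(d), Nnode = 1L), class = "phylo")
    attr(tree, "order") <- "cladewise"
    attr(tree, "clamped") <- 0
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  deficit <- sum(pmin(tree$edge.length, 0))
  tree$edge.length <- pmax(tree$edge.length, 0)
  attr(tree, "clamped") <- -deficit
  tree
}

# All non-trivial bipartitions of an unrooted tree, as a list of
# tip-label character vectors (one side each).
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n <- length(labs)
  sides <- lapply(parts, function(p) labs[p])
  # drop the root part (all tips); keep internal-edge splits only
  sides[vapply(sides, length, integer(1)) < n]
}

#' Test per-species monophyly on an unrooted tree
#'
#' A label subset is monophyletic iff it (or its complement) is one side
#' of a bipartition obtained by removing a single edge. Singleton subsets
#' are always monophyletic (every pendant edge is a bipartition).
#'
#' @param tree An [ape::phylo] tree.
#' @param label_subset Character vector of leaf labels, a proper
#'   non-empty subset of the leaf set.
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, label_subset) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(label_subset, tips)
  if (length(unknown) > 0L)
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  k <- length(unique(label_subset))
  if (k == 0L || k >= length(tips))
    stop("label subset must be a proper non-empty subset of the leaves")
  if (k == 1L || k == length(tips) - 1L) return(TRUE)
  subset <- sort(unique(label_subset))
  comp <- sort(setdiff(tips, subset))
  for (side in tree_bipartitions(tree)) {
    s <- sort(side)
    if (identical(s, subset) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

#' Per-species monophyly verdicts
#'
#' @param tree An [ape::phylo] tree.
#' @param species Named character vector mapping leaf label to species.
#' @return A `data.frame` with `species`, `n_leaves`, `monophyletic`.
#' @export
monophyly_report <- function(tree, species) {
  species <- species[tree$tip.label]
  sp <- sort(unique(species))
  data.frame(
    species = sp,
    n_leaves = vapply(sp, function(s) sum(species == s), integer(1)),
    monophyletic = vapply(sp, function(s) {
      labs <- names(species)[species == s]
      if (length(labs) == length(tree$tip.label)) TRUE
      else is_monophyletic(tree, labs)
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the NUMT tree from extracted sequences
#'
#' Convenience wrapper: aligns sequences to the query
#' ([align_to_query()]), builds the reference-anchored alignment, computes
#' JC distances, prunes labels with unusable pairs, and infers the
#' neighbour-joining tree.
#'
#' @param seqs Named character vector of NUMT sequences.
#' @param query The query sequence.
#' @param min_shared_sites Passed to [jc_distance()].
#' @param scoring A [scoring_scheme()].
#' @return A list with `msa`, `dist`, `tree`, and `dropped` (labels
#'   excluded for insufficient overlap or saturation).
#' @export
numt_tree <- function(seqs, query, min_shared_sites = 100L,
                      scoring = scoring_scheme()) {
  hits <- align_to_query(seqs, query, scoring)
  if (nrow(hits) < 2L) stop("need at least 2 alignable sequences")
  msa <- induce_reference_msa(hits, seqs, query, labels = hits$scaffold_id)
  D <- jc_distance(msa, min_shared_sites)
  pr <- prune_incomplete(D)
  tree <- if (nrow(pr$d) >= 2L) neighbor_joining(pr$d) else NULL
  list(msa = msa, dist = D, tree = tree, dropped = pr$dropped)
}

#' Write a reference-anchored alignment as FASTA
#'
#' @param msa A `ref_msa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "ref_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$rows))
    writeLines(c(paste0(">", msa$labels[i]), msa$rows[[i]]), con)
  invisible(path)
}
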