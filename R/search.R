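#' Alignment scoring scheme
#'
#' Defaults mirror blastn: match +2, mismatch -3, gap open 5, gap extend 2
#' (a gap of length L costs `gap_open + L * gap_extend`, subtracted).
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch score.
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive per-residue gap-extension penalty.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= gap_extend, gap_extend >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Build an exact k-mer seed index of a query
#'
#' Indexes the query and its reverse complement separately; k-mers
#' containing N are skipped. Positions are 0-based start offsets.
#'
#' @param query Query sequence (character or [Biostrings::DNAString]).
#' @param k Seed length, 4..15.
#' @return A list with `k`, `fwd` and `rev` (named lists k-mer -> sorted
#'   integer positions), and `Lq`.
#' @export
build_seed_index <- function(query, k = 11L) {
  q <- as_query_chr(query)
  Lq <- nchar(q)
  k <- as.integer(k)
  if (k < 4L || k > 15L) stop("k must be in 4..15")
  if (k > Lq) stop("k exceeds query length")
  index_one <- function(s) {
    starts <- seq_len(Lq - k + 1L) - 1L
    kmers <- substring(s, starts + 1L, starts + k)
    keep <- !grepl("N", kmers, fixed = TRUE)
    split(starts[keep], kmers[keep])
  }
  list(k = k, Lq = Lq, fwd = index_one(q), rev = index_one(revcomp(q)))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact Gotoh three-state dynamic programme with traceback; the
#' verification oracle for the seeded search. Ties are broken
#' deterministically (higher score, then longer alignment, then leftmost).
#' N never counts as a match. Guarded to `|a| * |b| <= 1e7` cells.
#'
#' @param a,b DNA strings.
#' @param scoring A [scoring_scheme()].
#' @return A one-row hit `data.frame` (`a` plays the query role, `b` the
#'   scaffold role, strand `+`), or a zero-row table if the best score is 0.
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme()) {
  a <- as_query_chr(a); b <- as_query_chr(b)
  r <- sw_align_cpp(a, b, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  if (r$score <= 0 || r$a_end <= r$a_start) return(empty_hits())
  data.frame(query_id = "a", scaffold_id = "b",
             qs = r$a_start, qe = r$a_end, ss = r$b_start, se = r$b_end,
             strand = "+", aln_len = r$aln_len,
             identity = r$matches / r$aln_len, score = r$score,
             matches = r$matches, gaps = r$gaps, cigar = r$cigar,
             evalue = NA_real_, stringsAsFactors = FALSE)
}

#' Gapped x-drop extension of one exact seed match
#'
#' Anchored at the seed start, the alignment is extended left and right by
#' banded affine-gap dynamic programming, pruning cells whose score falls
#' more than `x_drop` below the running best.
#'
#' @param scaffold Scaffold sequence (character scalar).
#' @param query Query sequence.
#' @param seed_match List or vector with `scaffold_pos`, `query_pos`
#'   (0-based seed starts) and `strand` (`"+"` or `"-"`; for `-` the
#'   `query_pos` refers to the reverse-complemented query).
#' @param scoring A [scoring_scheme()].
#' @param x_drop Termination threshold (default 50).
#' @param score_min Minimum score to report a hit (default 60).
#' @return A one-row hit `data.frame`, or a zero-row table when the
#'   extension scores below `score_min`.
#' @export
extend_seed <- function(scaffold, query, seed_match,
                        scoring = scoring_scheme(), x_drop = 50L,
                        score_min = 60L) {
  s <- as_query_chr(scaffold)
  q <- as_query_chr(query)
  strand <- if (!is.null(seed_match$strand)) seed_match$strand else "+"
  qeff <- if (strand == "-") revcomp(q) else q
  r <- extend_seed_cpp(qeff, s, as.integer(seed_match$query_pos),
                       as.integer(seed_match$scaffold_pos),
                       scoring$match, scoring$mismatch, scoring$gap_open,
                       scoring$gap_extend, as.integer(x_drop))
  if (!isTRUE(r$found) || r$score < score_min) return(empty_hits())
  Lq <- nchar(q)
  qs <- r$qs; qe <- r$qe; cigar <- r$cigar
  if (strand == "-") {
    qs <- Lq - r$qe; qe <- Lq - r$qs
    ops <- rev(expand_cigar(cigar))
    cigar <- compress_ops_r(ops)
  }
  data.frame(query_id = names(q), scaffold_id = names(s),
             qs = qs, qe = qe, ss = r$ss, se = r$se, strand = strand,
             aln_len = r$aln_len, identity = r$matches / r$aln_len,
             score = r$score, matches = r$matches, gaps = r$gaps,
             cigar = cigar, evalue = NA_real_, stringsAsFactors = FALSE)
}

compress_ops_r <- function(ops) {
  if (length(ops) == 0L) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Seeded search of a query against an assembly
#'
#' Finds exact k-mer seed matches on both strands, extends each with
#' gapped x-drop dynamic programming, discards extensions scoring below
#' `score_min`, and deduplicates overlapping hits per scaffold and strand,
#' keeping the best-scoring one. Output is sorted by scaffold then start
#' and is deterministic for identical inputs.
#'
#' @param query Query sequence (single FASTA record, character, or
#'   [Biostrings::DNAString]).
#' @param assembly Assembly ([Biostrings::DNAStringSet] or named character
#'   vector).
#' @param k Seed length (default 11, as in blastn's default word size).
#' @param scoring A [scoring_scheme()].
#' @param x_drop X-drop termination threshold (default 50).
#' @param score_min Minimum reported score (default 60, i.e. a perfect
#'   30-bp match; the downstream length filter, not the aligner, governs
#'   the 100-nt cutoff).
#' @return A hit `data.frame` with columns `query_id`, `scaffold_id`,
#'   `qs`, `qe`, `ss`, `se` (0-based half-open, forward strand), `strand`,
#'   `aln_len`, `identity`, `score`, `matches`, `gaps`, `cigar`, `evalue`.
#' @export
search_numts <- function(query, assembly, k = 11L,
                         scoring = scoring_scheme(), x_drop = 50L,
                         score_min = 60L) {
  q <- as_query_chr(query)
  if (nchar(q) == 0L) stop("empty query")
  a <- as_dna_chr(assembly)
  if (length(a) == 0L) stop("empty assembly")
  k <- as.integer(k)
  if (k < 4L || k > 15L) stop("k must be in 4..15")
  if (k > nchar(q)) stop("k exceeds query length")

  raw <- search_cpp(q, unname(a), k, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend,
                    as.integer(x_drop), as.integer(score_min))
  if (nrow(raw) == 0L) return(empty_hits())

  hits <- data.frame(
    query_id = names(q), scaffold_id = names(a)[raw$scaffold],
    qs = raw$qs, qe = raw$qe, ss = raw$ss, se = raw$se,
    strand = as.character(raw$strand), aln_len = raw$aln_len,
    identity = raw$matches / raw$aln_len, score = as.numeric(raw$score),
    matches = raw$matches, gaps = raw$gaps,
    cigar = as.character(raw$cigar), evalue = NA_real_,
    stringsAsFactors = FALSE)

  hits <- dedup_hits(hits)
  hits <- hits[order(hits$scaffold_id, hits$ss, hits$se, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

# Keep the single best-scoring hit in each transitive group of hits whose
# subject intervals overlap on the same scaffold and strand. Ties go to the
# longer alignment, then the leftmost start.
dedup_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)),
                    paste(hits$scaffold_id, hits$strand))) {
    o <- grp[order(hits$ss[grp], hits$se[grp])]
    cur <- o[1]; cur_end <- hits$se[cur]
    members <- cur
    flush <- function(members) {
      sc <- hits$score[members]
      len <- hits$aln_len[members]
      best <- members[order(-sc, -len, hits$ss[members])][1]
      keep[best] <<- TRUE
    }
    for (i in o[-1]) {
      if (hits$ss[i] < cur_end) {
        members <- c(members, i)
        cur_end <- max(cur_end, hits$se[i])
      } else {
        flush(members)
        members <- i
        cur_end <- hits$se[i]
      }
    }
    flush(members)
  }
  hits[keep, , drop = FALSE]
}
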