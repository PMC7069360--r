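#' Exclusion-filter parameters
#'
#' The three exclusion criteria applied to raw homology hits, in order:
#' (a) alignment length below `min_len` (default 100 nt, strict `<`);
#' (b) subject span covering at least `max_span_frac` of its scaffold
#' (default 0.95) — such scaffolds are treated as mitochondrial
#' contamination rather than nuclear insertions;
#' (c) alignment within `edge_tol` bp of a scaffold end (default 10 bp;
#' 0 demands exact abutment) — edge alignments may be truncated
#' assembly artefacts.
#' `merge_gap` (default 1000 bp) controls how far apart surviving hits may
#' be and still be merged into one insertion site.
#'
#' @param min_len Minimum alignment length kept (criterion a).
#' @param max_span_frac Scaffold-span fraction at or above which a hit is
#'   removed (criterion b).
#' @param edge_tol Distance (bp) from a scaffold end within which a hit is
#'   considered "at the edge" (criterion c).
#' @param merge_gap Maximum gap (bp) merged into one insertion site.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_len = 100L, max_span_frac = 0.95,
                          edge_tol = 10L, merge_gap = 1000L) {
  stopifnot(min_len >= 1, max_span_frac > 0, max_span_frac <= 1,
            edge_tol >= 0, merge_gap >= 0)
  structure(list(min_len = as.integer(min_len),
                 max_span_frac = max_span_frac,
                 edge_tol = as.integer(edge_tol),
                 merge_gap = as.integer(merge_gap)),
            class = "filter_params")
}

#' Apply the three exclusion criteria to homology hits
#'
#' A hit is removed iff any criterion fires; all firing criteria are
#' recorded, evaluated in the order `min_length`, `scaffold_span`, `edge`:
#' * `min_length`: `aln_len < min_len`;
#' * `scaffold_span`: `(se - ss) / scaffold_length >= max_span_frac`
#'   (the numerator is the subject span, a statement about scaffold
#'   coverage, not alignment columns);
#' * `edge`: `ss <= edge_tol` or `se >= scaffold_length - edge_tol`.
#'
#' @param hits A hit `data.frame` (from [search_numts()] or
#'   [read_blast_tab()]).
#' @param assembly The assembly the hits refer to.
#' @param params A [filter_params()].
#' @return A list of class `filter_report`: `records` (the hit table plus
#'   `kept` and `reasons` columns), `kept` (the surviving hits), `tallies`
#'   (named counts per reason plus `input`, `kept`, `removed`), and
#'   `params`.
#' @export
filter_hits <- function(hits, assembly, params = filter_params()) {
  lens <- scaffold_lengths(assembly)
  unknown <- setdiff(unique(hits$scaffold_id), names(lens))
  if (length(unknown) > 0L)
    stop("hit(s) reference scaffold(s) absent from assembly: ",
         paste(unknown, collapse = ", "))

  n <- nrow(hits)
  reasons <- character(n)
  if (n > 0L) {
    L <- as.numeric(lens[hits$scaffold_id])
    fail_a <- hits$aln_len < params$min_len
    fail_b <- (hits$se - hits$ss) / L >= params$max_span_frac
    fail_c <- hits$ss <= params$edge_tol | hits$se >= L - params$edge_tol
    reasons <- mapply(function(a, b, c) {
      paste(c(if (a) "min_length", if (b) "scaffold_span", if (c) "edge"),
            collapse = ",")
    }, fail_a, fail_b, fail_c, USE.NAMES = FALSE)
  } else {
    fail_a <- fail_b <- fail_c <- logical(0)
  }
  kept <- !nzchar(reasons)
  records <- hits
  records$kept <- kept
  records$reasons <- reasons
  structure(list(
    records = records,
    kept = hits[kept, , drop = FALSE],
    tallies = c(input = n, kept = sum(kept), removed = sum(!kept),
                min_length = sum(fail_a), scaffold_span = sum(fail_b),
                edge = sum(fail_c)),
    params = params), class = "filter_report")
}

#' Merge filtered hits into insertion sites
#'
#' Hits on the same scaffold merge transitively when the gap between
#' their subject intervals is at most `merge_gap`, regardless of strand
#' (inverted duplications within one insertion event would otherwise be
#' double-counted). Each resulting locus carries the union interval, the
#' strand/identity/score of its best-scoring member, and the member hits.
#'
#' @param kept_hits Hit `data.frame` (already filtered).
#' @param params A [filter_params()] (only `merge_gap` is used).
#' @return A locus `data.frame` with columns `scaffold_id`, `start`,
#'   `end`, `strand`, `name`, `identity`, `score`, `n_members`, plus a
#'   `members` list-column of member row indices into `kept_hits`.
#' @export
merge_insertion_sites <- function(kept_hits, params = filter_params()) {
  empty <- data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), identity = numeric(0),
                      score = numeric(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(kept_hits) == 0L) {
    empty$members <- list()
    return(empty)
  }
  loci <- list()
  for (sid in sort(unique(kept_hits$scaffold_id))) {
    idx <- which(kept_hits$scaffold_id == sid)
    idx <- idx[order(kept_hits$ss[idx], kept_hits$se[idx])]
    members <- idx[1]
    cur_end <- kept_hits$se[idx[1]]
    flush <- function(members, cur_end) {
      m <- kept_hits[members, , drop = FALSE]
      best <- members[order(-m$score, -m$aln_len, m$ss)][1]
      loci[[length(loci) + 1L]] <<- list(
        scaffold_id = sid, start = min(m$ss), end = max(m$se),
        strand = kept_hits$strand[best],
        identity = max(m$identity), score = max(m$score),
        n_members = length(members), members = members)
    }
    for (i in idx[-1]) {
      if (kept_hits$ss[i] - cur_end <= params$merge_gap) {
        members <- c(members, i)
        cur_end <- max(cur_end, kept_hits$se[i])
      } else {
        flush(members, cur_end)
        members <- i
        cur_end <- kept_hits$se[i]
      }
    }
    flush(members, cur_end)
  }
  out <- data.frame(
    scaffold_id = vapply(loci, `[[`, character(1), "scaffold_id"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    strand = vapply(loci, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  out <- cbind(out, data.frame(
    name = sprintf("%s:%d-%d(%s)", out$scaffold_id, out$start + 1L,
                   out$end, out$strand),
    identity = vapply(loci, `[[`, numeric(1), "identity"),
    score = vapply(loci, `[[`, numeric(1), "score"),
    n_members = vapply(loci, function(x) length(x$members), integer(1)),
    stringsAsFactors = FALSE))
  out$members <- lapply(loci, `[[`, "members")
  ord <- order(out$scaffold_id, out$start)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Extract NUMT sequences at insertion sites
#'
#' Slices each locus interval out of its scaffold; minus-strand loci are
#' reverse-complemented so every extracted sequence is in query
#' orientation. Labels are `scaffold:start-end(strand)` with 1-based
#' inclusive display coordinates.
#'
#' @param assembly The assembly.
#' @param loci Locus `data.frame` from [merge_insertion_sites()].
#' @return A named character vector of sequences.
#' @export
extract_numt_sequences <- function(assembly, loci) {
  seqs <- as_dna_chr(assembly)
  lens <- nchar(seqs)
  if (nrow(loci) == 0L) return(setNames(character(0), character(0)))
  if (any(!loci$scaffold_id %in% names(seqs)) ||
      any(loci$start < 0) || any(loci$end > lens[loci$scaffold_id]))
    stop("locus interval out of assembly bounds")
  out <- vapply(seq_len(nrow(loci)), function(i) {
    s <- substr(seqs[[loci$scaffold_id[i]]], loci$start[i] + 1L, loci$end[i])
    if (loci$strand[i] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, loci$name)
}

#' Count insertion sites
#'
#' @param loci Locus `data.frame`.
#' @return A list with `total` and `per_scaffold` (a `data.frame` sorted
#'   by scaffold id).
#' @export
count_sites <- function(loci) {
  if (nrow(loci) == 0L)
    return(list(total = 0L,
                per_scaffold = data.frame(scaffold_id = character(0),
                                          n_sites = integer(0),
                                          stringsAsFactors = FALSE)))
  tab <- table(loci$scaffold_id)
  list(total = nrow(loci),
       per_scaffold = data.frame(scaffold_id = names(tab),
                                 n_sites = as.integer(tab),
                                 stringsAsFactors = FALSE))
}
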