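#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the standard 12-column blastn tabular output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) and converts it to the internal hit table: 0-based
#' half-open coordinates on the forward strand, with subject rows where
#' `sstart > send` recorded as strand `-`. Percent identity becomes a
#' fraction; the E-value is carried as metadata only and never used in
#' filtering. Ingested rows have no column trace (`cigar` is `NA`).
#'
#' @param path Path to a tab-separated outfmt-6 file.
#' @param assembly The assembly the subject ids refer to
#'   (a [Biostrings::DNAStringSet] or named character vector).
#' @param query Optional query sequence; when given, query coordinates are
#'   validated against its length.
#' @return A hit `data.frame` (see [search_numts()] for the columns).
#' @export
read_blast_tab <- function(path, assembly, query = NULL) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lens <- scaffold_lengths(assembly)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               col.names = cols, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("cannot parse '", path, "' as 12-column outfmt 6: ",
           conditionMessage(e))
    })
  if (is.null(tab) || nrow(tab) == 0L) return(empty_hits())

  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (!r$sseqid %in% names(lens))
      stop("row ", i, ": subject id '", r$sseqid, "' not in assembly")
    if (r$sstart < 1 || r$send < 1 || max(r$sstart, r$send) > lens[[r$sseqid]])
      stop("row ", i, ": subject coordinates [", r$sstart, ",", r$send,
           "] exceed scaffold '", r$sseqid, "' length ", lens[[r$sseqid]])
    if (r$qstart < 1 || r$qend < r$qstart)
      stop("row ", i, ": invalid query coordinates")
    if (!is.null(query) && r$qend > nchar(as_query_chr(query)))
      stop("row ", i, ": query coordinates exceed query length")
  }

  minus <- tab$sstart > tab$send
  ss <- ifelse(minus, tab$send, tab$sstart) - 1L   # 1-based incl -> 0-based half-open
  se <- ifelse(minus, tab$sstart, tab$send)
  data.frame(
    query_id = tab$qseqid,
    scaffold_id = tab$sseqid,
    qs = tab$qstart - 1L,
    qe = tab$qend,
    ss = as.integer(ss),
    se = as.integer(se),
    strand = ifelse(minus, "-", "+"),
    aln_len = as.integer(tab$length),
    identity = tab$pident / 100,
    score = tab$bitscore,
    matches = as.integer(round(tab$pident / 100 * tab$length)),
    gaps = NA_integer_,
    cigar = NA_character_,
    evalue = tab$evalue,
    stringsAsFactors = FALSE
  )
}

#' Write hits in the outfmt-6 dialect
#'
#' Inverse of [read_blast_tab()] for the fields the format carries:
#' coordinates become 1-based inclusive, minus-strand hits are encoded by
#' swapped subject coordinates, and identity becomes percent identity.
#' The raw alignment score is written in the bitscore column and the
#' E-value column is `0` unless the hit carries one.
#'
#' @param hits A hit `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_blast_tab <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gapcols <- ifelse(is.na(hits$gaps), 0L, hits$gaps)
  mism <- hits$aln_len - hits$matches - gapcols
  gapopen <- vapply(hits$cigar, function(cg) {
    if (is.na(cg)) return(0L)
    ops <- expand_cigar(cg)
    sum(diff(c(FALSE, ops != "M")) == 1L)
  }, integer(1), USE.NAMES = FALSE)
  sstart <- ifelse(hits$strand == "+", hits$ss + 1L, hits$se)
  send <- ifelse(hits$strand == "+", hits$se, hits$ss + 1L)
  ev <- if ("evalue" %in% names(hits)) ifelse(is.na(hits$evalue), 0, hits$evalue) else 0
  out <- data.frame(hits$query_id, hits$scaffold_id,
                    sprintf("%.3f", 100 * hits$identity),
                    hits$aln_len, mism, gapopen,
                    hits$qs + 1L, hits$qe, sstart, send,
                    ev, hits$score)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# The canonical empty hit table.
empty_hits <- function() {
  data.frame(query_id = character(0), scaffold_id = character(0),
             qs = integer(0), qe = integer(0), ss = integer(0),
             se = integer(0), strand = character(0), aln_len = integer(0),
             identity = numeric(0), score = numeric(0), matches = integer(0),
             gaps = integer(0), cigar = character(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# Validate internal hit-table invariants against an assembly (and query).
validate_hits <- function(hits, assembly, query = NULL) {
  if (nrow(hits) == 0L) return(invisible(TRUE))
  lens <- scaffold_lengths(assembly)
  bad <- !hits$scaffold_id %in% names(lens)
  if (any(bad))
    stop("hit(s) reference unknown scaffold(s): ",
         paste(unique(hits$scaffold_id[bad]), collapse = ", "))
  stopifnot(all(hits$ss < hits$se),
            all(hits$se <= lens[hits$scaffold_id]),
            all(hits$qs < hits$qe),
            all(hits$aln_len >= pmax(hits$qe - hits$qs, hits$se - hits$ss)))
  if (!is.null(query))
    stopifnot(all(hits$qe <= nchar(as_query_chr(query))))
  invisible(TRUE)
}
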