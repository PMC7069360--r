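#' @useDynLib numtscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483587
}

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T, maps any other residue (including N) to N, and
#' reverses the sequence.
#'
#' @param x A single character string over the DNA alphabet.
#' @return A character string of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(gsub("[^ACGT]", "N", toupper(x)), "")[[1]]),
               collapse = ""))
}

# Coerce a DNAStringSet / DNAString / named character vector to a named
# uppercase character vector over {A,C,G,T,N}.
as_dna_chr <- function(x) {
  if (is(x, "XStringSet")) {
    out <- setNames(as.character(x), names(x))
  } else if (is(x, "XString")) {
    out <- setNames(as.character(x), "seq")
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("cannot interpret object of class ", class(x)[1], " as DNA sequences")
  }
  out <- toupper(out)
  out <- chartr("U", "T", out)
  gsub("[^ACGT]", "N", out)
}

# Single query sequence as a character scalar (plus its id).
as_query_chr <- function(query) {
  q <- as_dna_chr(query)
  if (length(q) != 1L) stop("query must contain exactly one sequence")
  q
}

# Uniform integer draw from [a, b] that is safe when a == b
# (sample(x, 1) on a scalar would sample 1..x).
sample_int_range <- function(a, b) {
  if (a == b) return(as.integer(a))
  as.integer(sample(seq.int(a, b), 1L))
}

# Expand a run-length cigar string ("12M1I3M") into a character vector of ops.
expand_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) return(character(0))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  rep(ops, lens)
}
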