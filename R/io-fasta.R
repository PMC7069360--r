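#' Read a FASTA file into a genome assembly or query set
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased, U is converted to T, and any residue outside
#' A/C/G/T/N is replaced by N. CRLF and LF files parse identically.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as_dna_chr(setNames(as.character(raw), ids))
  if (any(!nzchar(seqs))) stop("empty sequence(s) in '", path, "'")
  # guard against wildly non-nucleotide content (e.g. a protein FASTA):
  # after sanitisation such records collapse to mostly N
  n_frac <- vapply(seqs, function(s) {
    mean(strsplit(s, "")[[1]] == "N")
  }, numeric(1))
  if (all(n_frac > 0.9))
    stop("file '", path, "' does not look like nucleotide FASTA ",
         "(>90% non-ACGT residues in every record)")
  Biostrings::DNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs A named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  s <- as_dna_chr(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(s), path, width = width)
  invisible(path)
}

# Scaffold lengths of an assembly as a named integer vector.
scaffold_lengths <- function(assembly) {
  s <- as_dna_chr(assembly)
  setNames(nchar(s), names(s))
}
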