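#' Write loci as BED6
#'
#' Columns are chrom, 0-based half-open start/end, name, score
#' (`round(100 * identity)`, capped at 1000 per the BED spec), strand.
#'
#' @param loci A locus `data.frame` with columns `scaffold_id`, `start`,
#'   `end`, `name`, `identity` (or `score` already on the 0-1000 scale),
#'   `strand`.
#' @param path Output path.
#' @param assembly Optional assembly; when given, intervals are checked
#'   against scaffold bounds.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(loci, path, assembly = NULL) {
  if (nrow(loci) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!is.null(assembly)) {
    lens <- scaffold_lengths(assembly)
    if (any(!loci$scaffold_id %in% names(lens)) ||
        any(loci$end > lens[loci$scaffold_id]) || any(loci$start < 0))
      stop("locus interval outside scaffold bounds")
  }
  score <- if ("identity" %in% names(loci)) {
    pmin(1000L, as.integer(round(100 * loci$identity)))
  } else {
    pmin(1000L, as.integer(round(loci$score)))
  }
  name <- if ("name" %in% names(loci)) loci$name else
    sprintf("locus%d", seq_len(nrow(loci)))
  out <- data.frame(loci$scaffold_id, loci$start, loci$end, name, score,
                    loci$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file (at least 6 columns).
#' @return A `data.frame` with columns `scaffold_id`, `start`, `end`,
#'   `name`, `score`, `strand`; zero rows for an empty file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("'", path, "' is not BED6 (needs >= 6 columns)")
  out <- tab[, 1:6]
  names(out) <- c("scaffold_id", "start", "end", "name", "score", "strand")
  if (any(out$start < 0) || any(out$end <= out$start))
    stop("malformed BED interval(s) in '", path, "'")
  if (any(!out$strand %in% c("+", "-", ".")))
    stop("malformed BED strand field in '", path, "'")
  out
}
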