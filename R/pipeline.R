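#' End-to-end NUMT scan
#'
#' Runs the full detection procedure: seeded search of the query against
#' the assembly (or ingestion of a precomputed blastn tabular file), the
#' three exclusion filters, merging of surviving hits into insertion
#' sites, sequence extraction, and (when at least three sites are found)
#' the reference-anchored JC/NJ tree. Zero hits is a valid outcome, not
#' an error.
#'
#' @param genome Path to the assembly FASTA, or a loaded assembly.
#' @param query Path to the query FASTA (single record), or a loaded
#'   query.
#' @param blast_tab Optional path to a 12-column outfmt-6 file; when
#'   given it replaces the built-in search.
#' @param params A [filter_params()].
#' @param k,scoring,x_drop,score_min Search parameters (see
#'   [search_numts()]).
#' @param min_shared_sites Passed to [jc_distance()] for the tree.
#' @param build_tree Build the NUMT tree when >= 3 sites are found
#'   (default `TRUE`).
#' @param out_dir Optional output directory; when given, writes
#'   `hits.tsv`, `filter_report.tsv`, `numts.bed`, `numts.fasta`,
#'   `numts.nwk` (when a tree was built), and `summary.json`.
#' @return A list of class `numt_scan`: `summary`, `hits`, `report`,
#'   `loci`, `sequences`, `tree` (or `NULL`), `msa` (or `NULL`).
#' @export
run_scan <- function(genome, query, blast_tab = NULL,
                     params = filter_params(), k = 11L,
                     scoring = scoring_scheme(), x_drop = 50L,
                     score_min = 60L, min_shared_sites = 100L,
                     build_tree = TRUE, out_dir = NULL) {
  assembly <- if (is.character(genome) && length(genome) == 1L &&
                  file.exists(genome)) read_fasta(genome) else genome
  qry <- if (is.character(query) && length(query) == 1L &&
             file.exists(query)) read_fasta(query) else query
  q <- as_query_chr(qry)

  hits <- if (is.null(blast_tab)) {
    search_numts(q, assembly, k = k, scoring = scoring, x_drop = x_drop,
                 score_min = score_min)
  } else {
    read_blast_tab(blast_tab, assembly, q)
  }
  validate_hits(hits, assembly, q)

  report <- filter_hits(hits, assembly, params)
  loci <- merge_insertion_sites(report$kept, params)
  seqs <- extract_numt_sequences(assembly, loci)
  counts <- count_sites(loci)

  tree <- NULL; msa <- NULL; dropped <- character(0)
  if (build_tree && nrow(loci) >= 3L) {
    traced <- report$kept
    if (any(is.na(traced$cigar)))
      traced <- align_to_query(seqs, q)  # ingested hits have no trace
    nt <- tryCatch({
      if (any(is.na(traced$cigar))) stop("no traces")
      best <- vapply(loci$members, function(m) {
        mm <- report$kept[m, , drop = FALSE]
        m[order(-mm$score, -mm$aln_len)][1]
      }, numeric(1))
      locus_hits <- report$kept[best, , drop = FALSE]
      m <- induce_reference_msa(locus_hits, assembly, q,
                                labels = loci$name)
      D <- jc_distance(m, min_shared_sites)
      pr <- prune_incomplete(D)
      list(msa = m, tree = if (nrow(pr$d) >= 2L) neighbor_joining(pr$d)
           else NULL, dropped = pr$dropped)
    }, error = function(e) NULL)
    if (is.null(nt) && length(seqs) >= 3L) {
      nt <- tryCatch(numt_tree(seqs, q, min_shared_sites), error = function(e) NULL)
    }
    if (!is.null(nt)) {
      tree <- nt$tree; msa <- nt$msa; dropped <- nt$dropped
    }
  }

  summary <- list(
    tool = paste0("numtscan ", as.character(utils::packageVersion("numtscan"))),
    query_id = names(q),
    query_length = nchar(q),
    n_scaffolds = length(as_dna_chr(assembly)),
    params = list(min_len = params$min_len,
                  max_span_frac = params$max_span_frac,
                  edge_tol = params$edge_tol,
                  merge_gap = params$merge_gap,
                  k = k, x_drop = x_drop, score_min = score_min,
                  scoring = unclass(scoring)),
    hits_input = unname(report$tallies["input"]),
    hits_kept = unname(report$tallies["kept"]),
    hits_removed = unname(report$tallies["removed"]),
    removed_by = list(
      min_length = unname(report$tallies["min_length"]),
      scaffold_span = unname(report$tallies["scaffold_span"]),
      edge = unname(report$tallies["edge"])),
    insertion_sites = counts$total,
    per_scaffold = counts$per_scaffold,
    tree_built = !is.null(tree),
    tree_dropped_labels = dropped)

  res <- structure(list(summary = summary, hits = hits, report = report,
                        loci = loci, sequences = seqs, tree = tree,
                        msa = msa), class = "numt_scan")
  if (!is.null(out_dir)) write_scan_outputs(res, assembly, out_dir)
  res
}

# Write the standard artifact set for a scan result.
write_scan_outputs <- function(res, assembly, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- res$hits
  write.table(hits[, setdiff(names(hits), character(0))],
              file.path(out_dir, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  rec <- res$report$records
  write.table(rec, file.path(out_dir, "filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  loci_flat <- res$loci[, setdiff(names(res$loci), "members")]
  write_bed(loci_flat, file.path(out_dir, "numts.bed"), assembly)
  if (length(res$sequences) > 0L)
    write_fasta(res$sequences, file.path(out_dir, "numts.fasta"))
  else
    file.create(file.path(out_dir, "numts.fasta"))
  if (!is.null(res$tree))
    write_newick(res$tree, file.path(out_dir, "numts.nwk"))
  s <- res$summary
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Simulate a ground-truthed assembly and write its artifacts
#'
#' Runs [plant_numts()] and writes the assembly FASTA, the truth table as
#' BED6 plus an extended TSV (divergence, placement class, query
#' fragment), and a YAML echo of the configuration.
#'
#' @param query Query sequence (or path to a FASTA).
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The [plant_numts()] result, invisibly, with `paths` added.
#' @export
run_simulate <- function(query, config = sim_config(), out_dir) {
  qry <- if (is.character(query) && length(query) == 1L &&
             file.exists(query)) read_fasta(query) else query
  sim <- plant_numts(qry, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    assembly = file.path(out_dir, "assembly.fasta"),
    truth_bed = file.path(out_dir, "truth.bed"),
    truth_tsv = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "sim_config.yaml"))
  write_fasta(sim$assembly, paths$assembly)
  bed <- data.frame(scaffold_id = sim$truth$scaffold_id,
                    start = sim$truth$start, end = sim$truth$end,
                    name = sim$truth$name,
                    score = round(100 * (1 - sim$truth$divergence)),
                    strand = sim$truth$strand)
  write_bed(bed, paths$truth_bed, sim$assembly)
  write.table(sim$truth, paths$truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- unclass(config)
  cfg$insertions <- lapply(seq_len(nrow(config$insertions)), function(i)
    as.list(config$insertions[i, ]))
  yaml::write_yaml(cfg, paths$config)
  sim$paths <- paths
  invisible(sim)
}

#' Score predictions against a planted truth table
#'
#' A predicted locus is a true positive iff it reciprocally overlaps a
#' truth interval by at least `min_reciprocal` (each interval covers at
#' least that fraction of the other). Recall is computed over
#' `expected_detectable` truth rows only; precision over all predictions
#' (a prediction matching any truth interval, detectable or not, is not
#' a false positive). With zero predictions precision is reported as
#' `NA`.
#'
#' @param predicted Locus `data.frame` (or path to a BED6 file).
#' @param truth Truth `data.frame` from [plant_numts()] (or path to the
#'   extended truth TSV written by [run_simulate()]).
#' @param min_reciprocal Reciprocal-overlap threshold (default 0.5).
#' @return A list with `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `n_predicted`, `n_detectable`, and `matches` (a `data.frame`).
#' @export
run_evaluate <- function(predicted, truth, min_reciprocal = 0.5) {
  if (is.character(predicted) && length(predicted) == 1L)
    predicted <- read_bed(predicted)
  if (is.character(truth) && length(truth) == 1L) {
    truth <- read.table(truth, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("scaffold_id", "start", "end") %in% names(predicted)),
            all(c("scaffold_id", "start", "end", "expected_detectable")
                %in% names(truth)))
  if (nrow(predicted) > 0L && any(predicted$end <= predicted$start))
    stop("malformed predicted interval(s)")

  overlap_ok <- function(p, t) {
    ov <- max(0, min(p[2], t[2]) - max(p[1], t[1]))
    ov >= min_reciprocal * (p[2] - p[1]) && ov >= min_reciprocal * (t[2] - t[1])
  }
  np <- nrow(predicted)
  pred_match <- rep(NA_integer_, np)
  for (i in seq_len(np)) {
    cand <- which(truth$scaffold_id == predicted$scaffold_id[i])
    for (j in cand) {
      if (overlap_ok(c(predicted$start[i], predicted$end[i]),
                     c(truth$start[j], truth$end[j]))) {
        pred_match[i] <- j
        break
      }
    }
  }
  det <- which(truth$expected_detectable)
  det_hit <- vapply(det, function(j) any(pred_match == j, na.rm = TRUE),
                    logical(1))
  tp <- sum(!is.na(pred_match))
  fp <- sum(is.na(pred_match))
  fn <- sum(!det_hit)
  list(precision = if (np == 0L) NA_real_ else tp / np,
       recall = if (length(det) == 0L) NA_real_ else sum(det_hit) / length(det),
       tp = tp, fp = fp, fn = fn,
       n_predicted = np, n_detectable = length(det),
       matches = data.frame(
         predicted = seq_len(np),
         truth = pred_match,
         truth_name = ifelse(is.na(pred_match), NA_character_,
                             truth$name[pred_match])))
}
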