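#' Random background DNA
#'
#' I.i.d. residues with the requested GC content
#' (P(G) = P(C) = gc/2, P(A) = P(T) = (1-gc)/2).
#'
#' @param length Number of residues (>= 1).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Optional integer seed; when given the call is reproducible
#'   and leaves the caller's RNG state untouched.
#' @return A character string.
#' @export
generate_background <- function(length, gc = 0.4, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc <= 0 || gc >= 1) stop("gc must be in the open interval (0, 1)")
  gen <- function() {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthetic cox1-like query sequence
#'
#' A random AT-rich sequence standing in for a mitochondrial cox1 gene.
#' The default length (1534 bp) and GC content (0.38) are typical of
#' decapod cox1.
#'
#' @param length Query length in bp.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return A named character vector of length 1 (`cox1_synthetic`).
#' @export
random_query <- function(length = 1534L, gc = 0.38, seed = 1L) {
  setNames(generate_background(length, gc, seed), "cox1_synthetic")
}

#' Mutate a DNA fragment (NUMT decay model)
#'
#' Each site is substituted with probability `divergence` to a uniformly
#' chosen different base (a Jukes-Cantor-like uniform spectrum, matching
#' the JC distance used downstream). Indel events occur at rate
#' `indel_rate` per site; each event is an insertion or deletion with
#' equal probability and geometric length 1-3.
#'
#' @param fragment Non-empty DNA string.
#' @param divergence Per-site substitution probability in `[0, 0.75)`
#'   (beyond 0.75 the JC distance is unidentifiable).
#' @param indel_rate Per-site indel event probability.
#' @param seed Optional integer seed.
#' @return A list with `seq` (mutated string), `n_sub`, `n_ins`, `n_del`
#'   (realized event counts).
#' @export
mutate_fragment <- function(fragment, divergence = 0, indel_rate = 0,
                            seed = NULL) {
  if (!nzchar(fragment)) stop("fragment must be non-empty")
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must be in [0, 0.75)")
  if (indel_rate < 0 || indel_rate >= 1) stop("indel_rate must be in [0, 1)")
  run <- function() {
    bases <- strsplit(toupper(fragment), "")[[1]]
    L <- length(bases)
    n_sub <- 0L
    if (divergence > 0) {
      sub_at <- which(stats::runif(L) < divergence)
      n_sub <- length(sub_at)
      for (i in sub_at) {
        bases[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                   bases[i]), 1L)
      }
    }
    n_ins <- 0L; n_del <- 0L
    if (indel_rate > 0) {
      ev_at <- which(stats::runif(L) < indel_rate)
      # apply right-to-left so earlier positions stay valid
      for (i in rev(ev_at)) {
        len <- min(3L, 1L + stats::rgeom(1L, 0.5))
        if (stats::runif(1) < 0.5) {
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          bases <- append(bases, ins, after = i)
          n_ins <- n_ins + 1L
        } else {
          drop <- i:min(length(bases), i + len - 1L)
          bases <- bases[-drop]
          n_del <- n_del + 1L
        }
      }
    }
    list(seq = paste(bases, collapse = ""), n_sub = n_sub,
         n_ins = n_ins, n_del = n_del)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Specify one class of planted insertions
#'
#' @param placement_class One of `interior`, `edge_start`, `edge_end`,
#'   `contamination`.
#' @param n Number of insertions of this class.
#' @param frag_len_range Length range (bp) of the planted query fragment.
#' @param divergence Substitution fraction for [mutate_fragment()].
#' @param indel_rate Indel rate for [mutate_fragment()].
#' @param strand `"+"`, `"-"`, or `"random"`.
#' @return A one-row `data.frame`.
#' @export
insertion_spec <- function(placement_class = c("interior", "edge_start",
                                               "edge_end", "contamination"),
                           n = 1L, frag_len_range = c(150L, 800L),
                           divergence = 0.05, indel_rate = 0.002,
                           strand = "random") {
  placement_class <- match.arg(placement_class)
  stopifnot(n >= 1, length(frag_len_range) == 2,
            frag_len_range[1] <= frag_len_range[2],
            strand %in% c("+", "-", "random"))
  data.frame(placement_class = placement_class, n = as.integer(n),
             frag_min = as.integer(frag_len_range[1]),
             frag_max = as.integer(frag_len_range[2]),
             divergence = divergence, indel_rate = indel_rate,
             strand = strand, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_scaffolds Number of NUMT-free-by-default background scaffolds.
#' @param scaffold_length_range Length range (bp) of background scaffolds.
#' @param gc Background GC fraction.
#' @param insertions A `data.frame` of [insertion_spec()] rows
#'   (rbind them together).
#' @param seed Integer master seed; a fixed seed gives byte-identical
#'   assemblies and truth tables.
#' @param detect_min_len Minimum alignment length the downstream filter
#'   keeps; used to precompute `expected_detectable`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 10L,
                       scaffold_length_range = c(20000L, 60000L),
                       gc = 0.4,
                       insertions = insertion_spec(),
                       seed = 1L,
                       detect_min_len = 100L) {
  stopifnot(n_scaffolds >= 1, gc > 0, gc < 1,
            length(scaffold_length_range) == 2,
            scaffold_length_range[1] <= scaffold_length_range[2],
            all(insertions$divergence >= 0), all(insertions$divergence < 1),
            all(insertions$indel_rate >= 0), all(insertions$indel_rate < 1))
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length_range = as.integer(scaffold_length_range),
                 gc = gc, insertions = insertions, seed = as.integer(seed),
                 detect_min_len = as.integer(detect_min_len)),
            class = "sim_config")
}

#' Plant ground-truthed NUMTs in a synthetic assembly
#'
#' Generates background scaffolds, mutates query sub-fragments with
#' [mutate_fragment()] (reverse-complementing minus-strand plants), and
#' splices them in according to their placement class:
#' * `interior` plants sit well inside a background scaffold, pairwise
#'   separated by at least 3 kb;
#' * `edge_start` / `edge_end` plants abut a scaffold end (their own
#'   dedicated scaffold);
#' * `contamination` plants get a dedicated scaffold of which they make up
#'   at least 95% (emulating an unremoved mitochondrial scaffold).
#'
#' `expected_detectable` is `TRUE` only for interior plants whose planted
#' length is at least `detect_min_len` — the same rule the downstream
#' filters apply — so recall can be scored over detectable plants only.
#'
#' @param query Query sequence (named character or
#'   [Biostrings::DNAStringSet] of length 1).
#' @param config A [sim_config()].
#' @return A list with `assembly` ([Biostrings::DNAStringSet]), `truth`
#'   (`data.frame`: `name`, `scaffold_id`, `start`, `end`, `strand`,
#'   `q_start`, `q_end`, `divergence`, `indel_rate`, `placement_class`,
#'   `expected_detectable`), and `config`.
#' @export
plant_numts <- function(query, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  q <- as_query_chr(query)
  Lq <- nchar(q)
  ins <- config$insertions
  if (any(ins$frag_max > Lq))
    stop("insertion fragment length exceeds query length")

  with_seed(config$seed, {
    lens <- config$scaffold_length_range[1] +
      sample.int(config$scaffold_length_range[2] -
                 config$scaffold_length_range[1] + 1L,
                 config$n_scaffolds, replace = TRUE) - 1L
    scaffolds <- vapply(lens, function(L)
      generate_background(L, config$gc), character(1))
    names(scaffolds) <- sprintf("scaffold%03d", seq_along(scaffolds))

    # expand the per-class spec into one row per insertion
    plan <- ins[rep(seq_len(nrow(ins)), ins$n), , drop = FALSE]
    rownames(plan) <- NULL
    truth <- list()
    extra <- character(0)          # dedicated edge/contamination scaffolds
    interior_by_scaf <- vector("list", length(scaffolds))

    make_fragment <- function(row) {
      Lf <- sample_int_range(row$frag_min, row$frag_max)
      qs <- sample.int(Lq - Lf + 1L, 1L) - 1L
      frag <- substr(q, qs + 1L, qs + Lf)
      mut <- mutate_fragment(frag, row$divergence, row$indel_rate)
      strand <- if (row$strand == "random")
        sample(c("+", "-"), 1L) else row$strand
      planted <- if (strand == "-") revcomp(mut$seq) else mut$seq
      list(planted = planted, qs = qs, qe = qs + Lf, strand = strand)
    }

    idx <- 0L
    for (r in seq_len(nrow(plan))) {
      row <- plan[r, ]
      f <- make_fragment(row)
      Lp <- nchar(f$planted)
      idx <- idx + 1L
      name <- sprintf("plant%03d", idx)
      cls <- row$placement_class

      if (cls == "interior") {
        # round-robin over background scaffolds with >= 3 kb separation
        placed <- FALSE
        ord <- order(vapply(interior_by_scaf, length, integer(1)))
        for (si in ord) {
          L <- lens[si]
          if (Lp > 0.8 * L) next
          lo <- 1000L; hi <- L - 1000L - 0L
          occupied <- interior_by_scaf[[si]]
          for (try in seq_len(50L)) {
            pos <- sample_int_range(lo, hi)
            ok <- all(vapply(occupied, function(iv)
              pos > iv[2] + 3000L || pos < iv[1] - 3000L, logical(1)))
            if (ok) {
              interior_by_scaf[[si]] <- c(occupied, list(c(pos, pos)))
              truth[[name]] <- data.frame(
                name = name, scaffold_id = names(scaffolds)[si],
                start = pos, end = pos, strand = f$strand,
                q_start = f$qs, q_end = f$qe,
                divergence = row$divergence, indel_rate = row$indel_rate,
                placement_class = cls, planted_len = Lp,
                stringsAsFactors = FALSE)
              attr(truth[[name]], "planted_seq") <- f$planted
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (!placed) stop("could not place interior insertion ", name,
                          " without overlap; enlarge scaffolds")
      } else if (cls %in% c("edge_start", "edge_end")) {
        L <- sample_int_range(config$scaffold_length_range[1],
                              config$scaffold_length_range[2])
        bg <- generate_background(L, config$gc)
        sid <- sprintf("scaffold_edge%03d", idx)
        if (cls == "edge_start") {
          extra[sid] <- paste0(f$planted, bg)
          iv <- c(0L, Lp)
        } else {
          extra[sid] <- paste0(bg, f$planted)
          iv <- c(L, L + Lp)
        }
        truth[[name]] <- data.frame(
          name = name, scaffold_id = sid, start = iv[1], end = iv[2],
          strand = f$strand, q_start = f$qs, q_end = f$qe,
          divergence = row$divergence, indel_rate = row$indel_rate,
          placement_class = cls, planted_len = Lp,
          stringsAsFactors = FALSE)
      } else {                       # contamination
        # planted span ~98% of its scaffold (>= the 95% the filter targets)
        pad_total <- max(2L, round(Lp * 0.02 / 0.98))
        pad1 <- pad_total %/% 2L; pad2 <- pad_total - pad1
        sid <- sprintf("scaffold_mito%03d", idx)
        extra[sid] <- paste0(generate_background(max(1L, pad1), config$gc),
                             f$planted,
                             generate_background(max(1L, pad2), config$gc))
        s0 <- max(1L, pad1)
        truth[[name]] <- data.frame(
          name = name, scaffold_id = sid, start = s0, end = s0 + Lp,
          strand = f$strand, q_start = f$qs, q_end = f$qe,
          divergence = row$divergence, indel_rate = row$indel_rate,
          placement_class = cls, planted_len = Lp,
          stringsAsFactors = FALSE)
      }
    }

    # splice interior plants (they were recorded as zero-width anchors)
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- NULL
    planted_seqs <- lapply(truth, attr, "planted_seq")
    for (si in seq_along(scaffolds)) {
      rows <- which(truth_df$placement_class == "interior" &
                    truth_df$scaffold_id == names(scaffolds)[si])
      if (length(rows) == 0L) next
      rows <- rows[order(truth_df$start[rows])]
      seqin <- scaffolds[[si]]
      out <- character(0)
      prev <- 0L; shift <- 0L
      for (ri in rows) {
        pos <- truth_df$start[ri]
        frag <- planted_seqs[[truth_df$name[ri]]]
        out <- c(out, substr(seqin, prev + 1L, pos))
        truth_df$start[ri] <- pos + shift
        truth_df$end[ri] <- pos + shift + nchar(frag)
        out <- c(out, frag)
        shift <- shift + nchar(frag)
        prev <- pos
      }
      out <- c(out, substr(seqin, prev + 1L, nchar(seqin)))
      scaffolds[[si]] <- paste(out, collapse = "")
    }

    all_seqs <- c(scaffolds, extra)
    truth_df$expected_detectable <-
      truth_df$placement_class == "interior" &
      truth_df$planted_len >= config$detect_min_len
    truth_df <- truth_df[order(truth_df$scaffold_id, truth_df$start), ]
    rownames(truth_df) <- NULL

    lens_all <- nchar(all_seqs)
    stopifnot(all(truth_df$end <= lens_all[truth_df$scaffold_id]))
    span_frac <- (truth_df$end - truth_df$start) /
      lens_all[truth_df$scaffold_id]
    stopifnot(all(span_frac[truth_df$placement_class == "contamination"]
                  >= 0.95))

    list(assembly = Biostrings::DNAStringSet(all_seqs),
         truth = truth_df, config = config)
  })
}

#' Simulate NUMT sets from several species
#'
#' For each species a species-ancestor copy of the query is mutated at
#' `interspecies_divergence`; each of that species' NUMTs is then an
#' independent copy of the ancestor mutated at `intraspecies_divergence`.
#' Under this two-level model NUMTs of one species are star-shaped around
#' their ancestor, so each species should come out monophyletic in a
#' distance tree.
#'
#' @param query Query sequence.
#' @param n_species Number of species.
#' @param per_species_insertions NUMTs per species.
#' @param interspecies_divergence Ancestor divergence from the query
#'   (must exceed `intraspecies_divergence`).
#' @param intraspecies_divergence Per-NUMT divergence from its ancestor.
#' @param indel_rate Indel rate for both mutation levels.
#' @param seed Integer seed.
#' @return A list with `seqs` (named character vector, labels
#'   `sp<i>_numt<j>`) and `species` (named character vector mapping label
#'   to species id).
#' @export
plant_multispecies <- function(query, n_species = 3L,
                               per_species_insertions = 5L,
                               interspecies_divergence = 0.15,
                               intraspecies_divergence = 0.02,
                               indel_rate = 0.002, seed = 1L) {
  if (interspecies_divergence <= intraspecies_divergence)
    stop("interspecies divergence must exceed intraspecies divergence")
  q <- as_query_chr(query)
  with_seed(seed, {
    seqs <- character(0); species <- character(0)
    for (s in seq_len(n_species)) {
      anc <- mutate_fragment(q, interspecies_divergence, indel_rate)$seq
      for (j in seq_len(per_species_insertions)) {
        lab <- sprintf("sp%d_numt%d", s, j)
        seqs[lab] <- mutate_fragment(anc, intraspecies_divergence,
                                     indel_rate)$seq
        species[lab] <- sprintf("sp%d", s)
      }
    }
    list(seqs = seqs, species = species)
  })
}
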