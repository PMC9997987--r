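# Specificity screening: every bait variant is searched against every
# converted genome variant with a deterministic seed-and-extend local
# aligner, and the per-candidate maximum hit count over all (variant x
# genome variant) pairs feeds the design filter. This stands in for the
# conventional BLAST screen against unmodified, all-C>T and all-G>A versions
# of each reference genome, with a fully specified, reproducible hit
# criterion instead of vendor defaults.

#' Hit criterion for the specificity screen
#'
#' Defines what counts as one cross-hybridization hit: a cluster of local
#' alignments with score at least `min_score` under unit match/mismatch/gap
#' scoring. Overlapping alignments on the genome are merged and counted once;
#' per-(variant, genome) counts are capped at `max_tabulated`, mirroring
#' screens that tabulate only the top hits.
#'
#' @param match_score score for a match (> 0).
#' @param mismatch_score score for a mismatch (< 0).
#' @param gap_score score per gap position (< 0).
#' @param min_score minimum qualifying local alignment score.
#' @param max_tabulated cap on the tabulated hit count.
#' @param k exact k-mer seed length of the search (4-32).
#' @param min_seeds minimum number of exact `k`-mer seed matches a genome
#'   neighbourhood must contain before gapped extension is attempted (the
#'   classic two-hit seeding rule at the default of 2). The screen therefore
#'   assumes every qualifying alignment contains at least `min_seeds` exact
#'   `k`-mer matches -- true for the near-identical cross-hybridization
#'   signals it targets. Set `min_seeds = 1` for plain single-hit seeding.
#' @return an object of class `hit_criterion`.
#' @export
hit_criterion <- function(match_score = 1L, mismatch_score = -1L,
                          gap_score = -2L, min_score = 40L,
                          max_tabulated = 500L, k = 12L, min_seeds = 2L) {
  stopifnot(match_score > 0, mismatch_score < 0, gap_score < 0,
            min_score >= 1, max_tabulated >= 1, k >= 4, k <= 32,
            min_seeds >= 1)
  structure(list(match_score = as.integer(match_score),
                 mismatch_score = as.integer(mismatch_score),
                 gap_score = as.integer(gap_score),
                 min_score = as.integer(min_score),
                 max_tabulated = as.integer(max_tabulated),
                 k = as.integer(k),
                 min_seeds = as.integer(min_seeds)),
            class = "hit_criterion")
}

#' @export
print.hit_criterion <- function(x, ...) {
  cat(sprintf(
    "hit criterion: match %+d / mismatch %+d / gap %+d; min score %d; seed k=%d (>=%d per cluster); cap %d\n",
    x$match_score, x$mismatch_score, x$gap_score, x$min_score, x$k,
    x$min_seeds, x$max_tabulated))
  invisible(x)
}

#' Build the conversion-variant set of one or more genomes
#'
#' Each genome yields exactly three variants: unmodified, sense-unmethylated
#' (all C converted to T) and antisense-unmethylated (all G converted to A).
#' Four reference genomes therefore give the canonical 12-variant screening
#' set.
#'
#' @param genomes a single genome (named character vector) or a named list of
#'   genomes, one per reference species/assembly.
#' @return list of `genome_variant` objects, each
#'   `list(genome_id, mode, sequences)`.
#' @export
build_genome_variant_set <- function(genomes) {
  if (is.character(genomes)) genomes <- list(genome = genomes)
  stopifnot(is.list(genomes), length(genomes) >= 1)
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("genomes must be a named list", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate genome id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  out <- list()
  for (id in ids) {
    for (mode in CONVERSION_MODES) {
      out[[length(out) + 1L]] <- structure(
        list(genome_id = id, mode = mode,
             sequences = convert_genome(genomes[[id]], mode)),
        class = "genome_variant")
    }
  }
  out
}

#' Count cross-hybridization hits of one sequence against a genome variant
#'
#' Searches both orientations of `variant_seq` (as-is and
#' reverse-complemented), collects all local alignments with score at least
#' `criterion$min_score`, merges alignments whose genome intervals overlap
#' into single occurrences, and returns the number of merged clusters summed
#' over chromosomes, capped at `criterion$max_tabulated`. Case is ignored
#' (soft-masked sequence still aligns); `N` never matches.
#'
#' @param variant_seq a single bait/variant sequence.
#' @param genome_variant a `genome_variant` object from
#'   [build_genome_variant_set()], or a plain named character vector of
#'   chromosome sequences.
#' @param criterion a [hit_criterion()].
#' @return integer hit-cluster count.
#' @export
count_hits <- function(variant_seq, genome_variant,
                       criterion = hit_criterion()) {
  stopifnot(is.character(variant_seq), length(variant_seq) == 1,
            nchar(variant_seq) >= 1, inherits(criterion, "hit_criterion"))
  seqs <- if (inherits(genome_variant, "genome_variant")) {
    genome_variant$sequences
  } else {
    genome_variant
  }
  total <- 0L
  for (chromseq in seqs) {
    total <- total + .screen_hits_cpp(
      toupper(variant_seq), toupper(chromseq), criterion$match_score,
      criterion$mismatch_score, criterion$gap_score, criterion$min_score,
      criterion$k, criterion$min_seeds)
  }
  min(total, criterion$max_tabulated)
}

#' Screen bait candidates against a genome-variant set
#'
#' Counts hit clusters for every (bait variant x genome variant) pair and
#' summarises the per-candidate maximum -- the statistic the composition
#' filter bounds ("max hits across all genome variants").
#'
#' @param candidates candidate data.frame from [tile_candidates()].
#' @param variants variant data.frame (rows `candidate_id`, `state`,
#'   `sequence`), e.g. rows of [enumerate_variants()] over all candidates.
#' @param genome_variants list of `genome_variant` objects from
#'   [build_genome_variant_set()]; all three modes must be present for every
#'   genome id.
#' @param criterion a [hit_criterion()].
#' @return `list(hits =, summary =)`: `hits` is a long data.frame
#'   (`candidate_id`, `state`, `genome_id`, `mode`, `hits`) with one row per
#'   counting cell; `summary` has one row per candidate (`candidate_id`,
#'   `max_hits`).
#' @export
screen_candidates <- function(candidates, variants, genome_variants,
                              criterion = hit_criterion()) {
  if (!length(genome_variants)) {
    stop("configuration error: empty genome variant list", call. = FALSE)
  }
  stopifnot(all(vapply(genome_variants, inherits, logical(1),
                       "genome_variant")))
  gid <- vapply(genome_variants, `[[`, character(1), "genome_id")
  mode <- vapply(genome_variants, `[[`, character(1), "mode")
  for (g in unique(gid)) {
    missing <- setdiff(CONVERSION_MODES, mode[gid == g])
    if (length(missing)) {
      stop(sprintf("configuration error: genome '%s' is missing variant mode(s) %s",
                   g, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  unknown <- setdiff(variants$candidate_id, candidates$id)
  if (length(unknown)) {
    stop("variants reference unknown candidate(s): ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  baits <- toupper(variants$sequence)
  blocks <- vector("list", length(genome_variants))
  for (v in seq_along(genome_variants)) {
    gv <- genome_variants[[v]]
    counts <- integer(length(baits))
    for (chromseq in gv$sequences) {
      counts <- counts + .screen_hits_cpp(
        baits, toupper(chromseq), criterion$match_score,
        criterion$mismatch_score, criterion$gap_score, criterion$min_score,
        criterion$k, criterion$min_seeds)
    }
    blocks[[v]] <- data.frame(candidate_id = variants$candidate_id,
                              state = variants$state,
                              genome_id = gv$genome_id, mode = gv$mode,
                              hits = pmin(counts, criterion$max_tabulated),
                              stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, blocks)
  rownames(hits) <- NULL
  mx <- tapply(hits$hits, hits$candidate_id, max)
  summary <- data.frame(candidate_id = candidates$id,
                        max_hits = as.integer(mx[candidates$id]),
                        stringsAsFactors = FALSE)
  list(hits = hits, summary = summary)
}
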