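# Bait tiling, per-candidate methylation-state permutations, and composition
# filters. Conventions follow common capture-design practice: 80 nt baits at
# 2x tiling density (step = half the bait length), nine sequences per
# candidate (the unmodified original plus 4 methylation patterns x 2
# strands), and composition filters of < 25% repeat masking, 10-80% GC and a
# cap on cross-hybridization hits.

#' Extract the sequence of a target region from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param region single-row region data.frame (`chrom`, `start`, `end`,
#'   `name`, `strand`; 0-based half-open).
#' @return the substring `[start, end)`, case preserved; regions on strand
#'   `"-"` are returned reverse-complemented.
#' @export
extract_target_sequence <- function(genome, region) {
  stopifnot(is.character(genome), is.data.frame(region), nrow(region) == 1)
  chrom <- region$chrom
  if (!chrom %in% names(genome)) {
    stop(sprintf("region '%s': unknown chromosome '%s'", region$name, chrom),
         call. = FALSE)
  }
  L <- nchar(genome[[chrom]])
  if (region$start < 0 || region$end > L || region$start >= region$end) {
    stop(sprintf("region '%s': coordinates [%d, %d) out of bounds for %s (length %d)",
                 region$name, region$start, region$end, chrom, L),
         call. = FALSE)
  }
  s <- substr(genome[[chrom]], region$start + 1L, region$end)
  if (identical(region$strand, "-")) revcomp(s) else s
}

#' Tile bait candidates over a target sequence
#'
#' Candidates of length `bait_length` are placed every
#' `bait_length / tiling_density` bases from the target's 5' end, as long as
#' they fit: offsets `0, step, 2*step, ...` with `offset + bait_length <= L`.
#' With `anchor_end = TRUE` one extra candidate flush with the 3' end is
#' added when the last regular candidate does not already end there. GC and
#' mask fractions are computed on the unmodified (pre-conversion) sequence.
#'
#' @param target_seq the region sequence (as from
#'   [extract_target_sequence()]; already reverse-complemented for `-`
#'   regions).
#' @param region the single-row region data.frame the sequence came from.
#' @param bait_length bait length in nt; must be divisible by
#'   `tiling_density`.
#' @param tiling_density tiling density (2 = each interior base covered by
#'   two baits).
#' @param anchor_end add a final candidate flush with the target end.
#' @param n_max maximum number of ambiguous (`N`) bases tolerated per
#'   candidate; candidates exceeding it are dropped before filtering
#'   (synthesizers reject ambiguous bases).
#' @return data.frame with one row per candidate: `id`, `target_name`,
#'   `chrom`, `start` (0-based genomic), `length`, `sequence`,
#'   `mask_fraction`, `gc_fraction`, `n_cpg`. Zero rows (with a warning) if
#'   the target is shorter than `bait_length`.
#' @export
tile_candidates <- function(target_seq, region, bait_length = 80L,
                            tiling_density = 2L, anchor_end = FALSE,
                            n_max = 0L) {
  stopifnot(bait_length >= 1, tiling_density >= 1)
  if (bait_length %% tiling_density != 0) {
    stop("bait_length must be divisible by tiling_density", call. = FALSE)
  }
  empty <- data.frame(id = character(), target_name = character(),
                      chrom = character(), start = integer(),
                      length = integer(), sequence = character(),
                      mask_fraction = numeric(), gc_fraction = numeric(),
                      n_cpg = integer(), stringsAsFactors = FALSE)
  L <- nchar(target_seq)
  if (L < bait_length) {
    warning(sprintf("target '%s' (%d bp) is shorter than the bait length (%d)",
                    region$name, L, bait_length))
    return(empty)
  }
  step <- bait_length %/% tiling_density
  offsets <- seq.int(0L, L - bait_length, by = step)
  if (anchor_end && offsets[length(offsets)] + bait_length < L) {
    offsets <- c(offsets, L - bait_length)
  }
  seqs <- substring(target_seq, offsets + 1L, offsets + bait_length)
  # genomic start of each candidate; tiling walks the extracted frame, so on
  # "-" regions offset o maps back to end - o - bait_length
  gstart <- if (identical(region$strand, "-")) {
    region$end - offsets - bait_length
  } else {
    region$start + offsets
  }
  out <- data.frame(
    id = sprintf("%s_c%03d", region$name, seq_along(offsets)),
    target_name = region$name, chrom = region$chrom,
    start = as.integer(gstart), length = as.integer(bait_length),
    sequence = seqs,
    mask_fraction = vapply(seqs, compute_mask_fraction, numeric(1),
                           USE.NAMES = FALSE),
    gc_fraction = compute_gc(seqs),
    n_cpg = vapply(seqs, function(s) length(enumerate_cpg_sites(s)),
                   integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  n_amb <- nchar(gsub("[^Nn]", "", seqs))
  if (any(n_amb > n_max)) {
    message(sprintf("dropping %d candidate(s) with > %d ambiguous base(s)",
                    sum(n_amb > n_max), n_max))
    out <- out[n_amb <= n_max, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Enumerate the nine conversion-permutation variants of a candidate
#'
#' One unmodified original plus the eight methylation-state/strand
#' permutations: \{all methylated, a random 50% of CpGs methylated, the
#' complementary 50%, unmethylated\} x \{sense, antisense\}. The random split
#' is drawn once per candidate with a seed derived from `(seed, candidate
#' id)`, so designs are reproducible and overlapping candidates get
#' independent splits.
#'
#' @param candidate single-row candidate data.frame (needs `id` and
#'   `sequence`), as produced by [tile_candidates()].
#' @param seed integer design seed.
#' @param dedup collapse identical variant sequences? When `TRUE` the result
#'   additionally carries `multiplicity` and the collapsed `states`.
#' @return data.frame `candidate_id`, `state`, `sequence` with exactly 9 rows
#'   before deduplication. States are `original` and
#'   `<pattern>.<strand>` labels.
#' @export
enumerate_variants <- function(candidate, seed, dedup = FALSE) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1)
  seq <- candidate$sequence
  cpg <- enumerate_cpg_sites(seq)
  split <- make_split_sets(cpg, derive_seed(seed, "split", candidate$id))
  states <- expand.grid(pattern = METHYLATION_PATTERNS, strand = BAIT_STRANDS,
                        stringsAsFactors = FALSE)
  seqs <- mapply(function(p, s) {
    mset <- switch(p, split_A = split$A, split_B = split$B, NULL)
    apply_methylation_state(seq, p, s, mset)
  }, states$pattern, states$strand, USE.NAMES = FALSE)
  out <- data.frame(
    candidate_id = candidate$id,
    state = c("original", paste(states$pattern, states$strand, sep = ".")),
    sequence = c(seq, seqs), stringsAsFactors = FALSE)
  if (dedup) {
    grp <- split(seq_len(nrow(out)), out$sequence)
    first <- sort(vapply(grp, `[`, integer(1), 1))
    dd <- out[first, , drop = FALSE]
    dd$multiplicity <- vapply(dd$sequence,
                              function(s) sum(out$sequence == s), integer(1),
                              USE.NAMES = FALSE)
    dd$states <- vapply(dd$sequence, function(s) {
      paste(out$state[out$sequence == s], collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    rownames(dd) <- NULL
    return(dd)
  }
  out
}

#' GC fraction of sequences
#'
#' @param seq character vector of DNA strings.
#' @return numeric vector: `(G + C) / (non-N bases)`, case-insensitive.
#'   All-`N` (or empty) sequences yield 0 with a warning.
#' @export
compute_gc <- function(seq) {
  gc <- nchar(gsub("[^GgCc]", "", seq))
  den <- nchar(gsub("[Nn]", "", seq))
  if (any(den == 0)) {
    warning("GC content undefined for all-N sequence(s); reported as 0")
  }
  ifelse(den > 0, gc / den, 0)
}

#' Masked fraction of a sequence
#'
#' Repeat annotation reaches the designer as soft-masked (lowercase) or
#' hard-masked (`N`) sequence; both count as masked. Explicit mask intervals,
#' when given, are unioned with the sequence-level signal.
#'
#' @param seq a single DNA string.
#' @param mask_intervals optional `data.frame(start, end)` of additional
#'   masked intervals in local 0-based half-open coordinates within the bait
#'   span.
#' @return fraction of masked positions, in `[0, 1]`.
#' @export
compute_mask_fraction <- function(seq, mask_intervals = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  L <- nchar(seq)
  if (L == 0) return(0)
  if (is.null(mask_intervals)) {
    return(nchar(gsub("[^acgtnN]", "", seq)) / L)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  masked <- ch %in% c("a", "c", "g", "t", "n", "N")
  for (i in seq_len(nrow(mask_intervals))) {
    s <- mask_intervals$start[i]; e <- mask_intervals$end[i]
    if (s < 0 || e > L || s >= e) {
      stop("mask interval outside the bait span", call. = FALSE)
    }
    masked[(s + 1L):e] <- TRUE
  }
  mean(masked)
}

#' Composition-filter bait candidates
#'
#' Retention requires `mask_fraction < max_mask` (strict, so a bait exactly
#' at the mask bound fails), `gc_min <= gc_fraction <= gc_max` (inclusive)
#' and, when a hit table is supplied, `max hits <= max_hits` (inclusive).
#' Without a hit table the hit criterion is undetermined (`NA`) and does not
#' block retention.
#'
#' @param candidates candidate data.frame from [tile_candidates()].
#' @param hit_table optional per-candidate maximum cross-hybridization hits:
#'   either a named integer vector (names = candidate ids) or the `summary`
#'   data.frame from [screen_candidates()].
#' @param max_mask mask-fraction bound (strict `<`).
#' @param gc_min,gc_max inclusive GC bounds.
#' @param max_hits inclusive bound on the per-candidate maximum hit count.
#' @return `list(retained = <candidate rows kept>, report =
#'   data.frame(candidate_id, pass_mask, pass_gc, pass_hits, retained))`.
#' @export
filter_candidates <- function(candidates, hit_table = NULL, max_mask = 0.25,
                              gc_min = 0.10, gc_max = 0.80, max_hits = 10L) {
  stopifnot(max_mask >= 0, max_mask <= 1, gc_min >= 0, gc_max <= 1,
            gc_min <= gc_max, max_hits >= 0)
  pass_mask <- candidates$mask_fraction < max_mask
  pass_gc <- candidates$gc_fraction >= gc_min & candidates$gc_fraction <= gc_max
  if (is.null(hit_table)) {
    pass_hits <- rep(NA, nrow(candidates))
  } else {
    if (is.data.frame(hit_table)) {
      ht <- setNames(hit_table$max_hits, hit_table$candidate_id)
    } else {
      ht <- hit_table
    }
    hits <- unname(ht[candidates$id])
    if (anyNA(hits)) {
      stop("hit_table is missing candidate(s): ",
           paste(head(candidates$id[is.na(hits)], 3), collapse = ", "),
           call. = FALSE)
    }
    pass_hits <- hits <= max_hits
  }
  retained <- pass_mask & pass_gc & (is.na(pass_hits) | pass_hits)
  report <- data.frame(candidate_id = candidates$id, pass_mask = pass_mask,
                       pass_gc = pass_gc, pass_hits = pass_hits,
                       retained = retained, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  kept <- candidates[retained, , drop = FALSE]
  rownames(kept) <- NULL
  list(retained = kept, report = report)
}
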