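# The conversion algebra: everything that maps between native and converted
# (post-EM-seq/bisulfite) sequence space. Conversion chemistry rewrites
# unmethylated C to T on the sequenced strand; on the opposite strand the
# same event reads as G -> A. Methylated CpG cytosines are protected and stay
# C. These three facts generate both the whole-genome "conversion variants"
# used for specificity screening and the per-bait methylation-state
# permutations.

CONVERSION_MODES <- c("unmodified", "sense_unmethylated",
                      "antisense_unmethylated")
METHYLATION_PATTERNS <- c("all_methylated", "split_A", "split_B",
                          "unmethylated")
BAIT_STRANDS <- c("sense", "antisense")

#' Enumerate CpG sites in a sequence
#'
#' @param seq a single DNA string (alphabet `ACGTN`, case-insensitive).
#' @return ascending integer vector of 1-based positions `i` with
#'   `seq[i] == C` and `seq[i+1] == G` (case-insensitive). `N` never matches.
#' @export
#' @examples
#' enumerate_cpg_sites("ACGT")   # 2
#' enumerate_cpg_sites("CGCGN")  # 1 3
enumerate_cpg_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  assert_dna(seq)
  if (!nzchar(seq)) return(integer(0))
  m <- gregexpr("[Cc][Gg]", seq)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Convert a sequence (or genome) to a conversion-space variant
#'
#' `sense_unmethylated` replaces every `C` by `T` (the fully unmethylated
#' sense strand after conversion); `antisense_unmethylated` replaces every
#' `G` by `A` (the sense-strand shadow of a fully converted antisense
#' strand); `unmodified` is the identity. Case is preserved so soft-masking
#' survives; length is always preserved and the transform is idempotent.
#'
#' @param seq character vector of DNA sequences (a genome works as-is).
#' @param mode one of `"unmodified"`, `"sense_unmethylated"`,
#'   `"antisense_unmethylated"`.
#' @return character vector of converted sequences, names preserved.
#' @export
#' @examples
#' convert_genome("ACGT", "sense_unmethylated")     # "ATGT"
#' convert_genome("ACGT", "antisense_unmethylated") # "ACAT"
convert_genome <- function(seq, mode = CONVERSION_MODES) {
  mode <- match.arg(mode)
  stopifnot(is.character(seq))
  switch(mode,
         unmodified = seq,
         sense_unmethylated = chartr("Cc", "Tt", seq),
         antisense_unmethylated = chartr("Gg", "Aa", seq))
}

#' Split CpG positions into two random halves
#'
#' Models the "random 50% of CpGs methylated / the other 50%" bait states:
#' one seeded draw partitions the sites into set A (size `ceiling(n/2)`) and
#' its complement B. The draw is deterministic for a given seed.
#'
#' @param cpg_positions integer vector of distinct CpG positions.
#' @param seed integer seed.
#' @return `list(A =, B =)` of disjoint sorted position vectors with
#'   `union(A, B)` equal to the input.
#' @export
make_split_sets <- function(cpg_positions, seed) {
  stopifnot(!anyDuplicated(cpg_positions))
  n <- length(cpg_positions)
  if (n == 0) return(list(A = integer(0), B = integer(0)))
  na <- ceiling(n / 2)
  idx <- with_seed(as.integer(seed), sample.int(n))
  list(A = sort(cpg_positions[idx[seq_len(na)]]),
       B = sort(cpg_positions[idx[-seq_len(na)]]))
}

#' Apply a methylation state to a bait sequence
#'
#' Produces the sequence a converted library fragment would present for a
#' locus in the given methylation state. On the sense strand, cytosines at
#' methylated CpG positions are protected (stay `C`); every other cytosine --
#' including non-CpG cytosines, whose methylation is negligible in vertebrate
#' genomes -- converts to `T`. Antisense states are emitted in the
#' reverse-complement frame (the literal sequence a synthesizer would
#' receive): the sequence is reverse-complemented, each sense-strand CpG
#' cytosine at 1-based position `p` maps to the antisense CpG cytosine at
#' position `L - p` of the reverse complement, and the sense rule is then
#' applied there.
#'
#' @param seq a single DNA string.
#' @param pattern one of `"all_methylated"`, `"split_A"`, `"split_B"`,
#'   `"unmethylated"`. For `all_methylated`/`unmethylated` the
#'   `methylated_positions` argument is ignored (all/none of the CpG sites).
#' @param strand `"sense"` or `"antisense"`.
#' @param methylated_positions for the split patterns: 1-based sense-strand
#'   positions of the protected CpG cytosines; must be a subset of
#'   [enumerate_cpg_sites()] of `seq`.
#' @return a single DNA string of the same length as `seq`.
#' @export
#' @examples
#' apply_methylation_state("CACGT", "all_methylated", "sense")  # "TACGT"
#' apply_methylation_state("CACGT", "unmethylated", "sense")    # "TATGT"
apply_methylation_state <- function(seq, pattern = METHYLATION_PATTERNS,
                                    strand = BAIT_STRANDS,
                                    methylated_positions = NULL) {
  pattern <- match.arg(pattern)
  strand <- match.arg(strand)
  stopifnot(is.character(seq), length(seq) == 1)
  assert_dna(seq)
  cpg <- enumerate_cpg_sites(seq)
  m <- switch(pattern,
              all_methylated = cpg,
              unmethylated = integer(0),
              split_A = ,
              split_B = {
                if (is.null(methylated_positions)) {
                  stop("split patterns require methylated_positions",
                       call. = FALSE)
                }
                as.integer(methylated_positions)
              })
  if (length(setdiff(m, cpg))) {
    stop(sprintf("methylated position(s) %s are not CpG cytosines of the sequence",
                 paste(setdiff(m, cpg), collapse = ",")), call. = FALSE)
  }
  if (strand == "antisense") {
    L <- nchar(seq)
    return(sense_convert(revcomp(seq), L - m))
  }
  sense_convert(seq, m)
}

# Convert all cytosines to thymine except those at `protect` (1-based),
# preserving case. Workhorse for apply_methylation_state.
sense_convert <- function(seq, protect) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  isC <- ch == "C" | ch == "c"
  conv <- isC
  conv[protect] <- FALSE
  ch[conv & ch == "C"] <- "T"
  ch[conv & ch == "c"] <- "t"
  paste(ch, collapse = "")
}
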