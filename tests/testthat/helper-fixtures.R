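# Seeded fixture generators shared across test files. Fixtures are built in
# code at test time; nothing is read from disk.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small random CpG callset on the given chromosomes.
rand_cov <- function(n, chroms = c("chr1", "chr2"), max_pos = 500L,
                     max_depth = 30L) {
  pos_pool <- expand.grid(chrom = chroms, pos = seq_len(max_pos),
                          stringsAsFactors = FALSE)
  pick <- pos_pool[sample.int(nrow(pos_pool), n), ]
  depth <- sample.int(max_depth, n, replace = TRUE)
  m <- vapply(depth, function(d) sample.int(d + 1L, 1) - 1L, integer(1))
  data.frame(chrom = pick$chrom, pos = pick$pos,
             percent = ifelse(depth > 0, 100 * m / depth, 0),
             count_m = m, count_u = depth - m,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Random non-degenerate region set.
rand_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 500L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos - 20L, n, replace = TRUE) - 1L
  len <- sample(5:60, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + len, max_pos),
             name = sprintf("r%02d", seq_len(n)),
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

region_row <- function(chrom, start, end, name = "r", strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

# Plant a (possibly mutated, possibly converted) copy of a genome locus as a
# bait; mutations are point substitutions to a different base.
plant_bait <- function(genome, at, len, n_mut = 0L) {
  bait <- substr(genome, at, at + len - 1L)
  if (n_mut > 0) {
    ch <- strsplit(bait, "", fixed = TRUE)[[1]]
    pos <- sample.int(len, n_mut)
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    bait <- paste(ch, collapse = "")
  }
  bait
}
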