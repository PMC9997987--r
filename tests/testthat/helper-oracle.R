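# Independent oracles. Everything here is deliberately written without using
# the package's own implementation paths: naive character operations, full
# (unseeded, unbanded) Smith-Waterman scans, and brute-force loops.

# -- conversion oracles -------------------------------------------------------

naive_convert <- function(seq, mode) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (mode == "sense_unmethylated") {
    ch[ch == "C"] <- "T"; ch[ch == "c"] <- "t"
  } else if (mode == "antisense_unmethylated") {
    ch[ch == "G"] <- "A"; ch[ch == "g"] <- "a"
  }
  paste(ch, collapse = "")
}

oracle_revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
           a = "t", c = "g", g = "c", t = "a", n = "n")
  paste(map[ch], collapse = "")
}

# -- exhaustive local-alignment oracle ---------------------------------------

# All (start, end) genome intervals (1-based, closed) of local alignments
# with score >= min_score, full dynamic programme over the whole genome.
# Tie rule for start propagation: diagonal > up (gap in genome) > left
# (gap in bait) -- the same rule the package engine uses.
sw_intervals_oracle <- function(bait, genome, match, mismatch, gap,
                                min_score) {
  b <- strsplit(toupper(bait), "", fixed = TRUE)[[1]]
  g <- strsplit(toupper(genome), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  bv <- b %in% acgt
  gv <- g %in% acgt
  Lb <- length(b)
  starts <- integer(0); ends <- integer(0)
  Hprev <- integer(Lb + 1); Sprev <- integer(Lb + 1)
  for (j in seq_along(g)) {
    Hcur <- integer(Lb + 1); Scur <- integer(Lb + 1)
    for (i in seq_len(Lb)) {
      s <- if (bv[i] && gv[j] && b[i] == g[j]) match else mismatch
      dg <- Hprev[i] + s        # cell (i-1, j-1)
      up <- Hcur[i] + gap       # cell (i-1, j)
      lf <- Hprev[i + 1] + gap  # cell (i, j-1)
      h <- max(0L, dg, up, lf)
      if (h == 0L) next
      st <- if (h == dg) {
        if (Hprev[i] > 0L) Sprev[i] else j
      } else if (h == up) Scur[i] else Sprev[i + 1]
      Hcur[i + 1] <- h
      Scur[i + 1] <- st
      if (h >= min_score) {
        starts <- c(starts, st); ends <- c(ends, j)
      }
    }
    Hprev <- Hcur; Sprev <- Scur
  }
  cbind(starts, ends)
}

oracle_merge_count <- function(iv) {
  if (!nrow(iv)) return(0L)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  n <- 1L
  e <- iv[1, 2]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= e) e <- max(e, iv[r, 2]) else { n <- n + 1L; e <- iv[r, 2] }
  }
  n
}

oracle_count_hits <- function(bait, genome_seqs, criterion) {
  total <- 0L
  for (gs in genome_seqs) {
    iv <- rbind(
      sw_intervals_oracle(bait, gs, criterion$match_score,
                          criterion$mismatch_score, criterion$gap_score,
                          criterion$min_score),
      sw_intervals_oracle(oracle_revcomp(bait), gs, criterion$match_score,
                          criterion$mismatch_score, criterion$gap_score,
                          criterion$min_score))
    total <- total + oracle_merge_count(iv)
  }
  min(total, criterion$max_tabulated)
}

# -- tiling oracle ------------------------------------------------------------

brute_tile_offsets <- function(L, bait_length, density, anchor_end) {
  step <- bait_length %/% density
  offs <- integer(0)
  o <- 0L
  while (o + bait_length <= L) {  # every step-multiple that fits
    offs <- c(offs, o)
    o <- o + step
  }
  if (anchor_end && length(offs) &&
      offs[length(offs)] + bait_length < L) {
    offs <- c(offs, L - bait_length)
  }
  offs
}

# -- brute-force callset operations ------------------------------------------

brute_pos_in_regions <- function(chrom, pos, regions) {
  any(vapply(seq_len(nrow(regions)), function(i) {
    chrom == regions$chrom[i] && pos > regions$start[i] &&
      pos <= regions$end[i]
  }, logical(1)))
}

brute_intersect <- function(records, regions) {
  keep <- vapply(seq_len(nrow(records)), function(r) {
    brute_pos_in_regions(records$chrom[r], records$pos[r], regions)
  }, logical(1))
  records[keep, , drop = FALSE]
}

brute_filter <- function(records, min_depth) {
  keep <- vapply(seq_len(nrow(records)), function(r) {
    records$count_m[r] + records$count_u[r] >= min_depth
  }, logical(1))
  records[keep, , drop = FALSE]
}

brute_region_means <- function(records, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    vals <- c()
    for (r in seq_len(nrow(records))) {
      if (records$chrom[r] == regions$chrom[i] &&
          records$pos[r] > regions$start[i] &&
          records$pos[r] <= regions$end[i]) {
        vals <- c(vals, records$percent[r])
      }
    }
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
}

brute_match <- function(a, b) {
  out <- data.frame(chrom = character(), pos = integer(),
                    percent_a = numeric(), percent_b = numeric())
  for (r in seq_len(nrow(a))) {
    for (s in seq_len(nrow(b))) {
      if (a$chrom[r] == b$chrom[s] && a$pos[r] == b$pos[s]) {
        out <- rbind(out, data.frame(chrom = a$chrom[r], pos = a$pos[r],
                                     percent_a = a$percent[r],
                                     percent_b = b$percent[s]))
      }
    }
  }
  out
}
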