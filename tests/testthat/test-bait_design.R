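test_that("extract_target_sequence honours coordinates and strand", {
  genome <- c(chr1 = "AAACGTTT")
  r <- region_row("chr1", 2L, 6L)
  expect_identical(extract_target_sequence(genome, r), "ACGT")
  r$strand <- "-"
  expect_identical(extract_target_sequence(genome, r), "ACGT")  # palindrome
  # case is preserved
  genome2 <- c(chr1 = "aaACgttt")
  expect_identical(extract_target_sequence(genome2, region_row("chr1", 1L, 5L)),
                   "aACg")
  expect_error(
    extract_target_sequence(genome, region_row("chr1", 5L, 20L, "far")),
    "out of bounds.*far|far.*out of bounds")
  expect_error(
    extract_target_sequence(genome, region_row("chrX", 0L, 4L, "nochrom")),
    "unknown chromosome")
})

test_that("tile_candidates places offsets at step = length/density", {
  set.seed(31)
  r <- region_row("chr1", 1000L, 1200L, "t1")
  tc <- tile_candidates(rand_dna(200), r, 80L, 2L)
  expect_identical(nrow(tc), 4L)
  expect_identical(tc$start, c(1000L, 1040L, 1080L, 1120L))
  expect_identical(unique(nchar(tc$sequence)), 80L)
  expect_identical(tc$id, sprintf("t1_c%03d", 1:4))

  expect_identical(nrow(tile_candidates(rand_dna(80), region_row("chr1", 0L, 80L))), 1L)
  expect_warning(
    none <- tile_candidates(rand_dna(79), region_row("chr1", 0L, 79L)),
    "shorter")
  expect_identical(nrow(none), 0L)

  tc2 <- tile_candidates(rand_dna(210), region_row("chr1", 0L, 210L),
                         anchor_end = TRUE)
  expect_identical(tc2$start, c(0L, 40L, 80L, 120L, 130L))
})

test_that("tiling on minus-strand regions maps back to genomic coordinates", {
  set.seed(37)
  genome <- c(chr1 = rand_dna(400))
  r <- region_row("chr1", 100L, 300L, "m", "-")
  seq <- extract_target_sequence(genome, r)
  tc <- tile_candidates(seq, r, 80L, 2L)
  expect_identical(tc$start, c(220L, 180L, 140L, 100L))
  # each candidate sequence is the revcomp of its genomic span
  for (i in seq_len(nrow(tc))) {
    span <- substr(genome[["chr1"]], tc$start[i] + 1, tc$start[i] + 80)
    expect_identical(tc$sequence[i], revcomp(span))
  }
})

test_that("tile_candidates validates divisibility and drops N-heavy candidates", {
  expect_error(tile_candidates("ACGT", region_row("chr1", 0, 4), 80L, 3L),
               "divisible")
  s <- paste0(strrep("A", 100), "N", strrep("T", 100))
  expect_message(
    tc <- tile_candidates(s, region_row("chr1", 0L, nchar(s)), 80L, 2L),
    "ambiguous")
  expect_true(all(!grepl("N", tc$sequence)))
})

test_that("enumerate_variants yields nine states with a reproducible split", {
  set.seed(41)
  cand <- tile_candidates(rand_dna(80), region_row("chr1", 0L, 80L, "t"))
  v1 <- enumerate_variants(cand, 7)
  v2 <- enumerate_variants(cand, 7)
  expect_identical(v1, v2)
  expect_identical(nrow(v1), 9L)
  expect_identical(v1$state[1], "original")
  expect_identical(sum(v1$state == "original"), 1L)
  expect_identical(unique(nchar(v1$sequence)), 80L)
  # a different seed redraws the split sets but not the fixed states
  v3 <- enumerate_variants(cand, 8)
  fixed <- !grepl("split", v1$state)
  expect_identical(v1$sequence[fixed], v3$sequence[fixed])
})

test_that("dedup collapses CpG-free and palindromic variant sets", {
  # CpG-free candidate: all sense states equal full C->T conversion, all
  # antisense states equal the revcomp conversion -> at most 3 distinct
  cand <- data.frame(id = "x", sequence = "ACTACTACTACT",
                     stringsAsFactors = FALSE)
  dd <- enumerate_variants(cand, 1, dedup = TRUE)
  expect_lte(nrow(dd), 3L)
  expect_identical(sum(dd$multiplicity), 9L)

  # palindromic candidate: sense and antisense frames coincide pairwise
  pal <- data.frame(id = "p", sequence = "AACGCGTT", stringsAsFactors = FALSE)
  dv <- enumerate_variants(pal, 1, dedup = TRUE)
  expect_lt(nrow(dv), 9L)
  both <- grepl("sense", dv$states) & grepl("antisense", dv$states)
  expect_true(any(both))
})

test_that("compute_gc counts G+C over non-N bases", {
  expect_equal(compute_gc("GGCC"), 1)
  expect_equal(compute_gc("ATAT"), 0)
  expect_equal(compute_gc("ACGTN"), 0.5)
  expect_equal(compute_gc(c("gcgc", "ATgc")), c(1, 0.5))
  expect_warning(z <- compute_gc("NNNN"), "all-N")
  expect_equal(z, 0)
})

test_that("compute_mask_fraction unions sequence case and explicit intervals", {
  expect_equal(compute_mask_fraction("ACGTacgt"), 0.5)
  expect_equal(compute_mask_fraction("NNNN"), 1)
  expect_equal(compute_mask_fraction("ACGT",
                                     data.frame(start = 1L, end = 2L)), 0.25)
  # overlap of the two signals is not double-counted
  expect_equal(compute_mask_fraction("aCGT",
                                     data.frame(start = 0L, end = 1L)), 0.25)
  expect_error(compute_mask_fraction("ACGT",
                                     data.frame(start = 2L, end = 9L)),
               "span")
})

test_that("filter_candidates applies the documented boundary semantics", {
  cands <- data.frame(
    id = c("at_mask", "under_mask", "gc_low", "gc_high", "gc_out"),
    mask_fraction = c(0.25, 0.249, 0, 0, 0),
    gc_fraction = c(0.5, 0.5, 0.10, 0.80, 0.081),
    stringsAsFactors = FALSE)
  res <- filter_candidates(cands)
  expect_identical(res$report$pass_mask,
                   c(FALSE, TRUE, TRUE, TRUE, TRUE))  # strict "<"
  expect_identical(res$report$pass_gc,
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))  # inclusive bounds
  expect_identical(res$report$retained,
                   c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(res$report$pass_hits)))

  hits <- c(at_mask = 0L, under_mask = 10L, gc_low = 11L, gc_high = 0L,
            gc_out = 0L)
  res2 <- filter_candidates(cands, hit_table = hits)
  expect_identical(res2$report$pass_hits,
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))  # <= 10 inclusive
  expect_identical(res2$report$retained,
                   c(FALSE, TRUE, FALSE, TRUE, FALSE))
  # summary data.frame form of the hit table works too
  res3 <- filter_candidates(cands, hit_table = data.frame(
    candidate_id = names(hits), max_hits = unname(hits)))
  expect_identical(res3$report, res2$report)
  expect_error(filter_candidates(cands, hit_table = hits[-1]), "missing")
})

test_that("relaxing any threshold never shrinks the retained set", {
  set.seed(43)
  cands <- data.frame(
    id = paste0("c", 1:60),
    mask_fraction = runif(60, 0, 0.6),
    gc_fraction = runif(60),
    stringsAsFactors = FALSE)
  hits <- setNames(sample(0:20, 60, replace = TRUE), cands$id)
  base <- filter_candidates(cands, hits, max_mask = 0.2, gc_min = 0.2,
                            gc_max = 0.6, max_hits = 5)$retained$id
  for (relax in list(c(max_mask = 0.4), c(gc_min = 0.05), c(gc_max = 0.9),
                     c(max_hits = 15))) {
    args <- modifyList(list(candidates = cands, hit_table = hits,
                            max_mask = 0.2, gc_min = 0.2, gc_max = 0.6,
                            max_hits = 5), as.list(relax))
    wider <- do.call(filter_candidates, args)$retained$id
    expect_true(all(base %in% wider))
  }
})
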