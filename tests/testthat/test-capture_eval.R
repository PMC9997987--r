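test_that("summarize_region_coverage treats absent positions as zero depth", {
  depth <- data.frame(chrom = "chr1", pos = c(11L, 12L, 14L),
                      depth = c(10L, 10L, 20L), stringsAsFactors = FALSE)
  regions <- region_row("chr1", 10L, 14L)  # bases 11..14
  cs <- summarize_region_coverage(depth, regions)
  expect_equal(cs$mean_depth, 10)
  expect_equal(cs$breadth, 0.75)
  expect_identical(cs$min_depth, 0L)
  expect_identical(cs$max_depth, 20L)

  # region entirely absent from the track
  far <- summarize_region_coverage(depth, region_row("chr2", 0L, 10L))
  expect_equal(far$mean_depth, 0)
  expect_equal(far$breadth, 0)

  # two regions come back in input order
  two <- summarize_region_coverage(depth, rbind(
    region_row("chr2", 0L, 10L, "b"), region_row("chr1", 10L, 14L, "a")))
  expect_identical(two$name, c("b", "a"))

  empty <- summarize_region_coverage(depth, regions[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("filter_cov_records applies the inclusive depth bound and uniquifies", {
  rec <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 30L),
                    percent = c(75, 60, 40, 40),
                    count_m = c(3L, 3L, 2L, 2L),
                    count_u = c(1L, 2L, 3L, 3L), stringsAsFactors = FALSE)
  out <- filter_cov_records(rec, min_depth = 5L)
  expect_identical(out$pos, c(20L, 30L))  # depth 4 dropped, 5 kept, dup merged
  strict <- filter_cov_records(rec, min_depth = 5L, strict = TRUE)
  expect_identical(nrow(strict), 0L)
  rec$count_m[4] <- 3L
  expect_error(filter_cov_records(rec, min_depth = 0L), "chr1:30")
})

test_that("intersect_with_regions uses the 1-based/half-open bridge", {
  rec <- data.frame(chrom = "chr1", pos = c(100L, 101L, 200L, 201L),
                    percent = 0, count_m = 0L, count_u = 10L,
                    stringsAsFactors = FALSE)
  regions <- region_row("chr1", 100L, 200L)
  out <- intersect_with_regions(rec, regions)
  expect_identical(out$pos, c(101L, 200L))
  # overlapping regions emit each record once (pos 100 sits in the second
  # region but still appears a single time)
  out2 <- intersect_with_regions(rec, rbind(regions,
                                            region_row("chr1", 90L, 150L)))
  expect_identical(out2$pos, c(100L, 101L, 200L))
})

test_that("match_sites aligns shared keys", {
  a <- data.frame(chrom = "chr1", pos = c(101L, 105L), percent = c(10, 20),
                  count_m = 1L, count_u = 9L, stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", pos = c(105L, 109L), percent = c(30, 40),
                  count_m = 1L, count_u = 9L, stringsAsFactors = FALSE)
  m <- match_sites(a, b)
  expect_identical(nrow(m), 1L)
  expect_identical(m$pos, 105L)
  expect_equal(m$percent_a, 20)
  expect_equal(m$percent_b, 30)
  expect_identical(nrow(match_sites(a, transform(b, pos = pos + 1000L))), 0L)
  self <- match_sites(a, a)
  expect_identical(nrow(self), nrow(a))
  expect_equal(self$percent_a, self$percent_b)
  expect_error(match_sites(rbind(a, a), b), "unique")
})

test_that("pearson_r reproduces hand-computed values and refuses degeneracy", {
  mk <- function(pa, pb) {
    m <- data.frame(chrom = "c", pos = seq_along(pa), percent_a = pa,
                    percent_b = pb)
    class(m) <- c("matched_sites", "data.frame")
    m
  }
  expect_equal(pearson_r(mk(c(0, 50, 100), c(0, 50, 100))), 1)
  expect_equal(pearson_r(mk(c(0, 50, 100), c(100, 50, 0))), -1)
  # hand computation via the sum formulas: r = 4500 / sqrt(5000 * 4200)
  expect_equal(pearson_r(mk(c(0, 50, 100), c(10, 40, 100))),
               4500 / sqrt(5000 * 4200), tolerance = 1e-12)
  # affine invariance with positive slope
  set.seed(79)
  x <- runif(50, 0, 100)
  expect_equal(pearson_r(mk(x, 0.4 * x + 7)), 1)
  expect_error(pearson_r(mk(c(1, 2), c(5, 5))), "zero variance")
  expect_error(pearson_r(mk(1, 1)), "fewer than 2")
})

test_that("region_mean_methylation is the unweighted site mean, NA when empty", {
  rec <- data.frame(chrom = "chr1", pos = c(5L, 15L, 25L),
                    percent = c(0, 100, 75), count_m = 0L, count_u = 1L,
                    stringsAsFactors = FALSE)
  regions <- rbind(region_row("chr1", 0L, 20L, "both"),
                   region_row("chr1", 20L, 30L, "one"),
                   region_row("chr2", 0L, 30L, "none"))
  m <- region_mean_methylation(rec, regions)
  expect_equal(unname(m["both"]), 50)
  expect_equal(unname(m["one"]), 75)
  expect_true(is.na(m["none"]))
})

test_that("paired_t_test matches stats::t.test and handles degeneracy", {
  set.seed(83)
  x <- runif(24, 0, 100)
  y <- x + rnorm(24, 1, 4)
  mine <- paired_t_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(mine$dof, 23L)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(deg <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)),
                 "infinite")
  expect_identical(deg$t, Inf)
  expect_equal(deg$p, 0)
  # mean-zero differences give t = 0, p = 1
  flat <- paired_t_test(c(1, 2, 3), c(0, 2, 4))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  expect_error(paired_t_test(1, 1), "n >= 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("conversion_report pools counts per category", {
  rep <- rbind(
    data.frame(chrom = "lambda", pos = 1:100, strand = "+",
               count_m = c(1L, rep(0L, 99)), count_u = 1L,
               context = "CHH", trinucleotide = "CTT"),
    data.frame(chrom = "pUC19", pos = 1:50, strand = "+",
               count_m = 2L, count_u = c(rep(0L, 47), 1L, 1L, 1L),
               context = "CpG", trinucleotide = "CGA"),
    data.frame(chrom = "chr1", pos = 1:40, strand = "+",
               count_m = c(rep(1L, 2), rep(0L, 38)), count_u = 4L,
               context = rep(c("CHG", "CHH"), 20), trinucleotide = "CAG"))
  cr <- conversion_report(rep, "lambda", "pUC19")
  # lambda: 1 methylated of 1 + 100 unmethylated calls
  expect_equal(cr$lambda_error, 100 * 1 / 101)
  # pUC19 CpG: 50 x 2 methylated vs 3 unmethylated
  expect_equal(cr$puc19_retention, 100 * 100 / 103)
  # chr1 CHG rows: 1 methylated, 80 unmethylated (and the same for CHH)
  expect_equal(cr$chg_level, 100 * 1 / 81)
  expect_equal(cr$chh_level, 100 * 1 / 81)

  expect_warning(miss <- conversion_report(rep[rep$chrom != "lambda", ],
                                           "lambda", "pUC19"),
                 "unmethylated control")
  expect_true(is.na(miss$lambda_error))
})

test_that("random_promoter_regions intersects tracks with promoters", {
  lens <- c(chr1 = 50000L, tiny = 500L)
  # no promoters -> nothing
  empty <- random_promoter_regions(lens, rand_regions(3)[0, ], 10, 1000, 1)
  expect_identical(nrow(empty), 0L)
  # a promoter certain to be swallowed whole by dense tracks
  prom <- region_row("chr1", 20000L, 20400L, "p1")
  out <- random_promoter_regions(lens, prom, n_tracks = 400L,
                                 track_len = 10000L, seed = 5)
  expect_gte(nrow(out), 1)
  expect_true(all(out$start >= 20000 & out$end <= 20400))
  expect_true(any(out$end - out$start == 400))  # fully contained at least once
  # determinism
  out2 <- random_promoter_regions(lens, prom, n_tracks = 400L,
                                  track_len = 10000L, seed = 5)
  expect_identical(out$start, out2$start)
  expect_error(random_promoter_regions(c(tiny = 500L), prom,
                                       track_len = 10000L),
               "configuration error")
  # every output interval is inside its promoter (brute interval check)
  proms <- rand_regions(5, chroms = "chr1", max_pos = 40000L)
  res <- random_promoter_regions(lens, proms, n_tracks = 100L,
                                 track_len = 5000L, seed = 9)
  for (i in seq_len(nrow(res))) {
    inside <- any(proms$chrom == res$chrom[i] &
                    proms$start <= res$start[i] & proms$end >= res$end[i])
    expect_true(inside)
  }
})

test_that("filtering and intersecting commute", {
  set.seed(89)
  for (rep in 1:30) {
    rec <- rand_cov(40)
    regions <- rand_regions(4)
    a <- filter_cov_records(intersect_with_regions(rec, regions), 5L,
                            unique = FALSE)
    b <- intersect_with_regions(filter_cov_records(rec, 5L, unique = FALSE),
                                regions)
    expect_identical(a, b)
  }
})
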