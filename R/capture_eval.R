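# Capture-evaluation analytics: coverage summaries over target regions, CpG
# callset filtering/intersection/matching, correlations, region means,
# paired tests, spike-in conversion controls, and random-"promoter" region
# construction for method comparisons outside the capture panel.

#' Per-region coverage summaries from a per-base depth track
#'
#' Positions absent from the track count as depth 0, so `mean_depth` is the
#' mean over *all* bases of the region and `breadth` is the fraction of bases
#' with depth >= 1.
#'
#' @param depth_track `data.frame(chrom, pos, depth)` with 1-based positions.
#' @param regions region data.frame (0-based half-open).
#' @return data.frame with one row per region, in input order: `name`,
#'   `chrom`, `start`, `end`, `mean_depth`, `breadth`, `min_depth`,
#'   `max_depth`.
#' @export
summarize_region_coverage <- function(depth_track, regions) {
  assert_regions(regions)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth_track)),
            all(depth_track$depth >= 0))
  by_chrom <- split(depth_track[, c("pos", "depth")], depth_track$chrom)
  one <- function(i) {
    r <- regions[i, ]
    pos <- (r$start + 1L):r$end
    d <- rep(0L, length(pos))
    tr <- by_chrom[[r$chrom]]
    if (!is.null(tr)) {
      idx <- match(pos, tr$pos)
      d[!is.na(idx)] <- tr$depth[idx[!is.na(idx)]]
    }
    data.frame(name = r$name, chrom = r$chrom, start = r$start, end = r$end,
               mean_depth = mean(d), breadth = mean(d >= 1),
               min_depth = min(d), max_depth = max(d),
               stringsAsFactors = FALSE)
  }
  if (!nrow(regions)) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_depth = numeric(), breadth = numeric(),
                      min_depth = integer(), max_depth = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), one))
  rownames(out) <- NULL
  out
}

#' Depth-filter and uniquify a CpG callset
#'
#' Retains sites whose total call depth (`count_m + count_u`) meets the
#' minimum. "Above `min_depth`x coverage" is read inclusively (depth >=
#' `min_depth`); set `strict = TRUE` for a strict `>`. With `unique = TRUE`,
#' duplicate `(chrom, pos)` keys -- as arise when overlapping target regions
#' export the same site twice -- are collapsed to one record, provided their
#' counts agree.
#'
#' @param records CpG callset data.frame.
#' @param min_depth minimum depth (default 5).
#' @param unique collapse duplicate sites?
#' @param strict use a strict `>` instead of `>=`.
#' @return filtered callset data.frame.
#' @export
filter_cov_records <- function(records, min_depth = 5L, unique = TRUE,
                               strict = FALSE) {
  assert_cov(records)
  stopifnot(min_depth >= 0)
  depth <- records$count_m + records$count_u
  keep <- if (strict) depth > min_depth else depth >= min_depth
  out <- records[keep, , drop = FALSE]
  if (unique && nrow(out)) {
    key <- paste(out$chrom, out$pos, sep = ":")
    dup <- duplicated(key)
    if (any(dup)) {
      for (k in base::unique(key[dup])) {
        rows <- out[key == k, ]
        if (length(base::unique(rows$count_m)) > 1 ||
            length(base::unique(rows$count_u)) > 1) {
          stop(sprintf("conflicting counts for duplicated site %s", k),
               call. = FALSE)
        }
      }
      out <- out[!dup, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Intersect a CpG callset with target regions
#'
#' Keeps records whose 1-based position falls inside at least one region
#' (`start < pos <= end` against 0-based half-open regions); a record is
#' emitted once even when regions overlap.
#'
#' @param records CpG callset data.frame.
#' @param regions region data.frame.
#' @return subset of `records`.
#' @export
intersect_with_regions <- function(records, regions) {
  assert_cov(records)
  assert_regions(regions)
  keep <- pos_in_any_region(records$chrom, records$pos, regions)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match two CpG callsets on common sites
#'
#' @param a,b CpG callset data.frames, each unique by `(chrom, pos)`.
#' @return object of class `matched_sites`: a data.frame `chrom`, `pos`,
#'   `percent_a`, `percent_b` (one row per shared site) with attribute `n`.
#' @export
match_sites <- function(a, b) {
  assert_cov(a); assert_cov(b)
  ka <- paste(a$chrom, a$pos, sep = ":")
  kb <- paste(b$chrom, b$pos, sep = ":")
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("callsets must be unique by (chrom, pos); see filter_cov_records(unique = TRUE)",
         call. = FALSE)
  }
  idx <- match(ka, kb)
  sel <- !is.na(idx)
  out <- data.frame(chrom = a$chrom[sel], pos = a$pos[sel],
                    percent_a = a$percent[sel],
                    percent_b = b$percent[idx[sel]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("matched_sites", "data.frame"))
}

#' Pearson correlation of matched site-level methylation
#'
#' @param m a `matched_sites` object from [match_sites()].
#' @return the product-moment correlation of `percent_a` vs `percent_b`.
#'   Fewer than 2 sites or a zero-variance series is an error (never a silent
#'   0).
#' @export
pearson_r <- function(m) {
  stopifnot(inherits(m, "matched_sites"))
  if (nrow(m) < 2) {
    stop("correlation undefined: fewer than 2 matched sites", call. = FALSE)
  }
  if (sd(m$percent_a) == 0 || sd(m$percent_b) == 0) {
    stop("correlation undefined: zero variance in matched percentages",
         call. = FALSE)
  }
  cor(m$percent_a, m$percent_b)
}

#' Mean methylation per region
#'
#' Unweighted mean of the site-level methylation percentages falling in each
#' region (the `bedtools map -o mean` semantics); regions containing no sites
#' yield `NA`, not 0.
#'
#' @param records CpG callset data.frame (filter upstream as desired).
#' @param regions region data.frame.
#' @return named numeric vector, one element per region (names = region
#'   names), `NA` for empty regions.
#' @export
region_mean_methylation <- function(records, regions) {
  assert_cov(records)
  assert_regions(regions)
  out <- setNames(rep(NA_real_, nrow(regions)), regions$name)
  for (i in seq_len(nrow(regions))) {
    sel <- records$chrom == regions$chrom[i] &
      records$pos > regions$start[i] & records$pos <= regions$end[i]
    if (any(sel)) out[i] <- mean(records$percent[sel])
  }
  out
}

#' Paired t-test for replicate library comparisons
#'
#' Two-sided paired t-test on `d = x - y`: `t = mean(d) / (sd(d) / sqrt(n))`,
#' `dof = n - 1`. Degenerate zero-variance differences are handled explicitly:
#' all-zero differences give `t = 0, p = 1`; constant nonzero differences give
#' `t = +/-Inf, p = 0` with a warning.
#'
#' @param x,y equal-length numeric vectors of paired measurements (n >= 2).
#' @return `list(t =, dof =, p =)`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("paired t-test requires n >= 2", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, dof = n - 1L, p = 1))
    warning("zero-variance nonzero differences: t is infinite")
    return(list(t = sign(mean(d)) * Inf, dof = n - 1L, p = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, dof = n - 1L, p = 2 * pt(-abs(t), df = n - 1))
}

#' Conversion-control report from a cytosine context report
#'
#' Summarises the spike-in controls and the genomic non-CpG background:
#' * `lambda_error`: percent methylation called on the unmethylated control
#'   (all cytosine contexts) -- the residual conversion error;
#' * `puc19_retention`: percent methylation retained on the CpG-methylated
#'   control (CpG context) -- 100 minus the over-conversion rate;
#' * `chg_level` / `chh_level`: percent methylation in CHG/CHH context over
#'   the sample's own chromosomes (controls excluded), which should be near
#'   the error floor in vertebrate DNA.
#'
#' All four are pooled ratios `100 * sum(count_m) / sum(count_m + count_u)`.
#' A category with zero total calls yields `NA` with a warning.
#'
#' @param report_records cytosine context report data.frame.
#' @param lambda_chrom chromosome name of the unmethylated control.
#' @param puc19_chrom chromosome name of the methylated control.
#' @return `list(lambda_error =, puc19_retention =, chg_level =, chh_level =)`
#'   in percent.
#' @export
conversion_report <- function(report_records, lambda_chrom = "lambda",
                              puc19_chrom = "pUC19") {
  need <- c("chrom", "count_m", "count_u", "context")
  stopifnot(all(need %in% names(report_records)))
  rate <- function(sel, what) {
    m <- sum(report_records$count_m[sel])
    tot <- m + sum(report_records$count_u[sel])
    if (tot == 0) {
      warning(sprintf("no calls for %s; reported as NA", what))
      return(NA_real_)
    }
    100 * m / tot
  }
  is_lambda <- report_records$chrom == lambda_chrom
  is_puc <- report_records$chrom == puc19_chrom
  sample_rows <- !is_lambda & !is_puc
  list(
    lambda_error = rate(is_lambda, "unmethylated control"),
    puc19_retention = rate(is_puc & report_records$context == "CpG",
                           "methylated control (CpG)"),
    chg_level = rate(sample_rows & report_records$context == "CHG",
                     "sample CHG"),
    chh_level = rate(sample_rows & report_records$context == "CHH",
                     "sample CHH"))
}

#' Random "promoter" regions for panel-independent comparisons
#'
#' Places `n_tracks` random fixed-length tracks uniformly over the eligible
#' chromosomes (uniform over all valid placements, so chromosomes weigh in
#' proportion to their placeable length) and returns the non-empty
#' intersections of those tracks with the supplied promoter regions. Tracks
#' may overlap each other; duplicate output intervals are collapsed by
#' coordinates.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param promoters region data.frame of promoter intervals.
#' @param n_tracks number of random tracks.
#' @param track_len track length in bp; chromosomes shorter than this are
#'   excluded from placement.
#' @param seed integer seed.
#' @return region data.frame of intersection intervals (0-based half-open),
#'   each contained in one track and one promoter.
#' @export
random_promoter_regions <- function(chrom_lengths, promoters,
                                    n_tracks = 200L, track_len = 10000L,
                                    seed = 1L) {
  assert_regions(promoters)
  stopifnot(!is.null(names(chrom_lengths)), n_tracks >= 1, track_len >= 1)
  eligible <- chrom_lengths[chrom_lengths >= track_len]
  if (!length(eligible)) {
    stop("configuration error: no chromosome is long enough for the track length",
         call. = FALSE)
  }
  slots <- eligible - track_len + 1
  tracks <- with_seed(derive_seed(seed, "random_tracks"), {
    chrom <- sample(names(eligible), n_tracks, replace = TRUE,
                    prob = slots / sum(slots))
    start <- vapply(chrom, function(cc) {
      as.integer(sample.int(slots[[cc]], 1) - 1L)
    }, integer(1), USE.NAMES = FALSE)
    data.frame(chrom = chrom, start = start, end = start + track_len,
               stringsAsFactors = FALSE)
  })
  out <- list()
  for (i in seq_len(nrow(tracks))) {
    sel <- promoters$chrom == tracks$chrom[i] &
      promoters$start < tracks$end[i] & promoters$end > tracks$start[i]
    if (!any(sel)) next
    hit <- promoters[sel, , drop = FALSE]
    s <- pmax(hit$start, tracks$start[i])
    e <- pmin(hit$end, tracks$end[i])
    out[[length(out) + 1L]] <- data.frame(
      chrom = hit$chrom, start = s, end = e,
      name = hit$name, strand = hit$strand, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("chrom", "start", "end")]), , drop = FALSE]
  res$name <- sprintf("%s_rand%02d", res$name, seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}
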