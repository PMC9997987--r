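# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Case is preserved (soft-masked lowercase stays lowercase) and `N`/`n` map
#' to themselves, so masking annotation survives the transform.
#'
#' @param x character vector of DNA sequences (alphabet `ACGTNacgtn`).
#' @return character vector of reverse complements, names preserved.
#' @export
#' @examples
#' revcomp("AACGtt")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- vapply(chartr("ACGTNacgtn", "TGCANtgcan", x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

# Deterministic 31-bit seed derived from a global seed plus a path of labels.
# Polynomial rolling hash; stable across platforms and R versions.
derive_seed <- function(seed, ...) {
  path <- paste(c(as.character(seed), vapply(list(...), as.character,
                                             character(1))), collapse = "/")
  m <- 2147483647
  h <- 0
  for (cc in utf8ToInt(path)) h <- (h * 131 + cc) %% m
  as.integer(h)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Validate a DNA alphabet (used by the conversion algebra contracts).
assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (case-insensitive)",
                 what), call. = FALSE)
  }
  invisible(seq)
}

# Validate a regions data.frame (0-based half-open).
assert_regions <- function(regions) {
  need <- c("chrom", "start", "end", "name", "strand")
  if (!is.data.frame(regions) || !all(need %in% names(regions))) {
    stop("regions must be a data.frame with columns chrom, start, end, name, strand",
         call. = FALSE)
  }
  if (nrow(regions) && any(regions$end <= regions$start)) {
    stop("regions must satisfy end > start (0-based half-open)", call. = FALSE)
  }
  invisible(regions)
}

# Validate a CpG callset data.frame.
assert_cov <- function(records) {
  need <- c("chrom", "pos", "percent", "count_m", "count_u")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data.frame with columns chrom, pos, percent, count_m, count_u",
         call. = FALSE)
  }
  invisible(records)
}

# TRUE for each 1-based position that falls in >= 1 region (same chrom).
# Coordinate bridge: pos p is in [start, end) iff start < p <= end.
pos_in_any_region <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  if (!nrow(regions)) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos > regions$start[i] & pos <= regions$end[i])
  }
  hit
}

# Merge 1-based closed intervals that share at least one base.
# m: two-column matrix (start, end). Returns merged matrix.
merge_closed_intervals <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- matrix(NA_integer_, nrow(m), 2)
  k <- 1L
  out[1, ] <- m[1, ]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        k <- k + 1L
        out[k, ] <- m[i, ]
      }
    }
  }
  out[seq_len(k), , drop = FALSE]
}
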