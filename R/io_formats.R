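# I/O for the standard flat formats the toolkit touches. Readers are
# deliberately strict about the coordinate dialects:
#   * FASTA       — case preserved (lowercase = soft-masked repeat)
#   * BED         — 0-based half-open
#   * Bismark cov — 1-based, start == end, single cytosine per record
#   * cytosine report — 1-based, 7 columns
#   * depth track — 1-based per-base TSV
# All writers emit tab-separated, newline-terminated records without header.

#' Read a FASTA file, preserving case
#'
#' Lowercase bases carry the soft-masking (repeat) annotation used by
#' [compute_mask_fraction()], so sequences are read verbatim rather than
#' normalised to uppercase.
#'
#' @param path path to a FASTA file.
#' @return named character vector: one element per record, names are the
#'   FASTA ids (first whitespace-delimited token of the header), order as in
#'   the file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("FASTA error in '%s': empty file", path),
                           call. = FALSE)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) {
    stop(sprintf("FASTA error in '%s': line 1 does not start with '>'", path),
         call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(hdr)[which(!nzchar(ids) | is.na(ids))[1]]
    stop(sprintf("FASTA error in '%s': malformed header at line %d", path, bad),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("FASTA error in '%s': duplicate id '%s'",
                 path, ids[duplicated(ids)][1]), call. = FALSE)
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- seqs
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read target regions from BED
#'
#' BED3 to BED6 are accepted; intervals are 0-based half-open. A missing name
#' column yields auto names `region_<i>`, a missing strand column yields `"."`.
#'
#' @param path path to a BED file.
#' @return `data.frame(chrom, start, end, name, strand)`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("BED error in '%s': fewer than 3 columns at line %d",
                 path, lineno[which(ncol < 3)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("BED error in '%s': non-numeric start/end at line %d",
                 path, bad), call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- lineno[which(start >= end)[1]]
    stop(sprintf("BED error in '%s': start >= end at line %d", path, bad),
         call. = FALSE)
  }
  name <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                   character(1)),
                 paste0("region_", seq_along(fields)))
  name[!nzchar(name)] <- paste0("region_", which(!nzchar(name)))
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                     character(1)), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write target regions to BED6
#'
#' @param regions `data.frame(chrom, start, end, name, strand)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  assert_regions(regions)
  df <- data.frame(regions$chrom, regions$start, regions$end, regions$name,
                   0L, regions$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style CpG coverage file
#'
#' Six tab-separated columns: chrom, start, end, methylation percent,
#' methylated count, unmethylated count; positions are 1-based with
#' `start == end`. Counts are the primary data: if the stored percent
#' disagrees with `100 * count_m / (count_m + count_u)` by more than 0.01 it
#' is recomputed from the counts with a warning. Zero-depth records are kept
#' but flagged with a warning.
#'
#' @param path path to a `.cov` file.
#' @return `data.frame(chrom, pos, percent, count_m, count_u)`.
#' @export
read_bismark_cov <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      percent = numeric(), count_m = integer(),
                      count_u = integer(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6)) {
    stop(sprintf("coverage format error in '%s': fewer than 6 columns at line %d",
                 path, which(lengths(fields) < 6)[1]), call. = FALSE)
  }
  num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[`,
                                                        character(1), i)))
  pos <- num(2); end <- num(3); percent <- num(4)
  count_m <- num(5); count_u <- num(6)
  if (anyNA(pos) || anyNA(end) || anyNA(percent) || anyNA(count_m) ||
      anyNA(count_u)) {
    bad <- which(is.na(pos) | is.na(end) | is.na(percent) | is.na(count_m) |
                   is.na(count_u))[1]
    stop(sprintf("coverage format error in '%s': non-numeric field at line %d",
                 path, bad), call. = FALSE)
  }
  rec <- data.frame(chrom = vapply(fields, `[`, character(1), 1),
                    pos = as.integer(pos), percent = percent,
                    count_m = as.integer(count_m),
                    count_u = as.integer(count_u), stringsAsFactors = FALSE)
  depth <- rec$count_m + rec$count_u
  if (any(depth == 0)) {
    warning(sprintf("%d zero-depth record(s) in '%s'", sum(depth == 0), path))
  }
  derived <- ifelse(depth > 0, 100 * rec$count_m / depth, rec$percent)
  off <- depth > 0 & abs(derived - rec$percent) > 0.01
  if (any(off)) {
    warning(sprintf(
      "%d record(s) in '%s' had percent inconsistent with counts; recomputed from counts",
      sum(off), path))
    rec$percent[off] <- derived[off]
  }
  rec
}

#' Write a Bismark-style CpG coverage file
#'
#' @param records `data.frame(chrom, pos, percent, count_m, count_u)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(records, path) {
  assert_cov(records)
  df <- data.frame(records$chrom, records$pos, records$pos,
                   formatC(records$percent, format = "fg", digits = 10),
                   records$count_m, records$count_u)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style cytosine context report
#'
#' Seven tab-separated columns: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context (`CpG`, `CHG` or `CHH`), trinucleotide.
#'
#' @param path path to the report.
#' @return `data.frame(chrom, pos, strand, count_m, count_u, context,
#'   trinucleotide)`.
#' @export
read_cytosine_report <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), count_m = integer(),
                      count_u = integer(), context = character(),
                      trinucleotide = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7)) {
    stop(sprintf("cytosine report error in '%s': fewer than 7 columns at line %d",
                 path, which(lengths(fields) < 7)[1]), call. = FALSE)
  }
  g <- function(i) vapply(fields, `[`, character(1), i)
  out <- data.frame(chrom = g(1),
                    pos = suppressWarnings(as.integer(g(2))),
                    strand = g(3),
                    count_m = suppressWarnings(as.integer(g(4))),
                    count_u = suppressWarnings(as.integer(g(5))),
                    context = g(6), trinucleotide = g(7),
                    stringsAsFactors = FALSE)
  if (anyNA(out$pos) || anyNA(out$count_m) || anyNA(out$count_u)) {
    stop(sprintf("cytosine report error in '%s': non-numeric field", path),
         call. = FALSE)
  }
  bad <- !out$context %in% c("CpG", "CHG", "CHH")
  if (any(bad)) {
    stop(sprintf("cytosine report error in '%s': unknown context '%s' at line %d",
                 path, out$context[bad][1], which(bad)[1]), call. = FALSE)
  }
  out
}

#' Write a Bismark-style cytosine context report
#'
#' @param records data.frame as returned by [read_cytosine_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  need <- c("chrom", "pos", "strand", "count_m", "count_u", "context",
            "trinucleotide")
  stopifnot(all(need %in% names(records)))
  write.table(records[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Three tab-separated columns: chrom, 1-based position, depth. Positions
#' absent from the track are treated as depth 0 by downstream summaries.
#'
#' @param path path to the TSV.
#' @return `data.frame(chrom, pos, depth)`.
#' @export
read_depth_track <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer"))
  names(df) <- c("chrom", "pos", "depth")
  df
}

#' Write a per-base depth track
#'
#' @param depth `data.frame(chrom, pos, depth)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(depth, path) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  write.table(depth[, c("chrom", "pos", "depth")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
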