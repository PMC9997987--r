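# Seeded synthetic data: random (optionally soft-masked) genomes,
# promoter-like targets, per-CpG methylation profiles and simulated
# converted-library callsets. The generative model is deliberately simple --
# Poisson per-base depth, binomial methylation calls with conversion error
# and over-conversion, Beta-distributed regime methylation -- which is
# exactly the structure the evaluation analytics assume; see the methods
# vignette for what that does and does not establish.

#' Generate a random genome
#'
#' Uniform-random ACGT chromosomes; optionally a fraction of each chromosome
#' is soft-masked (lowercased) in contiguous runs to emulate repeat-masker
#' output.
#'
#' @param seed integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param mask_fraction target fraction of soft-masked bases per chromosome.
#' @param mask_run length of each masked run.
#' @return named character vector (a genome).
#' @export
make_genome <- function(seed, chrom_lengths, mask_fraction = 0,
                        mask_run = 150L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1),
            mask_fraction >= 0, mask_fraction < 1)
  with_seed(derive_seed(seed, "genome"), {
    out <- vapply(names(chrom_lengths), function(cc) {
      L <- chrom_lengths[[cc]]
      ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (mask_fraction > 0) {
        masked <- logical(L)
        target <- round(mask_fraction * L)
        run <- min(mask_run, L)
        tries <- 0L
        while (sum(masked) < target && tries < 50L * ceiling(target / run)) {
          s <- sample.int(L - run + 1L, 1)
          masked[s:(s + run - 1L)] <- TRUE
          tries <- tries + 1L
        }
        ch[masked] <- tolower(ch[masked])
      }
      paste(ch, collapse = "")
    }, character(1))
    names(out) <- names(chrom_lengths)
    out
  })
}

#' Place non-overlapping promoter-like target regions
#'
#' @param genome named character vector of chromosome sequences.
#' @param n number of regions.
#' @param length region length in bp.
#' @param seed integer seed.
#' @param chroms chromosomes eligible for placement (defaults to all);
#'   control spike-in chromosomes are typically excluded.
#' @return region data.frame of `n` disjoint regions named
#'   `target_01`, `target_02`, ...
#' @export
make_promoter_targets <- function(genome, n, length = 4000L, seed = 1L,
                                  chroms = names(genome)) {
  stopifnot(n >= 1, length >= 1, all(chroms %in% names(genome)))
  n <- as.integer(n)
  length <- as.integer(length)
  lens <- setNames(nchar(genome[chroms]), chroms)
  eligible <- lens[lens >= length]
  if (!base::length(eligible) ||
      sum(floor(eligible / length)) < n) {
    stop(sprintf("packing error: cannot place %d non-overlapping regions of %d bp",
                 n, length), call. = FALSE)
  }
  # rejection sampling with a bounded number of fresh restarts: random
  # sequential placement can in principle jam before n regions fit even when
  # packing is feasible, so a jammed attempt is discarded and redrawn from a
  # derived seed (deterministic for a given seed)
  for (attempt in 1:25) {
    placed <- with_seed(derive_seed(seed, "targets", attempt), {
      acc <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
      tries <- 0L
      while (nrow(acc) < n && (tries <- tries + 1L) <= 500L * n) {
        cc <- sample(names(eligible), 1,
                     prob = (eligible - length + 1) / sum(eligible - length + 1))
        s <- sample.int(eligible[[cc]] - length + 1L, 1) - 1L
        e <- s + length
        clash <- acc$chrom == cc & acc$start < e & acc$end > s
        if (!any(clash)) {
          acc <- rbind(acc, data.frame(chrom = cc, start = s, end = e,
                                       stringsAsFactors = FALSE))
        }
      }
      acc
    })
    if (nrow(placed) == n) {
      placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
      return(data.frame(chrom = placed$chrom, start = placed$start,
                        end = placed$end,
                        name = sprintf("target_%02d", seq_len(n)),
                        strand = "+", stringsAsFactors = FALSE))
    }
  }
  stop(sprintf("packing error: gave up placing %d non-overlapping regions of %d bp",
               n, length), call. = FALSE)
}

#' Enumerate cytosines and their contexts on both strands
#'
#' @param genome named character vector of chromosome sequences.
#' @return `data.frame(chrom, pos, strand, context, trinucleotide)` with
#'   1-based positions; `context` is `CpG` (C followed by G), `CHG`
#'   (C, non-G, G) or `CHH`, evaluated on the strand carrying the cytosine.
#'   Cytosines whose context window runs off the chromosome end or touches an
#'   `N` are classified with `N` treated as H (not G).
#' @export
enumerate_cytosine_contexts <- function(genome) {
  one_strand <- function(chrom, ch, strand) {
    L <- length(ch)
    if (strand == "+") {
      idx <- which(ch == "C" | ch == "c")
      n1 <- ifelse(idx + 1 <= L, ch[pmin(idx + 1, L)], "N")
      n2 <- ifelse(idx + 2 <= L, ch[pmin(idx + 2, L)], "N")
    } else {
      idx <- which(ch == "G" | ch == "g")
      n1 <- ifelse(idx - 1 >= 1, chartr("ACGTacgt", "TGCAtgca",
                                        ch[pmax(idx - 1, 1)]), "N")
      n2 <- ifelse(idx - 2 >= 1, chartr("ACGTacgt", "TGCAtgca",
                                        ch[pmax(idx - 2, 1)]), "N")
    }
    if (!length(idx)) return(NULL)
    n1u <- toupper(n1); n2u <- toupper(n2)
    context <- ifelse(n1u == "G", "CpG", ifelse(n2u == "G", "CHG", "CHH"))
    data.frame(chrom = chrom, pos = idx, strand = strand, context = context,
               trinucleotide = toupper(paste0("C", n1, n2)),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (chrom in names(genome)) {
    ch <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    out[[length(out) + 1L]] <- one_strand(chrom, ch, "+")
    out[[length(out) + 1L]] <- one_strand(chrom, ch, "-")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      trinucleotide = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Assign a methylation profile to every CpG site of a genome
#'
#' Plus-strand CpG sites inside target regions draw their true methylation
#' level from `promoter_beta` (low, promoter-like); all other sites draw from
#' `background_beta` (high, genomic background), giving the bimodal dynamic
#' range a method comparison needs. Control chromosomes are forced to 0
#' (unmethylated spike-in) or 1 (methylated spike-in).
#'
#' @param genome named character vector of chromosome sequences.
#' @param targets region data.frame of promoter-like targets.
#' @param seed integer seed.
#' @param promoter_beta,background_beta `c(shape1, shape2)` of the regime
#'   Beta distributions; defaults Beta(1, 9) (mean 0.1) and Beta(7, 3)
#'   (mean 0.7).
#' @param unmethylated_chroms,methylated_chroms control chromosome names
#'   (used only if present in the genome).
#' @return object of class `methylation_profile`: list with element `sites`,
#'   a `data.frame(chrom, pos, true_p, regime)` over all plus-strand CpG
#'   sites.
#' @export
make_methylation_profile <- function(genome, targets, seed = 1L,
                                     promoter_beta = c(1, 9),
                                     background_beta = c(7, 3),
                                     unmethylated_chroms = "lambda",
                                     methylated_chroms = "pUC19") {
  assert_regions(targets)
  sites <- list()
  for (chrom in names(genome)) {
    pos <- enumerate_cpg_sites(genome[[chrom]])
    if (length(pos)) {
      sites[[length(sites) + 1L]] <- data.frame(chrom = chrom, pos = pos,
                                                stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, sites)
  if (is.null(df)) df <- data.frame(chrom = character(), pos = integer())
  regime <- ifelse(pos_in_any_region(df$chrom, df$pos, targets),
                   "promoter_low", "background_high")
  regime[df$chrom %in% unmethylated_chroms] <- "control_unmethylated"
  regime[df$chrom %in% methylated_chroms] <- "control_methylated"
  true_p <- with_seed(derive_seed(seed, "profile"), {
    p <- numeric(nrow(df))
    sel <- regime == "promoter_low"
    p[sel] <- rbeta(sum(sel), promoter_beta[1], promoter_beta[2])
    sel <- regime == "background_high"
    p[sel] <- rbeta(sum(sel), background_beta[1], background_beta[2])
    p[regime == "control_unmethylated"] <- 0
    p[regime == "control_methylated"] <- 1
    p
  })
  df$true_p <- true_p
  df$regime <- regime
  rownames(df) <- NULL
  structure(list(sites = df), class = "methylation_profile")
}

#' Simulation configuration
#'
#' Defaults mirror a well-performing capture experiment at desk scale: mean
#' on-target depth 150x against a 2x off-target background, residual
#' conversion error 1.2% (methylation called on fully unmethylated DNA) and
#' over-conversion 2.3% (methylation lost on fully methylated DNA).
#'
#' @param seed integer seed.
#' @param mean_target_depth mean per-base depth inside target regions.
#' @param mean_background_depth mean per-base depth elsewhere.
#' @param conversion_error probability an unmethylated C is read as
#'   methylated.
#' @param overconversion probability a methylated C is read as unmethylated.
#' @param duplication_rate fraction of reads that are duplicates; depths and
#'   counts are inflated by `1 / (1 - duplication_rate)` to emulate a
#'   non-deduplicated callset.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, mean_target_depth = 150,
                              mean_background_depth = 2,
                              conversion_error = 0.012,
                              overconversion = 0.023,
                              duplication_rate = 0) {
  stopifnot(mean_target_depth > 0, mean_background_depth > 0,
            conversion_error >= 0, conversion_error < 1,
            overconversion >= 0, overconversion < 1,
            duplication_rate >= 0, duplication_rate < 1)
  structure(list(seed = as.integer(seed),
                 mean_target_depth = mean_target_depth,
                 mean_background_depth = mean_background_depth,
                 conversion_error = conversion_error,
                 overconversion = overconversion,
                 duplication_rate = duplication_rate),
            class = "simulation_config")
}

#' Simulate a converted methylation library at the call level
#'
#' Per-base depth is drawn as Poisson with the target or background mean;
#' each CpG site's methylated call count is Binomial(depth at the site, `q`)
#' with `q = true_p * (1 - overconversion) + (1 - true_p) * conversion_error`.
#' CpG records are emitted for sites with depth > 0. When a genome is
#' supplied, a cytosine context report covering both strands is generated:
#' non-CpG cytosines behave as unmethylated (`true_p = 0`), minus-strand CpG
#' cytosines inherit the site's `true_p`. No reads are simulated; the output
#' is directly the callset a methylation extractor would produce.
#'
#' @param profile a `methylation_profile`.
#' @param config a [simulation_config()].
#' @param targets region data.frame defining on-target positions.
#' @param genome optional genome (named character vector); required for the
#'   context report and the depth track.
#' @param seed seed for this library draw (defaults to `config$seed`); give a
#'   different seed to draw an independent technical replicate.
#' @param emit_context,emit_depth generate the cytosine context report /
#'   per-base depth track (both need `genome`).
#' @return object of class `simulated_library`: `list(cov =, context =,
#'   depth =)` where `cov` is a CpG callset data.frame and the other two may
#'   be `NULL`.
#' @export
simulate_coverage <- function(profile, config, targets, genome = NULL,
                              seed = config$seed, emit_context = !is.null(genome),
                              emit_depth = !is.null(genome)) {
  stopifnot(inherits(profile, "methylation_profile"),
            inherits(config, "simulation_config"))
  assert_regions(targets)
  if ((emit_context || emit_depth) && is.null(genome)) {
    stop("emit_context/emit_depth require the genome", call. = FALSE)
  }
  dup_f <- 1 / (1 - config$duplication_rate)
  inflate <- function(x) if (config$duplication_rate > 0) {
    as.integer(round(x * dup_f))
  } else x
  with_seed(derive_seed(seed, "library"), {
    sites <- profile$sites
    depth_track <- NULL
    if (!is.null(genome)) {
      # one Poisson draw per genome base; site depths are read off the track
      # so callset and track are mutually consistent
      tracks <- lapply(names(genome), function(chrom) {
        L <- nchar(genome[[chrom]])
        pos <- seq_len(L)
        mu <- ifelse(pos_in_any_region(rep(chrom, L), pos, targets),
                     config$mean_target_depth, config$mean_background_depth)
        data.frame(chrom = chrom, pos = pos, depth = rpois(L, mu),
                   stringsAsFactors = FALSE)
      })
      depth_track <- do.call(rbind, tracks)
      key <- split(seq_len(nrow(depth_track)), depth_track$chrom)
      site_depth <- integer(nrow(sites))
      for (chrom in unique(sites$chrom)) {
        rows <- sites$chrom == chrom
        tr <- depth_track[key[[chrom]], ]
        site_depth[rows] <- tr$depth[match(sites$pos[rows], tr$pos)]
      }
    } else {
      on_target <- pos_in_any_region(sites$chrom, sites$pos, targets)
      site_depth <- rpois(nrow(sites),
                          ifelse(on_target, config$mean_target_depth,
                                 config$mean_background_depth))
    }
    q <- sites$true_p * (1 - config$overconversion) +
      (1 - sites$true_p) * config$conversion_error
    count_m <- rbinom(nrow(sites), site_depth, q)
    count_u <- site_depth - count_m
    count_m <- inflate(count_m); count_u <- inflate(count_u)
    keep <- site_depth > 0
    cov <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                      percent = 100 * count_m[keep] /
                        (count_m[keep] + count_u[keep]),
                      count_m = as.integer(count_m[keep]),
                      count_u = as.integer(count_u[keep]),
                      stringsAsFactors = FALSE)
    rownames(cov) <- NULL

    context <- NULL
    if (emit_context) {
      ctx <- enumerate_cytosine_contexts(genome)
      # true_p: plus-strand CpG from the profile; minus-strand CpG inherits
      # the site value (its partner C is at pos - 1 on the plus strand);
      # CHG/CHH cytosines are unmethylated
      pk <- paste(sites$chrom, sites$pos, sep = ":")
      tp <- numeric(nrow(ctx))
      plus_cpg <- ctx$context == "CpG" & ctx$strand == "+"
      minus_cpg <- ctx$context == "CpG" & ctx$strand == "-"
      tp[plus_cpg] <- sites$true_p[match(paste(ctx$chrom[plus_cpg],
                                               ctx$pos[plus_cpg], sep = ":"),
                                         pk)]
      tp[minus_cpg] <- sites$true_p[match(paste(ctx$chrom[minus_cpg],
                                                ctx$pos[minus_cpg] - 1L,
                                                sep = ":"), pk)]
      tp[is.na(tp)] <- 0  # CpG on one strand only (edge or N partner)
      cd <- if (!is.null(depth_track)) {
        dt_key <- paste(depth_track$chrom, depth_track$pos, sep = ":")
        depth_track$depth[match(paste(ctx$chrom, ctx$pos, sep = ":"), dt_key)]
      } else {
        rpois(nrow(ctx), ifelse(pos_in_any_region(ctx$chrom, ctx$pos, targets),
                                config$mean_target_depth,
                                config$mean_background_depth))
      }
      qq <- tp * (1 - config$overconversion) + (1 - tp) * config$conversion_error
      cm <- rbinom(nrow(ctx), cd, qq)
      cu <- cd - cm
      context <- data.frame(chrom = ctx$chrom, pos = ctx$pos,
                            strand = ctx$strand,
                            count_m = as.integer(inflate(cm)),
                            count_u = as.integer(inflate(cu)),
                            context = ctx$context,
                            trinucleotide = ctx$trinucleotide,
                            stringsAsFactors = FALSE)
    }
    if (!is.null(depth_track) && config$duplication_rate > 0) {
      depth_track$depth <- inflate(depth_track$depth)
    }
    structure(list(cov = cov, context = context,
                   depth = if (emit_depth) depth_track else NULL),
              class = "simulated_library")
  })
}

#' Simulate an independent technical replicate library
#'
#' Redraws depths and calls from the same methylation profile with a new
#' seed, emulating a replicate library of the same sample.
#'
#' @inheritParams simulate_coverage
#' @param seed2 seed for the replicate draw.
#' @return a `simulated_library` (see [simulate_coverage()]).
#' @export
simulate_duplicate_library <- function(profile, config, targets, seed2,
                                       genome = NULL,
                                       emit_context = !is.null(genome),
                                       emit_depth = !is.null(genome)) {
  simulate_coverage(profile, config, targets, genome = genome, seed = seed2,
                    emit_context = emit_context, emit_depth = emit_depth)
}
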