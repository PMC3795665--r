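# Repeat copy-number estimation from coverage ratios.
#
# The estimator is the coverage quotient: genomic rRNA repeat copies
#   C = (total bases aligned to the repeat unit / unit length) / D,
# where D = total sequenced bases / genome size is the genome-wide fold
# coverage. Because coverage can vary across repeat units, C is an average
# over the whole array.

#' Genome-wide sequencing depth
#'
#' @param total_sequenced_bases Total bases in the sequencing project.
#' @param genome_size Estimated genome size in bases.
#' @return Fold coverage (total sequenced bases / genome size).
#' @export
genome_depth <- function(total_sequenced_bases, genome_size) {
  stopifnot_scalar_num(total_sequenced_bases, "total_sequenced_bases")
  stopifnot_scalar_num(genome_size, "genome_size")
  if (genome_size <= 0) stop("genome_size must be > 0", call. = FALSE)
  if (total_sequenced_bases <= 0)
    stop("total_sequenced_bases must be > 0", call. = FALSE)
  total_sequenced_bases / genome_size
}

#' Mean fold coverage of the repeat unit
#'
#' @param total_aligned_bases Bases aligned to the repeat reference (e.g.
#'   `pileup$total_aligned_bases`).
#' @param repeat_length Repeat unit length in bases.
#' @return Fold coverage of the unit (unrounded; round for display).
#' @export
mean_repeat_coverage <- function(total_aligned_bases, repeat_length) {
  stopifnot_scalar_num(total_aligned_bases, "total_aligned_bases")
  stopifnot_scalar_num(repeat_length, "repeat_length")
  if (repeat_length <= 0) stop("repeat_length must be > 0", call. = FALSE)
  total_aligned_bases / repeat_length
}

#' Estimate repeat copy number
#'
#' Copies = mean repeat coverage / genome depth. Keep the unrounded mean
#' coverage as input: rounding the intermediate can shift the final rounded
#' estimate by one unit. `digits` mirrors reporting precision (integers for
#' low-depth long-read datasets, one decimal for high-depth short-read
#' datasets); `NULL` returns the unrounded value.
#'
#' @param mean_coverage Mean repeat coverage (fold).
#' @param depth Genome-wide depth D (fold).
#' @param digits Decimal places for the reported estimate, or `NULL`.
#' @return Estimated copy number.
#' @export
estimate_copies <- function(mean_coverage, depth, digits = NULL) {
  stopifnot_scalar_num(mean_coverage, "mean_coverage")
  stopifnot_scalar_num(depth, "depth")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  x <- mean_coverage / depth
  if (is.null(digits)) x else round(x, digits)
}

#' Per-generation change in repeat copy number
#'
#' Rate for a mutation-accumulation line relative to its progenitor;
#' contractions give negative rates. By convention rates are computed from
#' the rounded reported estimates, so published per-generation figures are
#' reproducible; pass unrounded estimates for the alternative.
#'
#' @param c_line Copy-number estimate of the MA line.
#' @param c_progenitor Copy-number estimate of the progenitor.
#' @param t Generations of propagation (> 0).
#' @return Copies per generation.
#' @export
expansion_rate <- function(c_line, c_progenitor, t) {
  stopifnot_scalar_num(c_line, "c_line")
  stopifnot_scalar_num(c_progenitor, "c_progenitor")
  stopifnot_scalar_num(t, "t")
  if (t <= 0) stop("t (generations) must be > 0", call. = FALSE)
  (c_line - c_progenitor) / t
}

#' Coverage uniformity across annotated regions
#'
#' Compares each region's mean per-position depth with the whole-repeat mean
#' and flags regions within one standard deviation (population SD over
#' per-position depths). A region sitting well outside suggests a
#' sub-repeat duplication or deletion rather than whole-unit copy-number
#' change.
#'
#' @param pileup An `rdna_pileup`.
#' @param regions Region data.frame (`name`, `start`, `end`) or an
#'   `rdna_reference` carrying one.
#' @return List with `overall_mean`, `overall_sd`, and `regions`, a
#'   data.frame with per-region `mean_depth` and `within_1sd`.
#' @export
coverage_uniformity <- function(pileup, regions) {
  stopifnot(inherits(pileup, "rdna_pileup"))
  if (inherits(regions, "rdna_reference")) regions <- regions$regions
  if (is.null(regions) || !nrow(regions))
    stop("no regions to assess", call. = FALSE)
  depth <- pileup$depth
  L <- length(depth)
  validate_regions(regions, L)
  mu <- mean(depth)
  sdev <- sqrt(mean((depth - mu)^2))      # population SD
  rmean <- vapply(seq_len(nrow(regions)), function(i)
    mean(depth[regions$start[i]:regions$end[i]]), 0)
  list(overall_mean = mu,
       overall_sd = sdev,
       regions = data.frame(
         name = regions$name,
         length = regions$end - regions$start + 1L,
         mean_depth = rmean,
         within_1sd = abs(rmean - mu) <= sdev,
         stringsAsFactors = FALSE))
}

#' Copy-number estimate with a read-resampling bootstrap CI
#'
#' Resamples reads (mapped and unmapped alike) with replacement and
#' recomputes the coverage-quotient estimate, giving a percentile interval
#' that reflects the binomial sampling of reads into the repeat array.
#'
#' @param aligned_lengths Per-retained-read aligned lengths (e.g.
#'   `aln$length` from [naive_map()]).
#' @param n_reads_total Total reads in the dataset, including unmapped ones
#'   (which contribute zero aligned bases).
#' @param repeat_length Repeat unit length.
#' @param depth Genome-wide depth D.
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level for the percentile interval.
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return List with `estimate`, `ci` (length-2), and `boot` (replicates).
#' @export
bootstrap_copy_number <- function(aligned_lengths, n_reads_total,
                                  repeat_length, depth,
                                  n_boot = 200L, conf = 0.95, seed = NULL) {
  if (n_reads_total < length(aligned_lengths))
    stop("n_reads_total smaller than the number of aligned reads", call. = FALSE)
  lens <- c(aligned_lengths,
            rep(0L, n_reads_total - length(aligned_lengths)))
  est <- estimate_copies(mean_repeat_coverage(sum(lens), repeat_length), depth)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      tot <- sum(lens[sample.int(n_reads_total, n_reads_total, replace = TRUE)])
      estimate_copies(mean_repeat_coverage(tot, repeat_length), depth)
    }, 0)
  })
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(quantile(boot, c(alpha, 1 - alpha))),
       boot = boot)
}
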