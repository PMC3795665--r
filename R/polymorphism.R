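# Intragenomic polymorphism calling with the coverage-scaled error filter.
#
# A non-consensus allele at a site is accepted as a polymorphism when its
# read count reaches half the genome-wide 1x coverage depth: with 10x
# coverage, at least five identical calls of that allele are required. A
# variant carried by a single repeat copy is expected in ~D reads (each copy
# is sequenced to depth D), so the threshold demands half a copy-equivalent
# of support -- far above what per-base sequencing error (~4% for long-read
# 454-class data, ~1% for short-read Illumina-class data) produces at any
# one position and allele.

#' Coverage-scaled polymorphism threshold
#'
#' `ceiling(0.5 * D)`, floored at 2 so a 1x dataset can never call a
#' polymorphism from a single read.
#'
#' @param depth Genome-wide fold coverage D (> 0).
#' @return Integer minimum count of the variant allele.
#' @export
polymorphism_threshold <- function(depth) {
  stopifnot_scalar_num(depth, "depth")
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  max(2L, as.integer(ceiling(0.5 * depth)))
}

#' Call intragenomic polymorphisms from a pileup
#'
#' For every reference position whose consensus is a nucleotide (positions
#' with consensus `N` emit nothing) and every non-consensus allele observed
#' at least once, a call is emitted; `passed` records whether the allele
#' count reaches the threshold. The default threshold is dataset-level,
#' `ceiling(0.5 * depth)` (see [polymorphism_threshold()]); with
#' `per_site = TRUE` it is `max(2, ceiling(0.5 * site depth))` instead.
#' Deletion alleles may pass and are reported with variant `"del"`;
#' insertions are outside the per-position model.
#'
#' @param pileup An `rdna_pileup`.
#' @param consensus Matching `rdna_consensus` (same length).
#' @param depth Genome-wide fold coverage D used to set the threshold.
#' @param per_site Use the per-site-depth threshold variant.
#' @return data.frame of class `rdna_calls`: `position`, `consensus`,
#'   `variant`, `count`, `site_depth`, `threshold`, `passed`.
#' @export
call_polymorphisms <- function(pileup, consensus, depth, per_site = FALSE) {
  stopifnot(inherits(pileup, "rdna_pileup"),
            inherits(consensus, "rdna_consensus"))
  cm <- pileup$counts
  L <- nrow(cm)
  if (length(consensus$per_position) != L)
    stop("consensus length does not match pileup length", call. = FALSE)
  thr0 <- polymorphism_threshold(depth)
  cons <- consensus$per_position
  alle <- pileup_alleles()
  res <- vector("list", 5L)
  for (a in seq_along(alle)) {
    pos <- which(cons != alle[a] & cons != "N" & cm[, a] >= 1L)
    if (!length(pos)) next
    res[[a]] <- data.frame(position = pos,
                           consensus = cons[pos],
                           variant = alle[a],
                           count = cm[pos, a],
                           site_depth = pileup$depth[pos],
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(calls))
    calls <- data.frame(position = integer(0), consensus = character(0),
                        variant = character(0), count = integer(0),
                        site_depth = integer(0), stringsAsFactors = FALSE)
  calls$threshold <- if (per_site)
    pmax(2L, as.integer(ceiling(0.5 * calls$site_depth)))
  else rep(thr0, nrow(calls))
  calls$passed <- calls$count >= calls$threshold
  calls <- calls[order(calls$position, calls$variant), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("rdna_calls", "data.frame")
  calls
}

#' Sliding-window polymorphism profile
#'
#' Fraction of polymorphic positions in each window; a position counts once
#' however many variant alleles passed there. The customary summary uses
#' 50 bp windows at step 1.
#'
#' @param calls An `rdna_calls` data.frame.
#' @param L Repeat length.
#' @param window Window length in bases (default 50; must be <= `L`).
#' @param step Step between window starts (default 1).
#' @return data.frame: `start` (1-based window start), `window`,
#'   `polymorphic_fraction`.
#' @export
window_profile <- function(calls, L, window = 50L, step = 1L) {
  if (window > L) stop("window exceeds repeat length", call. = FALSE)
  if (window < 1L || step < 1L) stop("window and step must be >= 1", call. = FALSE)
  poly <- integer(L)
  poly[unique(calls$position[calls$passed])] <- 1L
  cs <- c(0L, cumsum(poly))
  starts <- seq.int(1L, L - window + 1L, by = step)
  data.frame(start = starts,
             window = window,
             polymorphic_fraction = (cs[starts + window] - cs[starts]) / window)
}

#' Per-region polymorphism summary
#'
#' Counts passed polymorphic positions in each annotated region, plus a
#' coding-vs-noncoding aggregate (noncoding = every unit position outside
#' the coding regions, i.e. the spacers).
#'
#' @param calls An `rdna_calls` data.frame.
#' @param ref An `rdna_reference` with a region table.
#' @return data.frame: `name`, `length`, `polymorphic_positions`, `density`.
#'   Aggregate rows are named `coding` and `noncoding`.
#' @export
region_summary <- function(calls, ref) {
  stopifnot(inherits(ref, "rdna_reference"))
  rg <- ref$regions
  if (is.null(rg) || !nrow(rg)) stop("reference has no regions", call. = FALSE)
  L <- ref$length
  poly_pos <- unique(calls$position[calls$passed])
  rows <- lapply(seq_len(nrow(rg)), function(i) {
    mask <- rg$start[i]:rg$end[i]
    data.frame(name = rg$name[i], length = length(mask),
               polymorphic_positions = sum(poly_pos %in% mask),
               stringsAsFactors = FALSE)
  })
  coding_mask <- unlist(lapply(which(rg$coding), function(i) rg$start[i]:rg$end[i]))
  noncoding_mask <- setdiff(seq_len(L), coding_mask)
  rows <- c(rows, list(
    data.frame(name = "coding", length = length(coding_mask),
               polymorphic_positions = sum(poly_pos %in% coding_mask),
               stringsAsFactors = FALSE),
    data.frame(name = "noncoding", length = length(noncoding_mask),
               polymorphic_positions = sum(poly_pos %in% noncoding_mask),
               stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  out$density <- ifelse(out$length > 0, out$polymorphic_positions / out$length, 0)
  rownames(out) <- NULL
  out
}

#' Write polymorphism calls as TSV
#'
#' Plain dump of the call table with a header comment stating the 1-based
#' coordinate convention.
#'
#' @param calls An `rdna_calls` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  con <- file(path, "w")
  writeLines("# rdnarray polymorphism calls; coordinates are 1-based inclusive",
             con)
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write polymorphism calls as a minimal VCF
#'
#' One record per call; CHROM is the repeat id, POS 1-based, REF the
#' consensus base, ALT the variant (`<DEL>` for the deletion allele), FILTER
#' `PASS` or `lowcount`, and INFO carries count, site depth and threshold.
#'
#' @param calls An `rdna_calls` data.frame.
#' @param ref An `rdna_reference`.
#' @param path Output path.
#' @param passed_only Write only passed calls (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_calls_vcf <- function(calls, ref, path, passed_only = TRUE) {
  stopifnot(inherits(ref, "rdna_reference"))
  x <- if (passed_only) calls[calls$passed, , drop = FALSE] else calls
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$id, ref$length),
    "##INFO=<ID=VC,Number=1,Type=Integer,Description=\"Variant allele count\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##INFO=<ID=THR,Number=1,Type=Integer,Description=\"Polymorphism threshold\">",
    "##FILTER=<ID=lowcount,Description=\"Variant count below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(x)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tVC=%d;DP=%d;THR=%d",
    ref$id, x$position, x$consensus,
    ifelse(x$variant == "del", "<DEL>", x$variant),
    ifelse(x$passed, "PASS", "lowcount"),
    x$count, x$site_depth, x$threshold) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
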