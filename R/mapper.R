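# Internal naive mapper: ungapped sliding placement of reads on the repeat
# unit, both strands. Stands in for an external aligner in simulation-based
# end-to-end validation; candidate offsets are canonical single-unit
# coordinates, so a read spanning a unit junction in a tandem array still
# places correctly (the unit is tiled internally).

#' Map reads to the repeat unit by ungapped sliding comparison
#'
#' Each read is placed at the reference offset minimizing mismatches under
#' ungapped comparison of both strands against a tiled copy of the unit
#' (so placements wrap across the unit junction, as in a tandem array).
#' Reads whose best placement exceeds `max_divergence` are dropped. Ties are
#' broken toward the forward strand, then the smallest offset. `N` compares
#' unequal to every base.
#'
#' @param reads Character vector of read sequences (optionally named) or a
#'   `Biostrings::DNAStringSet`.
#' @param ref An `rdna_reference`.
#' @param max_divergence Maximum allowed mismatch fraction, in \[0, 0.5\].
#' @return data.frame with columns `read_id`, `start` (1-based canonical
#'   unit coordinate), `strand`, `length`, `mismatches`, `identity` for the
#'   retained reads; attribute `n_dropped` counts dropped reads.
#' @export
naive_map <- function(reads, ref, max_divergence = 0.05) {
  stopifnot(inherits(ref, "rdna_reference"))
  if (!is.numeric(max_divergence) || max_divergence < 0 || max_divergence > 0.5)
    stop("max_divergence must be in [0, 0.5]", call. = FALSE)
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (!length(reads)) {
    out <- data.frame(read_id = character(0), start = integer(0),
                      strand = character(0), length = integer(0),
                      mismatches = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  reads <- toupper(reads)
  L <- ref$length
  lens <- nchar(reads)
  if (any(lens >= 2L * L))
    stop("reads must be shorter than twice the repeat unit length", call. = FALSE)
  if (any(lens == 0L)) stop("empty read sequence", call. = FALSE)
  ntile <- ceiling((L + max(lens) - 1L) / L)
  tile <- strrep(ref$sequence, ntile)
  res <- hamming_map_cpp(unname(reads), unname(revcomp(reads)), tile, L)
  identity <- 1 - res$mismatches / lens
  keep <- identity >= 1 - max_divergence
  out <- data.frame(read_id = names(reads)[keep],
                    start = res$start[keep],
                    strand = res$strand[keep],
                    length = lens[keep],
                    mismatches = res$mismatches[keep],
                    identity = identity[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build a pileup from naive_map placements
#'
#' Tallies the (strand-corrected) read bases at canonical unit positions;
#' positions past the unit end wrap modulo the unit length. The ungapped
#' model has no deletions or insertions, so only the four base slots are
#' filled and the conservation identity `total_aligned_bases == sum of
#' retained read lengths` holds exactly (reads containing `N` excepted:
#' `N` calls are not tallied).
#'
#' @param aln data.frame from [naive_map()].
#' @param reads The read set passed to [naive_map()] (named the same way).
#' @param ref An `rdna_reference`.
#' @return An `rdna_pileup`.
#' @export
pileup_from_alignments <- function(aln, reads, ref) {
  stopifnot(inherits(ref, "rdna_reference"))
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  reads <- toupper(reads)
  L <- ref$length
  if (!nrow(aln))
    return(new_pileup(ref$id, matrix(0L, L, 5L),
                      n_excluded = attr(aln, "n_dropped") %||% 0L))
  sq <- unname(reads[aln$read_id])
  if (anyNA(sq)) stop("alignment references reads absent from the read set",
                      call. = FALSE)
  flip <- aln$strand == "-"
  sq[flip] <- revcomp(sq[flip])
  lens <- aln$length
  pos <- (rep(aln$start - 1L, lens) + (sequence(lens) - 1L)) %% L + 1L
  bases <- unlist(strsplit(sq, "", fixed = TRUE), use.names = FALSE)
  code <- match(bases, DNA_BASES)
  keep <- !is.na(code)
  cm <- matrix(tabulate((code[keep] - 1L) * L + pos[keep], nbins = 5L * L),
               nrow = L, ncol = 5L)
  new_pileup(ref$id, cm, n_excluded = attr(aln, "n_dropped") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read shotgun reads from FASTA or FASTQ
#'
#' Format is taken from the first character of the file (`>` FASTA, `@`
#' FASTQ); qualities are discarded — downstream analyses use raw base
#' calls.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
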