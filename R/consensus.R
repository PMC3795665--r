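# Majority-rule consensus from a pileup.

#' Build the consensus repeat by majority base call
#'
#' At each position the allele with the highest count wins. Ties are broken
#' alphabetically (A < C < G < T < del) and the positions recorded.
#' Zero-depth positions emit `N` with winning fraction 0. Positions whose
#' majority call is the deletion allele are dropped from the collapsed
#' consensus string (so it stays a valid nucleotide sequence) and listed in
#' `dropped`; the full-length `per_position` vector keeps `"del"` there so
#' downstream per-position analyses stay in reference coordinates.
#'
#' @param pileup An `rdna_pileup`.
#' @return An `rdna_consensus`: list with `sequence` (collapsed string),
#'   `per_position` (length-L vector over A/C/G/T/del/N), `winning_fraction`,
#'   `ties` (tied positions), `dropped` (majority-deletion positions).
#' @export
build_consensus <- function(pileup) {
  stopifnot(inherits(pileup, "rdna_pileup"))
  cm <- pileup$counts
  L <- nrow(cm)
  if (!L) stop("empty pileup", call. = FALSE)
  depth <- pileup$depth
  idx <- max.col(cm, ties.method = "first")   # first = alphabetical tie-break
  win <- cm[cbind(seq_len(L), idx)]
  per_position <- pileup_alleles()[idx]
  per_position[depth == 0L] <- "N"
  winning_fraction <- ifelse(depth > 0L, win / depth, 0)
  ties <- which(depth > 0L & rowSums(cm == win) > 1L)
  dropped <- which(per_position == "del")
  keep <- per_position != "del"
  structure(
    list(sequence = paste(per_position[keep], collapse = ""),
         per_position = per_position,
         winning_fraction = winning_fraction,
         ties = ties,
         dropped = dropped),
    class = "rdna_consensus")
}

#' @export
print.rdna_consensus <- function(x, ...) {
  cat(sprintf(
    "rDNA consensus: %d bp (%d reference positions), %d tie(s), %d dropped, %d N\n",
    nchar(x$sequence), length(x$per_position), length(x$ties),
    length(x$dropped), sum(x$per_position == "N")))
  invisible(x)
}

#' Report runs of undetermined (N) consensus positions
#'
#' These are the stretches an external gap-filling step would have to patch;
#' no filling is attempted here.
#'
#' @param consensus An `rdna_consensus`.
#' @return data.frame of maximal N-runs as 1-based inclusive `start`, `end`
#'   intervals in reference coordinates (zero rows if none).
#' @export
gap_report <- function(consensus) {
  stopifnot(inherits(consensus, "rdna_consensus"))
  isn <- consensus$per_position == "N"
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Write a consensus sequence as FASTA
#'
#' @param consensus An `rdna_consensus`.
#' @param path Output path.
#' @param id Sequence name to use in the FASTA header.
#' @return Invisibly, `path`.
#' @export
write_consensus <- function(consensus, path, id = "consensus") {
  ss <- Biostrings::DNAStringSet(setNames(consensus$sequence, id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
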