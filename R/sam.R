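# SAM ingestion: mandatory fields only, CIGAR ops M/=/X/I/D/N/S/H/P.
# Base-quality strings are ignored -- the polymorphism model works on raw
# base calls.

# Parse the mandatory SAM fields of every non-header line.
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      cigar = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM record (fewer than 11 fields) at alignment line ",
         which(nf < 11L)[1L], call. = FALSE)
  data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag  = as.integer(vapply(f, `[`, "", 2L)),
    rname = vapply(f, `[`, "", 3L),
    pos   = as.integer(vapply(f, `[`, "", 4L)),
    cigar = vapply(f, `[`, "", 6L),
    seq   = toupper(vapply(f, `[`, "", 10L)),
    stringsAsFactors = FALSE)
}

# Walk one CIGAR, returning aligned (refpos, call) pairs, insertion records
# and the identity of the read against the reference.
walk_cigar <- function(pos, cigar, seq, refchars) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(m)) stop("unparsable CIGAR: ", cigar, call. = FALSE)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", m))
  ops <- sub("^\\d+", "", m)
  sq <- chars(seq)
  rp <- pos; qp <- 1L
  refpos <- integer(0); call <- character(0)
  ins_pos <- integer(0); ins_seq <- character(0)
  for (k in seq_along(ops)) {
    n <- lens[k]
    switch(ops[k],
      "M" = , "=" = , "X" = {
        refpos <- c(refpos, rp:(rp + n - 1L))
        call <- c(call, sq[qp:(qp + n - 1L)])
        rp <- rp + n; qp <- qp + n
      },
      "I" = {
        ins_pos <- c(ins_pos, rp - 1L)
        ins_seq <- c(ins_seq, paste(sq[qp:(qp + n - 1L)], collapse = ""))
        qp <- qp + n
      },
      "D" = {
        refpos <- c(refpos, rp:(rp + n - 1L))
        call <- c(call, rep("del", n))
        rp <- rp + n
      },
      "N" = { rp <- rp + n },
      "S" = { qp <- qp + n },
      "H" = , "P" = NULL)
  }
  if (length(refpos) && (min(refpos) < 1L || max(refpos) > length(refchars)))
    stop("alignment extends outside the reference (positions ",
         min(refpos), "-", max(refpos), ")", call. = FALSE)
  matches <- sum(call == refchars[refpos])
  list(refpos = refpos, call = call,
       ins_pos = ins_pos, ins_seq = ins_seq,
       identity = if (length(refpos)) matches / length(refpos) else 0)
}

# Shared SAM -> per-read aligned records; used by single- and dual-pass
# pileup builders.
sam_alignments <- function(path, ref) {
  stopifnot(inherits(ref, "rdna_reference"))
  df <- read_sam_records(path)
  refchars <- chars(ref$sequence)
  out <- vector("list", nrow(df))
  n_unmapped <- 0L
  for (i in seq_len(nrow(df))) {
    if (bitwAnd(df$flag[i], 4L) != 0L || df$rname[i] == "*") {
      n_unmapped <- n_unmapped + 1L
      next
    }
    if (df$rname[i] != ref$id)
      stop(sprintf("SAM record '%s' is aligned to '%s', not to reference '%s'",
                   df$qname[i], df$rname[i], ref$id), call. = FALSE)
    out[[i]] <- c(walk_cigar(df$pos[i], df$cigar[i], df$seq[i], refchars),
                  list(qname = df$qname[i]))
  }
  list(records = Filter(Negate(is.null), out), n_unmapped = n_unmapped)
}

records_to_pileup <- function(records, ref, n_excluded, n_unmapped) {
  L <- ref$length
  refpos <- unlist(lapply(records, `[[`, "refpos"), use.names = FALSE)
  call <- unlist(lapply(records, `[[`, "call"), use.names = FALSE)
  code <- match(call, pileup_alleles())
  keep <- !is.na(code)                      # N calls are not tallied
  cm <- matrix(tabulate((code[keep] - 1L) * L + refpos[keep], nbins = 5L * L),
               nrow = L, ncol = 5L)
  ins_pos <- unlist(lapply(records, `[[`, "ins_pos"), use.names = FALSE)
  ins_seq <- unlist(lapply(records, `[[`, "ins_seq"), use.names = FALSE)
  ins <- NULL
  if (length(ins_pos)) {
    key <- paste(ins_pos, ins_seq, sep = ":")
    agg <- rowsum(rep(1L, length(key)), key)
    parts <- strsplit(rownames(agg), ":", fixed = TRUE)
    ins <- data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
                      sequence = vapply(parts, `[`, "", 2L),
                      count = as.integer(agg[, 1L]),
                      stringsAsFactors = FALSE)
    ins <- ins[order(ins$position, ins$sequence), , drop = FALSE]
    rownames(ins) <- NULL
  }
  new_pileup(ref$id, cm, ins, n_excluded, n_unmapped)
}

#' Build a pileup from a SAM file
#'
#' Ingests a plain-text SAM alignment against the repeat reference and
#' tallies base calls per reference position. Reads whose identity
#' (matches / aligned columns, deletion columns included, insertions
#' excluded) falls below `min_identity` are excluded. Deletions are tallied
#' as a fifth allele; insertions go to a side table keyed by the preceding
#' reference position and do not add to depth. Unmapped records are skipped
#' and counted.
#'
#' @param path Path to a SAM file whose records align to `ref$id`.
#' @param ref An `rdna_reference`; a record mapped to any other reference
#'   name is an error.
#' @param min_identity Minimum read identity to retain (default 0.95; the
#'   permissive second pass uses 0.85).
#' @return An `rdna_pileup`.
#' @examples
#' fa <- system.file("extdata", "toy_repeat.fasta", package = "rdnarray")
#' ref <- load_reference(fa, annotation = NULL)
#' sam <- system.file("extdata", "toy_reads.sam", package = "rdnarray")
#' p <- pileup_from_sam(sam, ref, min_identity = 0.85)
#' p$total_aligned_bases
#' @export
pileup_from_sam <- function(path, ref, min_identity = 0.95) {
  al <- sam_alignments(path, ref)
  ident <- vapply(al$records, `[[`, 0, "identity")
  keep <- ident >= min_identity
  records_to_pileup(al$records[keep], ref,
                    n_excluded = sum(!keep), n_unmapped = al$n_unmapped)
}

#' Dual-stringency pileup (95% then 85% identity)
#'
#' Mirrors the two-pass mapping protocol: a stringent pass at
#' `levels[1]` identity, then a permissive pass at `levels[2]`. In
#' `"residual"` mode the second pass admits only reads that failed the
#' first; in `"all"` mode it re-admits every read at the permissive level.
#' For a fixed ingested alignment the two modes produce identical merged
#' tallies (each read's identity is fixed, so residual-first merging equals
#' a single permissive pass); they differ only in the per-pass bookkeeping
#' reported in the `passes` attribute.
#'
#' @inheritParams pileup_from_sam
#' @param levels Two decreasing identity thresholds.
#' @param mode `"residual"` (default) or `"all"`.
#' @return An `rdna_pileup` with attribute `passes`, a data.frame of
#'   per-pass retained-read counts and aligned bases.
#' @export
pileup_dual <- function(path, ref, levels = c(0.95, 0.85),
                        mode = c("residual", "all")) {
  mode <- match.arg(mode)
  stopifnot(length(levels) == 2L, levels[1] >= levels[2])
  al <- sam_alignments(path, ref)
  ident <- vapply(al$records, `[[`, 0, "identity")
  k1 <- ident >= levels[1]
  k2 <- if (mode == "residual") !k1 & ident >= levels[2] else ident >= levels[2]
  p1 <- records_to_pileup(al$records[k1], ref, 0L, al$n_unmapped)
  p2 <- records_to_pileup(al$records[k2], ref, 0L, 0L)
  merged <- if (mode == "residual") merge_pileups(p1, p2) else p2
  merged$n_excluded <- sum(ident < levels[2])
  attr(merged, "passes") <- data.frame(
    min_identity = levels,
    reads = c(sum(k1), sum(k2)),
    aligned_bases = c(p1$total_aligned_bases, p2$total_aligned_bases))
  merged
}
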