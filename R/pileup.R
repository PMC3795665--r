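# Pileup container: per-position tallies of A/C/G/T/deletion over the
# repeat unit. Insertions relative to the reference are kept in a side
# table keyed by the preceding reference position and never add to depth.

new_pileup <- function(ref_id, counts, insertions = NULL,
                       n_excluded = 0L, n_unmapped = 0L) {
  stopifnot(is.matrix(counts), ncol(counts) == 5L)
  colnames(counts) <- pileup_alleles()
  if (is.null(insertions))
    insertions <- data.frame(position = integer(0), sequence = character(0),
                             count = integer(0), stringsAsFactors = FALSE)
  structure(
    list(ref_id = ref_id,
         counts = counts,
         depth = as.integer(rowSums(counts)),
         total_aligned_bases = sum(counts),
         insertions = insertions,
         n_excluded = as.integer(n_excluded),
         n_unmapped = as.integer(n_unmapped)),
    class = "rdna_pileup")
}

#' @export
print.rdna_pileup <- function(x, ...) {
  cat(sprintf(
    "rDNA pileup on '%s': %d positions, %s aligned bases, mean depth %.1f\n",
    x$ref_id, nrow(x$counts),
    format(x$total_aligned_bases, big.mark = ","), mean(x$depth)))
  if (x$n_excluded) cat(sprintf("  %d read(s) excluded below identity threshold\n", x$n_excluded))
  if (x$n_unmapped) cat(sprintf("  %d unmapped record(s) skipped\n", x$n_unmapped))
  invisible(x)
}

#' Merge two pileups over the same reference
#'
#' Column counts and insertion tables are summed; exclusion counters add.
#'
#' @param a,b `rdna_pileup` objects over the same reference id and length.
#' @return A merged `rdna_pileup`.
#' @export
merge_pileups <- function(a, b) {
  stopifnot(inherits(a, "rdna_pileup"), inherits(b, "rdna_pileup"))
  if (!identical(a$ref_id, b$ref_id) || nrow(a$counts) != nrow(b$counts))
    stop("pileups are over different references", call. = FALSE)
  ins <- rbind(a$insertions, b$insertions)
  if (nrow(ins)) {
    key <- paste(ins$position, ins$sequence, sep = ":")
    agg <- rowsum(ins$count, key)
    parts <- strsplit(rownames(agg), ":", fixed = TRUE)
    ins <- data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
                      sequence = vapply(parts, `[`, "", 2L),
                      count = as.integer(agg[, 1L]),
                      stringsAsFactors = FALSE)
    ins <- ins[order(ins$position, ins$sequence), , drop = FALSE]
    rownames(ins) <- NULL
  }
  new_pileup(a$ref_id, a$counts + b$counts, ins,
             a$n_excluded + b$n_excluded, a$n_unmapped + b$n_unmapped)
}

#' Write a pileup as TSV
#'
#' Columns: position (1-based), A, C, G, T, del, depth. A header comment
#' states the coordinate convention.
#'
#' @param pileup An `rdna_pileup`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pileup <- function(pileup, path) {
  stopifnot(inherits(pileup, "rdna_pileup"))
  df <- data.frame(position = seq_len(nrow(pileup$counts)),
                   pileup$counts, depth = pileup$depth,
                   check.names = FALSE)
  con <- file(path, "w")
  writeLines(c("# rdnarray pileup; coordinates are 1-based inclusive",
               sprintf("# reference=%s", pileup$ref_id)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup()]
#'
#' @param path Path to the TSV.
#' @param ref_id Reference id to record; if `NULL`, taken from the
#'   `# reference=` header comment when present.
#' @return An `rdna_pileup` (insertion table empty: insertions are not
#'   round-tripped through the TSV).
#' @export
read_pileup <- function(path, ref_id = NULL) {
  hdr <- readLines(path, n = 5L)
  if (is.null(ref_id)) {
    m <- grep("^# reference=", hdr, value = TRUE)
    ref_id <- if (length(m)) sub("^# reference=", "", m[1L]) else "unknown"
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  cm <- as.matrix(df[, pileup_alleles(), drop = FALSE])
  storage.mode(cm) <- "integer"
  new_pileup(ref_id, cm)
}
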