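# Shared fixtures and independent oracles, built in code.

# reference object from an in-memory sequence (goes through the public
# FASTA loader so coordinate/validation behaviour is exercised too)
make_ref <- function(sequence, id = "ref", regions = NULL) {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(paste0(">", id), sequence), tmp)
  on.exit(unlink(tmp))
  load_reference(tmp, annotation = regions)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# minimal SAM writer: records are lists with qname, flag, pos, cigar, seq
write_sam <- function(records, ref_id, ref_len) {
  tmp <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_id, ref_len))
  body <- vapply(records, function(r) {
    rname <- if (bitwAnd(r$flag, 4L) != 0L) "*" else ref_id
    paste(r$qname, r$flag, rname, r$pos, 60L, r$cigar, "*", 0L, 0L,
          r$seq, "*", sep = "\t")
  }, "")
  writeLines(c(hdr, body), tmp)
  tmp
}

# Brute-force global alignment score by enumeration of every monotone
# alignment (no dynamic programming); affine gaps: a run of length g scores
# gap_open + g * gap_extend. Feasible up to ~8-mers.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = -2, gap_extend = -0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, 0L, score + if (ca[i] == cb[j]) match else mismatch)
    if (i <= na)
      rec(i + 1L, j, 1L, score + gap_extend + if (state == 1L) 0 else gap_open)
    if (j <= nb)
      rec(i, j + 1L, 2L, score + gap_extend + if (state == 2L) 0 else gap_open)
  }
  rec(1L, 1L, -1L, 0)
  best
}

# brute-force ungapped placement oracle: minimum mismatches of a read over
# every offset of the tiled unit, both strands
brute_force_best_placement <- function(read, unit) {
  L <- nchar(unit)
  tile <- strrep(unit, ceiling((L + nchar(read) - 1) / L))
  rl <- nchar(read)
  mm_at <- function(r) {
    rc <- strsplit(r, "")[[1]]
    vapply(seq_len(L), function(off) {
      tc <- strsplit(substr(tile, off, off + rl - 1L), "")[[1]]
      sum(tc != rc)
    }, 0L)
  }
  fw <- mm_at(read)
  rv <- mm_at(revcomp(read))
  list(min_mismatches = min(fw, rv),
       fw = fw, rv = rv)
}

# pileup directly from a count matrix (rows = positions, cols A,C,G,T,del)
pileup_from_counts <- function(counts, ref_id = "ref") {
  storage.mode(counts) <- "integer"
  rdnarray:::new_pileup(ref_id, counts)
}

# columns helper: build an L x 5 zero matrix and set some columns
zero_counts <- function(L) matrix(0L, nrow = L, ncol = 5L,
                                  dimnames = list(NULL, pileup_alleles()))
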