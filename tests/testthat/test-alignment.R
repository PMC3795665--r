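# SAM ingestion, pileup construction, the internal naive mapper

test_that("pileup_from_sam tallies perfect, staggered and filtered reads", {
  set.seed(201)
  unit <- rand_seq(60)
  ref <- make_ref(unit, id = "u", regions = NULL)
  sub <- function(a, b) substr(unit, a, b)

  # one perfect read over positions 1-10
  sam <- write_sam(list(list(qname = "r1", flag = 0L, pos = 1L,
                             cigar = "10M", seq = sub(1, 10))), "u", 60L)
  p <- pileup_from_sam(sam, ref)
  expect_identical(p$total_aligned_bases, 10L)
  expect_identical(sum(p$depth[1:10] == 1L), 10L)
  expect_identical(sum(p$depth[11:60]), 0L)

  # two staggered reads overlapping 5 bases
  sam <- write_sam(list(
    list(qname = "r1", flag = 0L, pos = 1L, cigar = "10M", seq = sub(1, 10)),
    list(qname = "r2", flag = 0L, pos = 6L, cigar = "10M", seq = sub(6, 15))),
    "u", 60L)
  p <- pileup_from_sam(sam, ref)
  expect_identical(unname(p$depth[6:10]), rep(2L, 5))
  expect_identical(p$total_aligned_bases, 20L)

  # an 80%-identity read is excluded at min identity 0.85
  bad <- strsplit(sub(21, 40), "")[[1]]
  bad[1:4] <- vapply(bad[1:4], function(b) setdiff(c("A","C","G","T"), b)[1], "")
  sam <- write_sam(list(list(qname = "r3", flag = 0L, pos = 21L,
                             cigar = "20M", seq = paste(bad, collapse = ""))),
                   "u", 60L)
  p <- pileup_from_sam(sam, ref, min_identity = 0.85)
  expect_identical(p$total_aligned_bases, 0L)
  expect_identical(p$n_excluded, 1L)
  # ... and included at 0.80
  p <- pileup_from_sam(sam, ref, min_identity = 0.80)
  expect_identical(p$total_aligned_bases, 20L)
})

test_that("deletions are a fifth allele, insertions a side table", {
  set.seed(202)
  unit <- rand_seq(40)
  ref <- make_ref(unit, id = "u", regions = NULL)
  # 10M5D10M: skips ref 11-15; 5-base insertion after ref position 20
  seq1 <- paste0(substr(unit, 1, 10), substr(unit, 16, 25))
  seq2 <- paste0(substr(unit, 16, 20), "ACGTA", substr(unit, 21, 30))
  sam <- write_sam(list(
    list(qname = "d", flag = 0L, pos = 1L, cigar = "10M5D10M", seq = seq1),
    list(qname = "i", flag = 0L, pos = 16L, cigar = "5M5I10M", seq = seq2)),
    "u", 40L)
  p <- pileup_from_sam(sam, ref, min_identity = 0.7)
  expect_identical(unname(p$counts[11:15, "del"]), rep(1L, 5))
  # deletion columns count toward depth, insertions do not
  expect_identical(unname(p$depth[11:15]), rep(1L, 5))
  expect_identical(p$insertions$position, 20L)
  expect_identical(p$insertions$sequence, "ACGTA")
  expect_identical(p$insertions$count, 1L)
  # conservation: aligned columns per read (20 + 5D, 15M)
  expect_identical(p$total_aligned_bases, 25L + 15L)
})

test_that("unmapped records are skipped and reference mismatch is an error", {
  set.seed(203)
  unit <- rand_seq(30)
  ref <- make_ref(unit, id = "u", regions = NULL)
  sam <- write_sam(list(
    list(qname = "ok", flag = 0L, pos = 1L, cigar = "10M",
         seq = substr(unit, 1, 10)),
    list(qname = "un", flag = 4L, pos = 0L, cigar = "*", seq = rand_seq(10))),
    "u", 30L)
  p <- pileup_from_sam(sam, ref)
  expect_identical(p$n_unmapped, 1L)
  expect_identical(p$total_aligned_bases, 10L)
  other <- make_ref(unit, id = "other", regions = NULL)
  expect_error(pileup_from_sam(sam, other), "not to reference")
})

test_that("lowering min identity never decreases depth anywhere", {
  set.seed(204)
  unit <- rand_seq(80)
  ref <- make_ref(unit, id = "u", regions = NULL)
  recs <- lapply(1:20, function(i) {
    start <- sample(1:61, 1)
    rd <- strsplit(substr(unit, start, start + 19), "")[[1]]
    nmut <- sample(0:5, 1)
    if (nmut) {
      at <- sample(20, nmut)
      rd[at] <- vapply(rd[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
    }
    list(qname = paste0("r", i), flag = 0L, pos = start, cigar = "20M",
         seq = paste(rd, collapse = ""))
  })
  sam <- write_sam(recs, "u", 80L)
  depths <- lapply(c(1.0, 0.95, 0.9, 0.85, 0.75),
                   function(mi) pileup_from_sam(sam, ref, mi)$depth)
  for (k in 2:length(depths))
    expect_true(all(depths[[k]] >= depths[[k - 1]]))
})

test_that("residual-first dual pass equals a single permissive pass", {
  set.seed(205)
  unit <- rand_seq(80)
  ref <- make_ref(unit, id = "u", regions = NULL)
  recs <- lapply(1:15, function(i) {
    start <- sample(1:61, 1)
    rd <- strsplit(substr(unit, start, start + 19), "")[[1]]
    at <- sample(20, sample(0:4, 1))
    rd[at] <- vapply(rd[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
    list(qname = paste0("r", i), flag = 0L, pos = start, cigar = "20M",
         seq = paste(rd, collapse = ""))
  })
  sam <- write_sam(recs, "u", 80L)
  dual <- pileup_dual(sam, ref, levels = c(0.95, 0.85), mode = "residual")
  single <- pileup_from_sam(sam, ref, min_identity = 0.85)
  expect_identical(dual$counts, single$counts)
  expect_identical(dual$total_aligned_bases, single$total_aligned_bases)
  alln <- pileup_dual(sam, ref, levels = c(0.95, 0.85), mode = "all")
  expect_identical(alln$counts, single$counts)
  expect_s3_class(attr(dual, "passes"), "data.frame")
})

test_that("naive_map places exact and reverse-complement substrings", {
  set.seed(206)
  unit <- rand_seq(400)
  ref <- make_ref(unit, id = "u", regions = NULL)
  rd <- substr(unit, 101, 180)
  aln <- naive_map(c(fwd = rd, rev = revcomp(rd)), ref)
  expect_identical(aln$start, c(101L, 101L))
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$identity, c(1, 1))
  # a read spanning the unit junction places at its true offset
  junction <- paste0(substr(unit, 361, 400), substr(unit, 1, 40))
  aj <- naive_map(c(j = junction), ref)
  expect_identical(aj$start, 361L)
  expect_identical(aj$mismatches, 0L)
})

test_that("naive_map drop decision matches a brute-force offset scan", {
  set.seed(207)
  unit <- rand_seq(300)
  ref <- make_ref(unit, id = "u", regions = NULL)
  rd <- strsplit(substr(unit, 51, 130), "")[[1]]     # 80-mer
  at <- sample(80, 8)                                 # 10% mismatches
  rd[at] <- vapply(rd[at], function(b) setdiff(c("A","C","G","T"), b)[1], "")
  rd <- paste(rd, collapse = "")
  oracle <- brute_force_best_placement(rd, unit)
  expect_identical(oracle$min_mismatches, 8L)
  expect_true(oracle$min_mismatches / 80 > 0.05)
  aln <- naive_map(c(x = rd), ref, max_divergence = 0.05)
  expect_identical(nrow(aln), 0L)
  expect_identical(attr(aln, "n_dropped"), 1L)
  # and retained when the divergence cap admits it
  aln2 <- naive_map(c(x = rd), ref, max_divergence = 0.15)
  expect_identical(aln2$start, 51L)
  expect_identical(aln2$mismatches, 8L)
})

test_that("error-free simulated reads recover their origin modulo the unit", {
  sp <- array_spec(copies = 5, unit_length = 250, background = 2000, seed = 208)
  g <- simulate_genome(sp)
  rs <- simulate_reads(g$genome, read_length = 60, depth = 4,
                       error_rate = 0, seed = 209)
  ref <- make_ref(g$truth$unit, id = "unit", regions = NULL)
  aln <- naive_map(rs$reads, ref, max_divergence = 0)
  # reads wholly inside the array must land at their origin mod L
  inside <- rs$truth$start >= g$truth$array_start &
    rs$truth$start + 60 - 1 <= g$truth$array_end
  tr <- rs$truth[inside, ]
  expected <- ((tr$start - g$truth$array_start) %% 250L) + 1L
  got <- aln$start[match(tr$read_id, aln$read_id)]
  expect_false(anyNA(got))
  expect_identical(got, expected)
  # conservation: aligned bases = sum of retained read lengths
  p <- pileup_from_alignments(aln, rs$reads, ref)
  expect_identical(p$total_aligned_bases, sum(aln$length))
  # empty read set is not an error
  e <- naive_map(character(0), ref)
  expect_identical(nrow(e), 0L)
})

test_that("pileup TSV round-trips counts and merge_pileups adds tallies", {
  set.seed(210)
  cm <- matrix(rbinom(50 * 5, 20, 0.2), ncol = 5)
  p <- pileup_from_counts(cm, "u")
  tmp <- tempfile(fileext = ".tsv")
  write_pileup(p, tmp)
  back <- read_pileup(tmp)
  expect_identical(unname(back$counts), unname(p$counts))
  expect_identical(back$ref_id, "u")
  m <- merge_pileups(p, p)
  expect_identical(m$counts, p$counts + p$counts)
  expect_identical(m$total_aligned_bases, 2L * p$total_aligned_bases)
  unlink(tmp)
})
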