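# coverage-scaled polymorphism threshold, calling, windows, region summary

test_that("threshold is ceiling(D/2) with a floor of 2", {
  expect_identical(polymorphism_threshold(10), 5L)
  expect_identical(polymorphism_threshold(9.5), 5L)   # ceiling(4.75)
  expect_identical(polymorphism_threshold(2), 2L)
  expect_identical(polymorphism_threshold(1), 2L)     # floor prevents 1-read calls
  expect_identical(polymorphism_threshold(6.3), 4L)
  expect_error(polymorphism_threshold(0), "depth")
})

test_that("calls pass exactly when the variant count reaches the threshold", {
  cm <- zero_counts(5)
  cm[1, "A"] <- 5L; cm[1, "G"] <- 5L     # tie: consensus A, variant G at 5
  cm[2, "A"] <- 9L; cm[2, "G"] <- 1L     # below threshold
  cm[3, "C"] <- 10L                      # monomorphic
  cm[4, "T"] <- 6L; cm[4, "del"] <- 5L   # deletion allele can pass
  # position 5 zero depth -> consensus N -> no calls
  p <- pileup_from_counts(cm)
  cons <- build_consensus(p)
  calls <- call_polymorphisms(p, cons, depth = 10)
  expect_identical(unique(calls$threshold), 5L)
  g1 <- calls[calls$position == 1L & calls$variant == "G", ]
  expect_true(g1$passed)                 # 5 >= 5
  g2 <- calls[calls$position == 2L & calls$variant == "G", ]
  expect_false(g2$passed)                # 1 < 5
  expect_false(3L %in% calls$position)
  expect_false(5L %in% calls$position)
  d4 <- calls[calls$position == 4L & calls$variant == "del", ]
  expect_true(d4$passed)
  # per-site threshold variant
  ps <- call_polymorphisms(p, cons, depth = 10, per_site = TRUE)
  expect_identical(ps$threshold[ps$position == 1L], 5L)   # ceil(10/2)
  expect_identical(ps$threshold[ps$position == 2L], 5L)
  # length mismatch is an error
  expect_error(call_polymorphisms(pileup_from_counts(zero_counts(4)), cons, 10),
               "length")
})

test_that("an error-free pileup from identical copies yields zero passed calls", {
  sp <- array_spec(copies = 8, unit_length = 300, background = 2000, seed = 501)
  g <- simulate_genome(sp)
  rs <- simulate_reads(g$genome, read_length = 80, depth = 10,
                       error_rate = 0, seed = 502)
  ref <- make_ref(g$truth$unit, id = "unit", regions = NULL)
  aln <- naive_map(rs$reads, ref, max_divergence = 0.05)
  p <- pileup_from_alignments(aln, rs$reads, ref)
  calls <- call_polymorphisms(p, build_consensus(p), depth = 10)
  expect_identical(sum(calls$passed), 0L)
})

test_that("window profiles count positions once and respect edges", {
  calls <- data.frame(position = c(10L, 10L, 20L, 30L, 40L, 50L,
                                   60L, 70L, 80L, 90L, 95L),
                      passed = c(TRUE, TRUE, rep(TRUE, 9)))
  # positions 10..95: position 10 has two passed alleles but counts once
  wp <- window_profile(calls, L = 100L, window = 50L, step = 1L)
  expect_identical(nrow(wp), 51L)
  expect_equal(wp$polymorphic_fraction[wp$start == 1L], 5 / 50)
  # 6 distinct positions (50,60,70,80,90,95) in window 46..95
  expect_equal(wp$polymorphic_fraction[wp$start == 46L], 6 / 50)
  expect_error(window_profile(calls, L = 40L, window = 50L), "window")
  # no passed calls -> all zero; everything polymorphic -> all one
  none <- data.frame(position = integer(0), passed = logical(0))
  expect_true(all(window_profile(none, 60L)$polymorphic_fraction == 0))
  all_p <- data.frame(position = 1:60, passed = TRUE)
  expect_true(all(window_profile(all_p, 60L)$polymorphic_fraction == 1))
  # order invariance
  shuf <- calls[sample(nrow(calls)), ]
  expect_equal(window_profile(shuf, 100L)$polymorphic_fraction,
               wp$polymorphic_fraction)
})

test_that("step-1 window sums satisfy the exact coverage identity", {
  # each passed position p is covered by the windows starting in
  # [max(1, p-w+1), min(p, L-w+1)]; brute force on a small L
  set.seed(503)
  L <- 30L; w <- 7L
  pos <- sort(sample(L, 9))
  calls <- data.frame(position = pos, passed = TRUE)
  wp <- window_profile(calls, L, window = w, step = 1L)
  lhs <- sum(wp$polymorphic_fraction * w)
  rhs <- sum(vapply(pos, function(p)
    min(p, L - w + 1L) - max(1L, p - w + 1L) + 1L, 0L))
  expect_equal(lhs, rhs)
})

test_that("region summary aggregates coding vs noncoding correctly", {
  set.seed(504)
  rg <- data.frame(name = c("18S", "ITS", "26S"),
                   start = c(1L, 41L, 61L), end = c(40L, 60L, 100L),
                   coding = c(TRUE, FALSE, TRUE))
  ref <- make_ref(rand_seq(100), regions = rg)
  # 9 passed positions in coding space (80 bases), 1 in the ITS (20 bases)
  calls <- data.frame(position = c(5L, 10L, 15L, 20L, 65L, 70L, 80L, 90L,
                                   95L, 45L),
                      passed = TRUE)
  rs <- region_summary(calls, ref)
  expect_identical(rs$polymorphic_positions[rs$name == "18S"], 4L)
  expect_identical(rs$polymorphic_positions[rs$name == "ITS"], 1L)
  expect_identical(rs$polymorphic_positions[rs$name == "coding"], 9L)
  expect_identical(rs$polymorphic_positions[rs$name == "noncoding"], 1L)
  expect_gt(rs$density[rs$name == "coding"], rs$density[rs$name == "noncoding"])
  # empty call list -> zero densities
  e <- region_summary(data.frame(position = integer(0), passed = logical(0)), ref)
  expect_true(all(e$density == 0))
})

test_that("variants placed mostly in coding regions give higher coding density", {
  # simulator truth comparison: 80% of variant sites inside the gene region
  set.seed(507)
  rg <- data.frame(name = c("gene", "spacer"), start = c(1L, 201L),
                   end = c(200L, 400L), coding = c(TRUE, FALSE))
  coding_pos <- sample(1:200, 16)
  noncoding_pos <- sample(201:400, 4)
  v <- data.frame(pos = c(coding_pos, noncoding_pos),
                  base = "A", freq = 0.4)
  sp <- array_spec(copies = 15, unit_length = 400, variants = v,
                   background = 3000, seed = 505)
  g <- simulate_genome(sp)
  rs <- simulate_reads(g$genome, read_length = 100, depth = 10,
                       error_rate = 0.01, seed = 506)
  ref <- make_ref(g$truth$unit, regions = rg)
  aln <- naive_map(rs$reads, ref, max_divergence = 0.05)
  p <- pileup_from_alignments(aln, rs$reads, ref)
  D <- genome_depth(sum(nchar(rs$reads)), nchar(g$genome))
  calls <- call_polymorphisms(p, build_consensus(p), D)
  rsum <- region_summary(calls, ref)
  expect_gt(rsum$density[rsum$name == "coding"],
            rsum$density[rsum$name == "noncoding"])
})

test_that("VCF output is minimal but well-formed", {
  cm <- zero_counts(6)
  cm[2, "A"] <- 6L; cm[2, "G"] <- 5L
  cm[4, "T"] <- 6L; cm[4, "del"] <- 5L
  p <- pileup_from_counts(cm)
  ref <- make_ref("ACGTAC", regions = NULL)
  calls <- call_polymorphisms(p, build_consensus(p), depth = 10)
  tmp <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, ref, tmp)
  v <- readLines(tmp)
  expect_true(any(startsWith(v, "##fileformat=VCFv4.2")))
  body <- v[!startsWith(v, "#")]
  expect_identical(length(body), 2L)
  f <- strsplit(body, "\t")
  expect_identical(vapply(f, `[`, "", 2L), c("2", "4"))
  expect_identical(vapply(f, `[`, "", 5L), c("G", "<DEL>"))
  unlink(tmp)
})
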