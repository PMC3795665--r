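# Synthetic genomes with tandem rDNA arrays, shotgun read sets and MA-line
# series, with full truth records, so every pipeline stage can be validated
# without external data.

#' Specification of a synthetic tandem repeat array
#'
#' Describes a genome carrying `copies` near-identical repeat units (one
#' dominant variant plus low-frequency site variants) embedded in
#' single-copy background sequence.
#'
#' @param copies Copy number C of the repeat unit (>= 1).
#' @param unit_length Unit length L in bases (ignored when `unit` given).
#' @param unit Optional explicit unit sequence; `NULL` draws a random one at
#'   generation time.
#' @param variants Optional data.frame with columns `pos` (1-based position
#'   on the unit), `base` (variant nucleotide) and `freq` (carrier frequency
#'   across copies, strictly inside (0, 1): a fixed variant is just the
#'   reference).
#' @param background Total single-copy background length in bases, split
#'   into two flanks around the array.
#' @param seed Optional RNG seed making the generated genome reproducible.
#' @return An `rdna_array_spec`.
#' @export
array_spec <- function(copies, unit_length = 2000L, unit = NULL,
                       variants = NULL, background = 20000L, seed = NULL) {
  if (!is.numeric(copies) || copies < 1L) stop("copies must be >= 1", call. = FALSE)
  if (!is.null(unit)) unit_length <- nchar(unit)
  if (unit_length < 21L) stop("unit_length must be at least 21", call. = FALSE)
  if (!is.null(variants)) {
    stopifnot(all(c("pos", "base", "freq") %in% names(variants)))
    if (any(variants$freq <= 0 | variants$freq >= 1))
      stop("variant frequencies must lie strictly inside (0, 1)", call. = FALSE)
    if (any(variants$pos < 1L | variants$pos > unit_length))
      stop("variant position outside the unit", call. = FALSE)
    if (!all(variants$base %in% DNA_BASES))
      stop("variant bases must be A/C/G/T", call. = FALSE)
    if (anyDuplicated(variants$pos))
      stop("one variant per unit position", call. = FALSE)
  }
  structure(
    list(copies = as.integer(copies), unit_length = as.integer(unit_length),
         unit = unit, variants = variants,
         background = as.integer(background), seed = seed),
    class = "rdna_array_spec")
}

# background with no 20-mer shared with the unit, so single-copy depth is
# unambiguous
make_background <- function(n, unit) {
  if (n <= 0L) return("")
  kmers <- function(s, k) {
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  }
  unit_k <- unique(c(kmers(unit, 20L), kmers(revcomp(unit), 20L)))
  for (try in 1:10) {
    bg <- random_dna(n)
    if (!any(kmers(bg, 20L) %in% unit_k)) return(bg)
  }
  stop("could not generate background free of unit 20-mers", call. = FALSE)
}

#' Generate a genome with a tandem repeat array
#'
#' The genome is background flank + C concatenated unit copies + background
#' flank. Each copy carries each variant independently with its stated
#' frequency. If a variant base equals the unit's base at that position
#' (possible with a random unit), the unit base is rotated to the next
#' nucleotide so the variant is a genuine alternative; the truth record
#' stores the final unit.
#'
#' @param spec An `rdna_array_spec`.
#' @return List with `genome` (string) and `truth` (unit, carrier matrix,
#'   realized frequencies, array coordinates, spec).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "rdna_array_spec"))
  with_seed(spec$seed, {
    unit <- spec$unit
    if (is.null(unit)) unit <- random_dna(spec$unit_length)
    unit <- toupper(unit)
    uc <- chars(unit)
    v <- spec$variants
    carriers <- NULL
    if (!is.null(v) && nrow(v)) {
      clash <- uc[v$pos] == v$base
      if (any(clash))
        uc[v$pos[clash]] <- DNA_BASES[match(uc[v$pos[clash]], DNA_BASES) %% 4L + 1L]
      unit <- paste(uc, collapse = "")
      carriers <- matrix(rbinom(nrow(v) * spec$copies, 1L, rep(v$freq, spec$copies)) == 1L,
                         nrow = nrow(v), ncol = spec$copies)
    }
    copies <- vapply(seq_len(spec$copies), function(j) {
      cc <- uc
      if (!is.null(carriers)) {
        idx <- carriers[, j]
        cc[v$pos[idx]] <- v$base[idx]
      }
      paste(cc, collapse = "")
    }, "")
    half <- spec$background %/% 2L
    bg_left <- make_background(half, unit)
    bg_right <- make_background(spec$background - half, unit)
    array_seq <- paste(copies, collapse = "")
    genome <- paste0(bg_left, array_seq, bg_right)
    list(genome = genome,
         truth = list(
           unit = unit,
           copies = spec$copies,
           carriers = carriers,
           realized_freq = if (is.null(carriers)) NULL else rowMeans(carriers),
           variants = v,
           array_start = nchar(bg_left) + 1L,
           array_end = nchar(bg_left) + nchar(array_seq),
           spec = spec))
  })
}

#' Simulate uniform shotgun reads with substitution errors
#'
#' Reads are placed uniformly over the genome to the target depth, drawn
#' from either strand, and hit with i.i.d. substitution errors at the
#' platform rate (~0.04 for 454-class long reads, ~0.01 for Illumina-class
#' short reads). Indel errors are off: the per-position pileup model is
#' substitution-centric.
#'
#' @param genome Genome string (e.g. from [simulate_genome()]).
#' @param read_length Read length in bases (<= genome length).
#' @param depth Target fold coverage (> 0).
#' @param error_rate Per-base substitution error rate in \[0, 0.25).
#' @param seed Optional RNG seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `start` on the genome, `strand`, `n_errors`).
#' @export
simulate_reads <- function(genome, read_length = 100L, depth = 10,
                           error_rate = 0.01, seed = NULL) {
  G <- nchar(genome)
  if (read_length > G) stop("read_length exceeds genome length", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)", call. = FALSE)
  with_seed(seed, {
    n <- max(1L, as.integer(round(depth * G / read_length)))
    starts <- sample.int(G - read_length + 1L, n, replace = TRUE)
    reads <- substring(genome, starts, starts + read_length - 1L)
    n_err <- integer(n)
    if (error_rate > 0) {
      mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                    nrow = read_length)
      err <- which(runif(length(mat)) < error_rate)
      if (length(err)) {
        cur <- match(mat[err], DNA_BASES)
        ok <- !is.na(cur)
        shift <- sample.int(3L, sum(ok), replace = TRUE)
        mat[err[ok]] <- DNA_BASES[(cur[ok] - 1L + shift) %% 4L + 1L]
        n_err <- tabulate(((err[ok] - 1L) %/% read_length) + 1L, nbins = n)
      }
      reads <- apply(mat, 2L, paste, collapse = "")
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads[strand == "-"] <- revcomp(reads[strand == "-"])
    names(reads) <- sprintf("read_%06d", seq_len(n))
    list(reads = reads,
         truth = data.frame(read_id = names(reads), start = starts,
                            strand = strand, n_errors = n_err,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated reads as FASTQ
#'
#' Quality strings are uniform placeholders (`I`): the simulator's error
#' model is rate-based, and downstream analyses ignore qualities.
#'
#' @param reads Named character vector (e.g. from [simulate_reads()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  lines <- rbind(paste0("@", names(reads)), unname(reads), "+",
                 strrep("I", nchar(reads)))
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Simulate a mutation-accumulation line series
#'
#' Each line's copy number drifts from the progenitor's by
#' `round(rate * generations)` plus integer noise
#' (`round(rnorm(0, sd = sqrt(|rate| * generations) / 2))`, so a zero rate
#' gives exactly the base copy number). All lines share the progenitor's
#' unit sequence and variant table.
#'
#' @param spec Progenitor `rdna_array_spec`.
#' @param rate True copies-per-generation rate (`rate * generations > -C`).
#' @param generations Generations of propagation per line.
#' @param lines Number of MA lines.
#' @param seed Optional RNG seed.
#' @return List with `specs` (one `rdna_array_spec` per line) and `truth`
#'   (data.frame: `line`, `copies`, `true_rate`).
#' @export
simulate_ma_series <- function(spec, rate, generations, lines, seed = NULL) {
  stopifnot(inherits(spec, "rdna_array_spec"))
  if (rate * generations <= -spec$copies)
    stop("rate * generations would exhaust the array", call. = FALSE)
  with_seed(seed, {
    unit <- spec$unit
    if (is.null(unit)) unit <- random_dna(spec$unit_length)
    drift <- as.integer(round(rate * generations))
    noise_sd <- sqrt(abs(rate) * generations) / 2
    noise <- as.integer(round(rnorm(lines, 0, noise_sd)))
    c_new <- spec$copies + drift + noise
    if (any(c_new < 1L))
      stop("noise drove a line's copy number below 1; reduce noise or generations",
           call. = FALSE)
    specs <- lapply(seq_len(lines), function(i)
      array_spec(copies = c_new[i], unit = unit, variants = spec$variants,
                 background = spec$background,
                 seed = if (is.null(spec$seed)) NULL else spec$seed + i))
    list(specs = specs,
         truth = data.frame(line = paste0("MA", seq_len(lines)),
                            copies = c_new,
                            true_rate = (c_new - spec$copies) / generations,
                            stringsAsFactors = FALSE))
  })
}
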