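# Interspecific divergence: global alignment of two consensus repeats and
# classification of divergent sites into transitions, transversions and
# complex events (indels, inversions).

TRANSITIONS <- c("AG", "GA", "CT", "TC")

#' Global pairwise alignment of two consensus sequences
#'
#' Needleman-Wunsch with affine gaps (Gotoh). Default scoring: match +1,
#' mismatch -1, gap open -2, gap extend -0.5 (a gap run of length g scores
#' `gap_open + g * gap_extend`). Trace-back is deterministic: diagonal
#' preferred, then up (gap in `b`), then left.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return An `rdna_alignment`: list with aligned strings `a` and `b`
#'   (equal length, gaps as `-`), `score`, and the scoring `params`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = -2, gap_extend = -0.5) {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty strings", call. = FALSE)
  a <- toupper(a); b <- toupper(b)
  res <- nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  structure(
    list(a = res$a, b = res$b, score = res$score,
         params = c(match = match, mismatch = mismatch,
                    gap_open = gap_open, gap_extend = gap_extend)),
    class = "rdna_alignment")
}

#' @export
print.rdna_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: %d columns, score %.1f\n",
              nchar(x$a), x$score))
  invisible(x)
}

#' Classify divergence events in a pairwise alignment
#'
#' Each mismatch column is a transition (A<->G, C<->T) or transversion
#' (purine <-> pyrimidine). Each maximal gap run is one complex event;
#' adjacent gap runs separated by fewer than `merge_gap` columns merge into
#' a single complex event (columns absorbed in the merge count to that
#' event, not as substitutions). A gapless mismatch run of length >=
#' `min_inversion` whose reverse complement equals the partner's run is
#' re-labelled as one complex (inversion) event. Event positions are
#' 1-based coordinates on the first sequence.
#'
#' @param alignment An `rdna_alignment`.
#' @param merge_gap Gap runs closer than this many columns merge (default 3).
#' @param min_inversion Minimum length of an inversion run (default 4).
#' @return List with `events` (data.frame: `position`, `class`, `detail`,
#'   `length`, `col_start`, `col_end`) and `totals` (named vector over
#'   transition/transversion/complex).
#' @export
classify_events <- function(alignment, merge_gap = 3L, min_inversion = 4L) {
  stopifnot(inherits(alignment, "rdna_alignment"))
  ca <- chars(alignment$a)
  cb <- chars(alignment$b)
  n <- length(ca)
  posA <- cumsum(ca != "-")          # seqA coordinate at or before column
  gap <- ca == "-" | cb == "-"
  mism <- !gap & ca != cb
  ev <- list()

  # maximal gap runs -> complex intervals, merged when separated by fewer
  # than merge_gap columns
  r <- rle(gap)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  gs <- starts[r$values]; ge <- ends[r$values]
  if (length(gs)) {
    ms <- gs[1L]; me <- ge[1L]
    ivs <- list()
    if (length(gs) > 1L) for (k in 2L:length(gs)) {
      if (gs[k] - me - 1L < merge_gap) {
        me <- ge[k]
      } else {
        ivs[[length(ivs) + 1L]] <- c(ms, me); ms <- gs[k]; me <- ge[k]
      }
    }
    ivs[[length(ivs) + 1L]] <- c(ms, me)
    for (iv in ivs) {
      cols <- iv[1L]:iv[2L]
      ga <- sum(ca[cols] == "-"); gb <- sum(cb[cols] == "-")
      detail <- if (ga > 0L && gb > 0L) "indel"
                else if (gb > 0L) "deletion" else "insertion"
      ev[[length(ev) + 1L]] <- data.frame(
        position = max(1L, posA[iv[1L]]),
        class = "complex", detail = detail,
        length = iv[2L] - iv[1L] + 1L,
        col_start = iv[1L], col_end = iv[2L],
        stringsAsFactors = FALSE)
    }
    in_complex <- logical(n)
    for (iv in ivs) in_complex[iv[1L]:iv[2L]] <- TRUE
  } else in_complex <- logical(n)

  # substitution columns outside complex intervals; inversion detection on
  # maximal gapless mismatch runs
  sub <- mism & !in_complex
  r <- rle(sub)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rs <- starts[r$values]; re <- ends[r$values]
  for (k in seq_along(rs)) {
    cols <- rs[k]:re[k]
    runA <- paste(ca[cols], collapse = "")
    runB <- paste(cb[cols], collapse = "")
    if (length(cols) >= min_inversion &&
        all(c(ca[cols], cb[cols]) %in% DNA_BASES) &&
        revcomp(runA) == runB) {
      ev[[length(ev) + 1L]] <- data.frame(
        position = posA[rs[k]], class = "complex", detail = "inversion",
        length = length(cols), col_start = rs[k], col_end = re[k],
        stringsAsFactors = FALSE)
      next
    }
    for (cc in cols) {
      if (!(ca[cc] %in% DNA_BASES) || !(cb[cc] %in% DNA_BASES)) next
      pair <- paste0(ca[cc], cb[cc])
      ev[[length(ev) + 1L]] <- data.frame(
        position = posA[cc],
        class = if (pair %in% TRANSITIONS) "transition" else "transversion",
        detail = paste0(ca[cc], ">", cb[cc]),
        length = 1L, col_start = cc, col_end = cc,
        stringsAsFactors = FALSE)
    }
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(position = integer(0), class = character(0),
               detail = character(0), length = integer(0),
               col_start = integer(0), col_end = integer(0),
               stringsAsFactors = FALSE)
  events <- events[order(events$col_start), , drop = FALSE]
  rownames(events) <- NULL
  totals <- setNames(integer(3), c("transition", "transversion", "complex"))
  tt <- table(events$class)
  totals[names(tt)] <- as.integer(tt)
  list(events = events, totals = totals,
       params = c(merge_gap = merge_gap, min_inversion = min_inversion))
}

#' Per-region divergence class counts
#'
#' Tallies divergence events by annotated region of the first sequence;
#' events outside every region fall in the `unannotated` row.
#'
#' @param events Event data.frame from [classify_events()].
#' @param regions Region data.frame (`name`, `start`, `end`) or an
#'   `rdna_reference`.
#' @return data.frame: `name`, `length`, per-class counts, `density`
#'   (events per base).
#' @export
region_divergence <- function(events, regions) {
  if (inherits(regions, "rdna_reference")) regions <- regions$regions
  if (is.null(regions) || !nrow(regions)) stop("no regions", call. = FALSE)
  classes <- c("transition", "transversion", "complex")
  assign_region <- function(p) {
    i <- which(p >= regions$start & p <= regions$end)
    if (length(i)) regions$name[i[1L]] else "unannotated"
  }
  reg <- vapply(events$position, assign_region, "")
  names_all <- c(regions$name, "unannotated")
  out <- data.frame(name = names_all,
                    length = c(regions$end - regions$start + 1L, NA_integer_),
                    stringsAsFactors = FALSE)
  for (cl in classes)
    out[[cl]] <- vapply(names_all, function(nm)
      sum(reg == nm & events$class == cl), 0L)
  out$total <- as.integer(rowSums(out[classes]))
  out$density <- ifelse(is.na(out$length), NA_real_, out$total / out$length)
  rownames(out) <- NULL
  out
}
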