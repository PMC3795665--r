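# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Alleles tallied in a pileup column
#'
#' The pileup model is 4-allele plus a deletion slot; insertions live in a
#' side table and never enter column depth.
#'
#' @return Character vector `c("A","C","G","T","del")`.
#' @export
pileup_alleles <- function() c(DNA_BASES, "del")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences over A, C, G, T, N.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a single string into a character vector of single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
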