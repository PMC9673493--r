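# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All `simulate_*()` generators route their randomness through this so that
#' a seed argument fully determines the output without clobbering the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Uniform random DNA string of length n (uses current RNG stream).
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All k-mers of a character sequence, as a character vector (1-based starts).
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-DNA characters (first offender: %s)",
                 what, names(x)[bad][1] %||% which(bad)[1]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# Coerce a DNAStringSet / named character vector to named character.
as_named_chr <- function(genomes) {
  if (methods::is(genomes, "XStringSet")) {
    x <- as.character(genomes)
  } else if (is.character(genomes)) {
    x <- genomes
  } else {
    stop("genomes must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("genome sequences must be named")
  }
  if (anyDuplicated(names(x))) stop("duplicate genome ids")
  toupper(x)
}
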