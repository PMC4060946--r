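#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif median cor.test chisq.test setNames
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors, delegating to
#' [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T, possibly N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Coordinates are 0-based half-open everywhere inside the package;
## conversion to 1-based happens only at the SAM boundary.

#' Extract 0-based half-open substrings of a genome sequence
#' @noRd
subseq0 <- function(sequence, start, end) {
  substring(sequence, start + 1L, end)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to give every pipeline stage its own
#' reproducible stream while keeping all randomness tied to one master seed.
#' Result is always a valid 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param offset small integer distinguishing the consumer.
#' @return integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 7919 + 12345) %% 2147483647)
}

#' Distribution constructors for simulator parameters
#'
#' Fragment lengths, chimera deletion lengths and duplication arm lengths are
#' supplied to the simulator as sampling functions `f(n)` returning `n`
#' integer draws. These helpers build the common choices.
#'
#' @param min,max range bounds in bases.
#' @param meanlog,mean,sd distribution parameters in bases.
#' @param value constant value in bases.
#' @return a function of one argument `n`.
#' @name distributions
NULL

#' @rdname distributions
#' @export
dist_loguniform <- function(min, max) {
  stopifnot(min > 0, max >= min)
  function(n) as.integer(round(exp(runif(n, log(min), log(max)))))
}

#' @rdname distributions
#' @export
dist_normal <- function(mean, sd) {
  function(n) as.integer(round(rnorm(n, mean, sd)))
}

#' @rdname distributions
#' @export
dist_constant <- function(value) {
  value <- as.integer(value)
  function(n) rep(value, n)
}
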