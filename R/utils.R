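# Internal helpers shared across modules.

#' @importFrom stats rbinom rmultinom rnorm runif qpois rgeom setNames
#'   aggregate
#' @importFrom utils read.delim write.table
NULL

# Classed error so callers can distinguish "no deletion in this product" from
# genuine misuse.
ds_stop <- function(msg, class, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "delscreen_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

is_dna_string <- function(x) {
  is.character(x) && length(x) == 1L && nchar(x) >= 1L &&
    !grepl("[^ACGT]", x)
}

check_dna <- function(x, what) {
  if (!is_dna_string(x)) {
    ds_stop(sprintf("%s must be a non-empty uppercase A/C/G/T string", what),
            "delscreen_bad_sequence")
  }
  invisible(x)
}

# Longest common prefix / suffix lengths of two strings (byte-wise).
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Round half away from zero to an integer percent
#'
#' Plain `round()` in R rounds half to even; coverage tables in this field
#' report half-up percentages (e.g. 91 for 380/416).
#'
#' @param x numeric vector.
#' @return integer vector, `floor(x + 0.5)`.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Zero-truncated Poisson draw (template count in an aliquot known to contain
# at least one mutant template).
rztpois <- function(n, lambda) {
  lo <- exp(-lambda)
  qpois(runif(n, min = lo, max = 1), lambda)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A base different from all of `avoid`.
other_base <- function(avoid) {
  sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
}
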