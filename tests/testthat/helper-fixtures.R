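# Shared helpers for the test suite. All fixtures are generated in code.

# Amplicon whose whole length is the internal span (for tiny hand-checked
# sequences where primer geometry is irrelevant).
bare_amplicon <- function(seq, id = "amp") {
  amplicon(id, seq, 0L, 0L, nchar(seq), nchar(seq))
}

# The fields that define a canonical call, for identical() comparisons.
allele_fields <- function(a) {
  a[c("left", "right", "insert", "break_class", "ambiguity_width")]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Plant every (L, R, insert) event on one amplicon sequence and check the
# caller against the enumeration oracle. Returns the number of cases run;
# stops at the first disagreement.
check_oracle_agreement <- function(aseq, insert_lengths = 0:3) {
  alen <- nchar(aseq)
  amp <- bare_amplicon(aseq)
  cases <- 0L
  for (L in 0:(alen - 2L)) {
    for (R in (L + 1L):alen) {
      for (ilen in insert_lengths) {
        if (alen - (R - L) + ilen >= alen) next
        ins <- if (ilen > 0L) random_seq(ilen) else ""
        prod <- paste0(substr(aseq, 1L, L), ins, substr(aseq, R + 1L, alen))
        if (nchar(prod) < 1L) next
        dec <- tryCatch(
          enumerate_decompositions(aseq, prod, k_min = 1L),
          delscreen_no_deletion = function(e) NULL)
        cb <- tryCatch(
          call_breakpoint(amp, prod, k_min = 1L),
          delscreen_no_deletion = function(e) NULL)
        if (is.null(dec) != is.null(cb)) {
          stop(sprintf("oracle/caller disagree on no-deletion at L=%d R=%d",
                       L, R))
        }
        if (!is.null(dec)) {
          top <- dec[1L, ]
          if (!(top$left == cb$allele$left && top$right == cb$allele$right &&
                identical(top$insert, cb$allele$insert))) {
            stop(sprintf("canonical mismatch at L=%d R=%d ins=%s", L, R, ins))
          }
          w0 <- sum(nchar(dec$insert) == 0L)
          expected_w <- if (w0 > 0L) w0 else 1L
          if (expected_w != cb$allele$ambiguity_width) {
            stop(sprintf("ambiguity width mismatch at L=%d R=%d", L, R))
          }
        }
        cases <- cases + 1L
      }
    }
  }
  cases
}

# One planted fixture case: amplicon + deletion (+ optional reads).
planted_case <- function(seed, amplicon_length = 600L,
                         deletion_size_range = c(100L, 400L), ...) {
  sp <- fixture_spec(seed = seed, amplicon_length = amplicon_length,
                     deletion_size_range = deletion_size_range, ...)
  plant_deletion(make_amplicon(sp), sp)
}

# reverse complement without reaching into package internals
rc <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}
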