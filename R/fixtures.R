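# Seeded synthetic-data generators: random amplicons with nested primer
# anchors, planted deletions with controlled break class and microhomology,
# and Sanger-like inward read pairs. Ground truth is constructed, never
# derived from the caller, so round-trip tests are meaningful.

#' Specify the synthetic deletion-allele generator
#'
#' Defaults emulate the allele spectrum of PCR deletion screens: deletions
#' of a few hundred bp to ~1.5 kb (always under the 3 kb primer-placement
#' cap), roughly a quarter of events carrying inserted/duplicated sequence
#' (1097 of 4101 characterized deletions), insert sizes mostly a few bases
#' with an ~8% heavy tail of 100 bp - 2 kb inserts (87 of those 1097), and
#' short flank microhomology at the remaining breakpoints.
#'
#' @param seed RNG seed; every generator draw derives from it.
#' @param amplicon_length wild-type amplicon length, bp.
#' @param primer_len primer length; external/internal anchors are placed
#'   `primer_len` and `2 * primer_len` from each end.
#' @param deletion_size_range `c(min, max)` deletion size, bp; max must be
#'   under 3000 and fit the internal span.
#' @param insertion_prob probability a planted event is an insertion break.
#' @param insertion_geom_mean mean of the small-insert size component
#'   (1 + geometric).
#' @param insertion_tail_prob probability an insert is drawn from the
#'   heavy-tail component instead.
#' @param insertion_tail_range uniform range of heavy-tail insert sizes,
#'   capped at 2000 bp.
#' @param microhomology_probs probabilities of microhomology lengths
#'   0..10 at zero-insert breaks (length 0 gives a clean break, length h a
#'   break with `h + 1` equivalent placements).
#' @param read_error_rate substitution error rate of [make_reads()].
#' @return an object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, amplicon_length = 2500L,
                         primer_len = 20L,
                         deletion_size_range = c(200L, 1500L),
                         insertion_prob = 0.27,
                         insertion_geom_mean = 3,
                         insertion_tail_prob = 0.08,
                         insertion_tail_range = c(100L, 2000L),
                         microhomology_probs =
                           c(0.35, 0.25, 0.15, 0.10, 0.06, 0.04,
                             0.02, 0.01, 0.01, 0.005, 0.005),
                         read_error_rate = 0) {
  if (amplicon_length < 8L * primer_len + 50L) {
    ds_stop("amplicon_length too small for nested primer placement",
            "delscreen_config_error")
  }
  if (deletion_size_range[1L] < 1L ||
      deletion_size_range[2L] < deletion_size_range[1L] ||
      deletion_size_range[2L] >= 3000L) {
    ds_stop("deletion_size_range must be within [1, 3000)",
            "delscreen_config_error")
  }
  if (deletion_size_range[2L] > amplicon_length - 4L * primer_len - 2L) {
    ds_stop("deletion_size_range must fit inside the internal primer span",
            "delscreen_config_error")
  }
  if (insertion_tail_range[2L] > 2000L) {
    ds_stop("insert sizes are capped at 2000 bp", "delscreen_config_error")
  }
  if (length(microhomology_probs) != 11L || any(microhomology_probs < 0)) {
    ds_stop("microhomology_probs must give 11 weights for lengths 0..10",
            "delscreen_config_error")
  }
  structure(
    list(seed = as.integer(seed),
         amplicon_length = as.integer(amplicon_length),
         primer_len = as.integer(primer_len),
         deletion_size_range = as.integer(deletion_size_range),
         insertion_prob = insertion_prob,
         insertion_geom_mean = insertion_geom_mean,
         insertion_tail_prob = insertion_tail_prob,
         insertion_tail_range = as.integer(insertion_tail_range),
         microhomology_probs = microhomology_probs /
           sum(microhomology_probs),
         read_error_rate = read_error_rate),
    class = "fixture_spec"
  )
}

#' Generate a random amplicon with nested primer anchors
#'
#' @param spec a [fixture_spec()]; the sequence is reproducible per
#'   `spec$seed`.
#' @return an [amplicon()] with anchors at `primer_len`/`2*primer_len`
#'   from each end.
#' @export
make_amplicon <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$amplicon_length
  p <- spec$primer_len
  amplicon(sprintf("synamp%06d", spec$seed), random_dna(n),
           ext_left = p, int_left = 2L * p,
           int_right = n - 2L * p, ext_right = n - p)
}

# Engineer the bases around a planted zero-insert break so that the
# microhomology length - and hence the placement count and canonical L -
# is exactly as requested. 1-based indexing on the sequence vector.
engineer_microhomology <- function(bases, L, R, h) {
  if (h > 0L) {
    bases[(R - h + 1L):R] <- bases[(L - h + 1L):L]
  }
  # stop leftward extension of the homology run
  if (L - h >= 1L && bases[R - h] == bases[L - h]) {
    bases[R - h] <- other_base(bases[L - h])
  }
  # stop rightward extension (would shift the canonical L)
  if (R + 1L <= length(bases) && bases[R + 1L] == bases[L + 1L]) {
    bases[R + 1L] <- other_base(bases[L + 1L])
  }
  bases
}

#' Plant a deletion allele in an amplicon
#'
#' Draws a deletion size and break class, engineers the local sequence so
#' the planted event's canonical form is known by construction (flank
#' microhomology of length `h` gives exactly `h + 1` equivalent placements;
#' insert ends are forced to differ from the adjacent flank bases so the
#' planted `(left, right, insert)` is already flank-maximal), and returns
#' the ground truth with the deletion-product sequence.
#'
#' The amplicon sequence may be base-edited around the breakpoints to
#' enforce the drawn microhomology, so the returned `amplicon` replaces the
#' input for all downstream calling.
#'
#' @param amp an [amplicon()] (typically from [make_amplicon()]).
#' @param spec a [fixture_spec()].
#' @param seed RNG seed for the event draw (default `spec$seed + 1`).
#' @param allele_id identifier for the truth allele.
#' @return list with `amplicon` (possibly edited), `truth` (a canonical
#'   [deletion_allele()]), and `product` (the deletion product sequence).
#' @export
plant_deletion <- function(amp, spec, seed = spec$seed + 1L,
                           allele_id = "planted1") {
  stopifnot(inherits(amp, "amplicon"), inherits(spec, "fixture_spec"))
  set.seed(seed)
  n <- nchar(amp$seq)
  rng <- spec$deletion_size_range
  lo_size <- rng[1L]
  hi_size <- min(rng[2L], internal_span(amp) - 2L)
  if (hi_size < lo_size) {
    ds_stop("requested deletion size exceeds the internal span",
            "delscreen_config_error")
  }
  size <- if (hi_size == lo_size) lo_size else
    sample(lo_size:hi_size, 1L)
  # keep a margin inside the internal span so guard bases stay clear of
  # the primer anchors and sequence ends
  margin <- 12L
  L_lo <- amp$int_left + margin
  L_hi <- amp$int_right - size - margin
  if (L_hi < L_lo) {
    ds_stop("deletion does not fit inside the internal primer span",
            "delscreen_config_error")
  }
  L <- if (L_hi == L_lo) L_lo else sample(L_lo:L_hi, 1L)
  R <- L + size
  bases <- strsplit(amp$seq, "", fixed = TRUE)[[1L]]
  if (runif(1L) < spec$insertion_prob) {
    ins_len <- if (runif(1L) < spec$insertion_tail_prob) {
      sample(spec$insertion_tail_range[1L]:spec$insertion_tail_range[2L], 1L)
    } else {
      min(1L + rgeom(1L, 1 / spec$insertion_geom_mean), 2000L)
    }
    # the product must remain shorter than the amplicon (deletions are
    # detected as faster-running bands), so the net change stays negative
    ins_len <- min(ins_len, size - 1L)
    ins <- strsplit(random_dna(ins_len), "", fixed = TRUE)[[1L]]
    # flank-maximal canonical form: insert must not extend either flank
    # (a 1-bp insert must differ from both adjacent bases at once)
    if (ins_len == 1L) {
      if (ins[1L] %in% c(bases[L + 1L], bases[R])) {
        ins[1L] <- other_base(c(bases[L + 1L], bases[R]))
      }
    } else {
      if (ins[1L] == bases[L + 1L]) ins[1L] <- other_base(bases[L + 1L])
      if (ins[ins_len] == bases[R]) ins[ins_len] <- other_base(bases[R])
    }
    insert <- paste(ins, collapse = "")
    truth <- deletion_allele(allele_id, amp$id, L, R, insert = insert,
                             break_class = "insertion", seq_length = n)
  } else {
    h <- sample(0:10, 1L, prob = spec$microhomology_probs)
    h <- min(h, size - 1L)  # homology cannot swallow the whole deletion
    bases <- engineer_microhomology(bases, L, R, h)
    truth <- deletion_allele(allele_id, amp$id, L, R,
                             break_class = if (h == 0L) "clean" else
                               "ambiguous",
                             ambiguity_width = h + 1L, seq_length = n)
  }
  amp2 <- amplicon(amp$id, paste(bases, collapse = ""), amp$ext_left,
                   amp$int_left, amp$int_right, amp$ext_right)
  list(amplicon = amp2, truth = truth,
       product = reconstruct_product(amp2, truth))
}

#' Generate an inward-facing Sanger-like read pair from a product
#'
#' The left read is the product prefix; the right read is the
#' reverse-complement of the product suffix (as sequenced from the right
#' internal primer). Substitution errors are planted independently per
#' base; no indel errors are generated.
#'
#' @param product deletion-product sequence.
#' @param read_len length of each read; the two reads must jointly cover
#'   the product (`2 * read_len >= nchar(product)`).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return list `left_read`, `right_read`.
#' @export
make_reads <- function(product, read_len, error_rate = 0, seed = NULL) {
  check_dna(product, "product")
  np <- nchar(product)
  if (read_len > np) read_len <- np
  if (2L * read_len < np) {
    ds_stop("reads do not jointly cover the product (coverage gap)",
            "delscreen_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  mutate <- function(x) {
    if (error_rate <= 0) return(x)
    b <- strsplit(x, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(b)) < error_rate)
    for (i in hit) b[i] <- other_base(b[i])
    paste(b, collapse = "")
  }
  left <- substr(product, 1L, read_len)
  right <- revcomp(substr(product, np - read_len + 1L, np))
  list(left_read = mutate(left), right_read = mutate(right))
}
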