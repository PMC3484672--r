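# Core domain types: amplicons with nested primer anchors, minimal exon gene
# models, and deletion alleles, plus the silent-allele and size rules applied
# when deciding whether an isolated deletion counts as a gene knockout.
#
# Coordinates are 0-based half-open everywhere internally; report writers emit
# 1-based inclusive positions and say so in their headers.

#' Construct an amplicon with nested primer anchors
#'
#' An amplicon is the genomic target region amplified by a nested PCR primer
#' set: external primers drive the first-round reaction, internal primers the
#' second; the internal span is the product scored on gels and is the interval
#' within which deletions can be detected.
#'
#' @param id amplicon identifier.
#' @param seq uppercase A/C/G/T sequence of the wild-type region.
#' @param ext_left,int_left,int_right,ext_right primer anchor positions,
#'   0-based, satisfying
#'   `0 <= ext_left <= int_left < int_right <= ext_right <= nchar(seq)`.
#' @return an object of class `"amplicon"`.
#' @examples
#' amp <- amplicon("amp1", paste(rep("ACGT", 30), collapse = ""),
#'                 ext_left = 10, int_left = 20, int_right = 100,
#'                 ext_right = 110)
#' internal_span(amp)
#' @export
amplicon <- function(id, seq, ext_left, int_left, int_right, ext_right) {
  check_dna(seq, "amplicon seq")
  pos <- c(ext_left = ext_left, int_left = int_left,
           int_right = int_right, ext_right = ext_right)
  if (any(pos != floor(pos)) || any(pos < 0)) {
    ds_stop("primer anchors must be non-negative integers",
            "delscreen_bad_amplicon")
  }
  n <- nchar(seq)
  if (!(0 <= ext_left && ext_left <= int_left && int_left < int_right &&
        int_right <= ext_right && ext_right <= n)) {
    ds_stop("primer anchors must satisfy 0 <= ext_left <= int_left < int_right <= ext_right <= length(seq)",
            "delscreen_bad_amplicon")
  }
  structure(
    list(id = as.character(id), seq = seq,
         ext_left = as.integer(ext_left), int_left = as.integer(int_left),
         int_right = as.integer(int_right), ext_right = as.integer(ext_right)),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon %s> %d bp, internal span [%d,%d) = %d bp\n",
              x$id, nchar(x$seq), x$int_left, x$int_right, internal_span(x)))
  invisible(x)
}

#' Internal (scored) span of an amplicon in bp
#' @param amp an [amplicon()].
#' @return integer, `int_right - int_left`.
#' @export
internal_span <- function(amp) {
  stopifnot(inherits(amp, "amplicon"))
  amp$int_right - amp$int_left
}

#' Construct a minimal exon-level gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (or data.frame) of `[start, end)` exon
#'   intervals in chromosome coordinates (0-based half-open), sorted and
#'   non-overlapping.
#' @return an object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", exons) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L) {
    ds_stop("exons must be an n x 2 matrix of [start, end) intervals",
            "delscreen_bad_gene_model")
  }
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"])) {
    ds_stop("every exon must have end > start", "delscreen_bad_gene_model")
  }
  if (is.unsorted(exons[, "start"], strictly = TRUE) ||
      (nrow(exons) > 1L &&
       any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))) {
    ds_stop("exons must be sorted and non-overlapping",
            "delscreen_bad_gene_model")
  }
  if (!strand %in% c("+", "-")) {
    ds_stop("strand must be '+' or '-'", "delscreen_bad_gene_model")
  }
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s%s, %d exon(s), span [%d,%d)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons[, "start"]), max(x$exons[, "end"])))
  invisible(x)
}

#' Construct a deletion allele
#'
#' Breakpoints fall into three classes: `clean` (a unique zero-insert
#' placement), `ambiguous` (microhomology shared by the two flanks allows
#' several equivalent placements; `ambiguity_width` counts them), and
#' `insertion` (novel bases between the flanks). Class and fields must agree:
#' an insertion break has a non-empty insert; an ambiguous break has an empty
#' insert and `ambiguity_width >= 2`; a clean break has an empty insert and
#' `ambiguity_width == 1`.
#'
#' @param allele_id allele identifier.
#' @param amplicon_id identifier of the amplicon the breakpoints refer to.
#' @param left,right deletion interval `[left, right)`, 0-based half-open in
#'   amplicon coordinates.
#' @param insert inserted sequence between the flanks (`""` if none).
#' @param break_class one of `"clean"`, `"ambiguous"`, `"insertion"`.
#' @param ambiguity_width number of equivalent zero-insert placements
#'   (1 for clean and insertion breaks).
#' @param seq_length optional amplicon length to bound-check `right` against.
#' @return an object of class `"deletion_allele"`.
#' @export
deletion_allele <- function(allele_id, amplicon_id, left, right, insert = "",
                            break_class = c("clean", "ambiguous", "insertion"),
                            ambiguity_width = 1L, seq_length = NULL) {
  break_class <- match.arg(break_class)
  left <- as.integer(left); right <- as.integer(right)
  ambiguity_width <- as.integer(ambiguity_width)
  if (!(0L <= left && left < right)) {
    ds_stop("need 0 <= left < right", "delscreen_bad_allele")
  }
  if (!is.null(seq_length) && right > seq_length) {
    ds_stop("right breakpoint beyond amplicon end", "delscreen_bad_allele")
  }
  if (!is.character(insert) || length(insert) != 1L ||
      (nzchar(insert) && grepl("[^ACGT]", insert))) {
    ds_stop("insert must be '' or an A/C/G/T string", "delscreen_bad_allele")
  }
  ok <- switch(break_class,
    clean     = !nzchar(insert) && ambiguity_width == 1L,
    ambiguous = !nzchar(insert) && ambiguity_width >= 2L,
    insertion = nzchar(insert) && ambiguity_width == 1L
  )
  if (!ok) {
    ds_stop(sprintf("fields inconsistent with break_class '%s'", break_class),
            "delscreen_bad_allele")
  }
  structure(
    list(allele_id = as.character(allele_id),
         amplicon_id = as.character(amplicon_id),
         left = left, right = right, insert = insert,
         break_class = break_class, ambiguity_width = ambiguity_width),
    class = "deletion_allele"
  )
}

#' @export
print.deletion_allele <- function(x, ...) {
  cat(sprintf("<deletion_allele %s> %s:[%d,%d) %d bp, %s%s%s\n",
              x$allele_id, x$amplicon_id, x$left, x$right, deletion_size(x),
              x$break_class,
              if (x$break_class == "ambiguous")
                sprintf(" (width %d)", x$ambiguity_width) else "",
              if (nzchar(x$insert))
                sprintf(" +%dbp insert", nchar(x$insert)) else ""))
  invisible(x)
}

#' Deletion size in bp
#' @param allele a [deletion_allele()].
#' @return integer, `right - left`.
#' @export
deletion_size <- function(allele) {
  stopifnot(inherits(allele, "deletion_allele"))
  allele$right - allele$left
}

#' Classify a deletion as silent or exonic
#'
#' A deletion that does not extend across at least one exon boundary removes
#' only intronic (or flanking) sequence and is treated as a silent allele, not
#' a gene knockout. The predicate: the allele is `exonic` iff the open deleted
#' interval, lifted to chromosome coordinates, strictly contains at least one
#' exon start or exon end; a deletion that merely abuts a boundary is silent.
#' The rule only looks at boundary coordinates, so it is invariant under
#' strand flips.
#'
#' @param allele a [deletion_allele()].
#' @param gene a [gene_model()] on the same chromosome as the amplicon.
#' @param amplicon_offset chromosomal position (0-based) of amplicon base 0.
#' @return `"silent"` or `"exonic"`.
#' @examples
#' gm <- gene_model("g", "I", "+", rbind(c(0, 100), c(200, 300)))
#' al <- deletion_allele("a", "amp", 120, 180, break_class = "clean")
#' classify_silent(al, gm, amplicon_offset = 0)  # intron-only -> silent
#' @export
classify_silent <- function(allele, gene, amplicon_offset = 0L) {
  stopifnot(inherits(allele, "deletion_allele"), inherits(gene, "gene_model"))
  dl <- amplicon_offset + allele$left
  dr <- amplicon_offset + allele$right
  span_lo <- min(gene$exons[, "start"])
  span_hi <- max(gene$exons[, "end"])
  if (dr <= span_lo || dl >= span_hi) {
    ds_stop("deletion interval lies outside the gene span",
            "delscreen_out_of_range")
  }
  boundaries <- c(gene$exons[, "start"], gene$exons[, "end"])
  if (any(boundaries > dl & boundaries < dr)) "exonic" else "silent"
}

#' Check a deletion against the primer-placement size bound
#'
#' Deletions recoverable by a nested primer set are bounded by the internal
#' span, and by design of primer placement all are under 3 kb. Returns `FALSE`
#' (with an optional warning) rather than erroring, since the bound derives
#' from primer geometry, not from the calling algorithm.
#'
#' @param allele a [deletion_allele()].
#' @param amp the [amplicon()] it was called on.
#' @param warn emit a warning when the bound is violated.
#' @return logical: `deletion_size < internal span` and `< 3000`.
#' @export
check_size_bound <- function(allele, amp, warn = FALSE) {
  stopifnot(inherits(amp, "amplicon"))
  sz <- deletion_size(allele)
  ok <- sz < internal_span(amp) && sz < 3000L
  if (!ok && warn) {
    warning(sprintf("deletion %s: size %d violates the primer-placement bound",
                    allele$allele_id, sz))
  }
  ok
}

#' Check allele size against an observed gel band shift
#'
#' The deletion product runs faster than the wild-type internal band; the
#' predicted product length is `internal span - deletion size + insert
#' length`. The call is consistent with the gel iff the predicted length is
#' within `tolerance_frac` (relative to predicted) of the observed band.
#'
#' @param allele a [deletion_allele()].
#' @param amp the [amplicon()].
#' @param observed_product_bp band size read off the gel, bp.
#' @param tolerance_frac relative tolerance (gel sizing is coarse; 0.15 is a
#'   typical slab-gel allowance). Zero demands exact agreement.
#' @return logical.
#' @export
check_band_shift <- function(allele, amp, observed_product_bp,
                             tolerance_frac = 0.15) {
  stopifnot(inherits(amp, "amplicon"))
  if (!is.numeric(observed_product_bp) || observed_product_bp <= 0) {
    ds_stop("observed_product_bp must be positive", "delscreen_config_error")
  }
  if (!is.numeric(tolerance_frac) || tolerance_frac < 0) {
    ds_stop("tolerance_frac must be >= 0", "delscreen_config_error")
  }
  predicted <- internal_span(amp) - deletion_size(allele) + nchar(allele$insert)
  abs(predicted - observed_product_bp) <= tolerance_frac * predicted
}
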