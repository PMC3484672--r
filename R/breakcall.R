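# Deletion breakpoint calling and normalization.
#
# A deletion product aligned to its wild-type amplicon decomposes as
#   product = amplicon[0:L] + insert + amplicon[R:end],  L < R.
# When the two flanks share microhomology the same product admits several
# zero-insert placements; when novel bases sit between the flanks no
# zero-insert placement exists. The reporting standard used here for the
# genome-browser display of deletions is:
#   * among zero-insert placements, take the rightmost possible left
#     breakpoint (microhomology bases are pushed onto the left flank);
#     unique placement = "clean", >= 2 placements = "ambiguous";
#   * otherwise minimize the insert (equivalently maximize the matched
#     flanks), then take the rightmost L = "insertion".
# enumerate_decompositions() is the brute-force enumeration of every valid
# (L, R, insert); call_breakpoint() computes the canonical choice directly
# from longest-common-prefix/suffix arithmetic. The two agree by the ordering
# defined on decompositions, which the test suite checks exhaustively.

#' Enumerate all decompositions of a deletion product against its amplicon
#'
#' Brute-force enumeration of every `(L, R, insert)` with
#' `product == substr(amplicon, 1, L) + insert + substr(amplicon, R+1, end)`
#' and `L < R`. Positions are 0-based half-open. This is the reference
#' oracle behind the canonical caller; it is quadratic in the flank lengths
#' and intended for amplicon-scale sequences.
#'
#' @param amplicon_seq wild-type amplicon sequence (uppercase ACGT).
#' @param product_seq deletion product sequence, strictly shorter.
#' @param k_min minimum length of the maximal shared prefix and suffix for
#'   the product to be accepted as a deletion product of this amplicon at
#'   all; below it a no-deletion-found error is raised.
#' @param max_insert drop decompositions whose insert exceeds this length
#'   (`Inf` keeps all).
#' @return data.frame with columns `left`, `right`, `insert`,
#'   `matched_left`, `matched_right`, sorted by (insert length, decreasing
#'   matched flank total, decreasing `left`), so the canonical decomposition
#'   is always row 1.
#' @seealso [call_breakpoint()] for the closed-form canonical call.
#' @examples
#' enumerate_decompositions("AAAGCTGCTTT", "AAAGCTTT",
#'                          k_min = 1, max_insert = 0)
#' @export
enumerate_decompositions <- function(amplicon_seq, product_seq, k_min = 10L,
                                     max_insert = Inf) {
  check_dna(amplicon_seq, "amplicon_seq")
  check_dna(product_seq, "product_seq")
  na <- nchar(amplicon_seq); np <- nchar(product_seq)
  if (np >= na) {
    ds_stop("product is not shorter than the amplicon: no deletion",
            "delscreen_no_deletion")
  }
  maxP <- lcp_len(amplicon_seq, product_seq)
  maxS <- lcs_len(amplicon_seq, product_seq)
  if (maxP < k_min || maxS < k_min) {
    ds_stop(sprintf(
      "product does not anchor on the amplicon (shared prefix %d, suffix %d, need >= %d)",
      maxP, maxS, k_min), "delscreen_no_deletion")
  }
  Lv <- 0:maxP
  mr_hi <- pmin(maxS, np - Lv, na - Lv - 1L)   # insert >= 0 and R > L
  n_mr <- pmax(mr_hi + 1L, 0L)
  L <- rep.int(Lv, n_mr)
  mr <- sequence(n_mr) - 1L
  keep <- (np - L - mr) <= max_insert
  L <- L[keep]; mr <- mr[keep]
  if (length(L) == 0L) {
    ds_stop("no decomposition satisfies the constraints",
            "delscreen_no_deletion")
  }
  dec <- data.frame(
    left = L,
    right = na - mr,
    insert = substring(product_seq, L + 1L, np - mr),
    matched_left = L,
    matched_right = mr,
    stringsAsFactors = FALSE
  )
  ins_len <- np - L - mr
  dec <- dec[order(ins_len, -(dec$matched_left + dec$matched_right),
                   -dec$left), , drop = FALSE]
  rownames(dec) <- NULL
  dec
}

# Shared core: canonical decomposition from prefix/suffix arithmetic.
canonical_decomposition <- function(amplicon_seq, product_seq, k_min) {
  na <- nchar(amplicon_seq); np <- nchar(product_seq)
  if (np >= na) {
    ds_stop("product is not shorter than the amplicon: no deletion",
            "delscreen_no_deletion")
  }
  maxP <- lcp_len(amplicon_seq, product_seq)
  maxS <- lcs_len(amplicon_seq, product_seq)
  if (maxP < k_min || maxS < k_min) {
    ds_stop(sprintf(
      "product does not anchor on the amplicon (shared prefix %d, suffix %d, need >= %d)",
      maxP, maxS, k_min), "delscreen_no_deletion")
  }
  lo <- max(0L, np - maxS)           # smallest valid zero-insert L
  hi <- min(maxP, np)                # largest valid zero-insert L
  if (lo <= hi) {
    L <- hi
    placements <- cbind(left = lo:hi, right = (na - np) + (lo:hi))
    list(left = L, right = na - (np - L), insert = "",
         width = hi - lo + 1L, placements = placements)
  } else {
    L <- maxP
    R <- na - maxS
    list(left = L, right = R,
         insert = substr(product_seq, L + 1L, np - maxS),
         width = 1L, placements = cbind(left = L, right = R))
  }
}

#' Call and normalize a deletion breakpoint from a product sequence
#'
#' Aligns the deletion product to the wild-type amplicon, chooses the
#' canonical decomposition (see [enumerate_decompositions()] for the
#' ordering), classifies the break, and returns a report carrying the
#' allele, the discrete flanking sequences, and every equivalent placement.
#'
#' @param amp an [amplicon()].
#' @param product_seq assembled deletion product sequence.
#' @param allele_id identifier given to the called allele.
#' @param k_min minimum anchor (maximal shared prefix/suffix) length; below
#'   it the product is not accepted as a deletion product.
#' @return an object of class `"breakpoint_report"`: a list with `allele`
#'   (a [deletion_allele()]), `flank_left`, `flank_right`, `all_placements`
#'   (matrix with one row per equivalent zero-insert placement), and
#'   `amplicon_id`.
#' @examples
#' amp <- amplicon("a", "AAAGCTGCTTT", 0, 0, 11, 11)
#' rep <- call_breakpoint(amp, "AAAGCTTT", k_min = 1)
#' rep$allele$break_class       # "ambiguous"
#' rep$allele$ambiguity_width   # 4
#' @export
call_breakpoint <- function(amp, product_seq, allele_id = "allele1",
                            k_min = 10L) {
  stopifnot(inherits(amp, "amplicon"))
  check_dna(product_seq, "product_seq")
  dec <- canonical_decomposition(amp$seq, product_seq, k_min)
  cls <- if (nzchar(dec$insert)) "insertion"
         else if (dec$width >= 2L) "ambiguous" else "clean"
  allele <- deletion_allele(allele_id, amp$id, dec$left, dec$right,
                            insert = dec$insert, break_class = cls,
                            ambiguity_width = dec$width,
                            seq_length = nchar(amp$seq))
  report <- structure(
    list(allele = allele,
         flank_left = substr(amp$seq, 1L, dec$left),
         flank_right = substr(amp$seq, dec$right + 1L, nchar(amp$seq)),
         all_placements = dec$placements,
         amplicon_id = amp$id,
         k_min = as.integer(k_min)),
    class = "breakpoint_report"
  )
  stopifnot(identical(reconstruct_product(amp, allele), product_seq))
  report
}

#' @export
print.breakpoint_report <- function(x, ...) {
  print(x$allele)
  cat(sprintf("  placements: %d; flanks %d/%d bp\n",
              nrow(x$all_placements), nchar(x$flank_left),
              nchar(x$flank_right)))
  invisible(x)
}

#' Reconstruct the deletion product implied by an allele
#'
#' @param amp the [amplicon()].
#' @param allele a [deletion_allele()] on that amplicon.
#' @return the product sequence `amplicon[0:left] + insert + amplicon[right:]`.
#' @export
reconstruct_product <- function(amp, allele) {
  stopifnot(inherits(amp, "amplicon"), inherits(allele, "deletion_allele"))
  paste0(substr(amp$seq, 1L, allele$left), allele$insert,
         substr(amp$seq, allele$right + 1L, nchar(amp$seq)))
}

#' Normalize a breakpoint report to the canonical form
#'
#' Re-derives the canonical placement from the product sequence the report
#' reconstructs. Reports produced by [call_breakpoint()] are already
#' canonical, so the operation is idempotent; reports built from an
#' arbitrary (e.g. leftmost) placement are rewritten to rightmost-L /
#' minimal-insert form.
#'
#' @param report a `"breakpoint_report"`.
#' @param amp the [amplicon()] the report refers to.
#' @return a canonical `"breakpoint_report"` with the same `allele_id`.
#' @export
normalize_report <- function(report, amp) {
  stopifnot(inherits(report, "breakpoint_report"))
  product <- reconstruct_product(amp, report$allele)
  call_breakpoint(amp, product, allele_id = report$allele$allele_id,
                  k_min = report$k_min %||% 10L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge two inward-facing Sanger reads into one product-sequence estimate.
# left covers the product prefix; right is given on the product strand.
# Returns list(seq, conflicts).
merge_reads <- function(left, right, min_overlap, max_mismatch_rate) {
  nl <- nchar(left); nr <- nchar(right)
  if (min(nl, nr) < min_overlap) return(NULL)
  rl <- charToRaw(left); rr <- charToRaw(right)
  best <- NULL
  for (k in min(nl, nr):min_overlap) {
    a <- rl[(nl - k + 1L):nl]
    b <- rr[1:k]
    mm <- sum(a != b)
    if (mm <= max_mismatch_rate * k) {
      best <- list(k = k, mm = mm)
      break
    }
  }
  if (is.null(best)) return(NULL)
  k <- best$k
  conflicts <- 0L
  if (best$mm > 0L) {
    # Resolve each disagreement toward the read with the longer exact match
    # run flanking it: the left read is trusted near its 5' anchor, the
    # right read near its 3' anchor.
    a <- rl[(nl - k + 1L):nl]
    b <- rr[1:k]
    for (i in which(a != b)) {
      left_run <- 0L
      j <- i - 1L
      while (j >= 1L && a[j] == b[j]) { left_run <- left_run + 1L; j <- j - 1L }
      right_run <- 0L
      j <- i + 1L
      while (j <= k && a[j] == b[j]) { right_run <- right_run + 1L; j <- j + 1L }
      # bases to the left of the overlap all come from the left read; count
      # them into its run, and symmetrically for the right read
      left_run <- left_run + (nl - k)
      right_run <- right_run + (nr - k)
      if (right_run > left_run) a[i] <- b[i]
      conflicts <- conflicts + 1L
    }
    rl[(nl - k + 1L):nl] <- a
  }
  merged <- paste0(rawToChar(rl), rawToChar(rr[seq_len(nr)[-seq_len(k)]]))
  list(seq = merged, conflicts = conflicts)
}

#' Call a breakpoint from a pair of Sanger reads off the internal primers
#'
#' Deletion products are sequenced inward from both internal primers; the
#' left read reports the product prefix on the reference strand and the
#' right read the product suffix on the opposite strand (it is
#' reverse-complemented here, with auto-detection in case it was supplied
#' already on the reference strand). The reads are merged over their best
#' overlap and the merged estimate is passed to [call_breakpoint()]. With
#' error-free reads spanning the break the result is identical to calling
#' on the true product.
#'
#' When reads disagree inside the overlap, each conflicting base is taken
#' from the read with the longer exact match run around it; the number of
#' resolved conflicts is recorded on the report as attribute
#' `"merge_conflicts"`.
#'
#' @param amp an [amplicon()].
#' @param left_read read from the left internal primer (product prefix).
#' @param right_read read from the right internal primer (product suffix,
#'   normally as sequenced, i.e. reverse-complement of the product).
#' @param max_mismatch_rate maximum tolerated mismatch fraction in the read
#'   overlap; 0 demands an exact merge.
#' @param min_overlap minimum read overlap accepted by the merge.
#' @param allele_id,k_min passed to [call_breakpoint()].
#' @return a `"breakpoint_report"`.
#' @export
call_from_reads <- function(amp, left_read, right_read,
                            max_mismatch_rate = 0, min_overlap = 10L,
                            allele_id = "allele1", k_min = 10L) {
  stopifnot(inherits(amp, "amplicon"))
  check_dna(left_read, "left_read")
  check_dna(right_read, "right_read")
  if (max_mismatch_rate < 0 || max_mismatch_rate >= 1) {
    ds_stop("max_mismatch_rate must be in [0, 1)", "delscreen_config_error")
  }
  candidates <- list(revcomp(right_read), right_read)
  merged <- NULL
  for (rs in candidates) {
    merged <- merge_reads(left_read, rs, min_overlap, max_mismatch_rate)
    if (!is.null(merged)) break
  }
  if (is.null(merged)) {
    # distinguish "would merge at a laxer threshold" from "no overlap at all"
    relaxed <- merge_reads(left_read, candidates[[1L]], min_overlap, 0.3)
    if (is.null(relaxed)) relaxed <- merge_reads(left_read, candidates[[2L]],
                                                 min_overlap, 0.3)
    if (!is.null(relaxed)) {
      ds_stop("read overlap mismatch rate above max_mismatch_rate",
              "delscreen_low_quality")
    }
    ds_stop("reads fail to overlap: cannot assemble a product sequence",
            "delscreen_assembly_error")
  }
  report <- call_breakpoint(amp, merged$seq, allele_id = allele_id,
                            k_min = k_min)
  attr(report, "merge_conflicts") <- merged$conflicts
  report
}

#' Tabulate breakpoint reports
#'
#' @param reports a `"breakpoint_report"` or list of them.
#' @param flank_bp number of flanking bases to include (each side).
#' @return data.frame with 1-based inclusive `left`/`right` columns
#'   (WormBase-style display coordinates: `left` is the last retained base
#'   of the left flank, `right` the first retained base of the right flank
#'   minus... see column comments in the TSV header written by
#'   [write_breakpoint_tsv()]); internal 0-based fields are also kept.
#' @export
breakpoint_table <- function(reports, flank_bp = 30L) {
  if (inherits(reports, "breakpoint_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    a <- r$allele
    data.frame(
      allele_id = a$allele_id,
      amplicon_id = a$amplicon_id,
      left_1based = a$left + 1L,     # first deleted base, 1-based inclusive
      right_1based = a$right,        # last deleted base, 1-based inclusive
      left0 = a$left, right0 = a$right,
      size = deletion_size(a),
      break_class = a$break_class,
      ambiguity_width = a$ambiguity_width,
      insert = a$insert,
      flank_left = substr(r$flank_left,
                          max(1L, nchar(r$flank_left) - flank_bp + 1L),
                          nchar(r$flank_left)),
      flank_right = substr(r$flank_right, 1L,
                           min(flank_bp, nchar(r$flank_right))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a breakpoint report TSV
#'
#' @param reports list of `"breakpoint_report"` objects.
#' @param path output path.
#' @param flank_bp flanking bases per side (>= 30 by reporting convention).
#' @return `path`, invisibly.
#' @export
write_breakpoint_tsv <- function(reports, path, flank_bp = 30L) {
  tab <- breakpoint_table(reports, flank_bp = flank_bp)
  tab <- tab[, c("allele_id", "amplicon_id", "left_1based", "right_1based",
                 "size", "break_class", "ambiguity_width", "insert",
                 "flank_left", "flank_right")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(
    "# deletion breakpoint report;",
    "coordinates 1-based inclusive (first/last deleted base)"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called deletions as a BED track
#'
#' @param reports list of `"breakpoint_report"` objects.
#' @param path output path.
#' @param offsets named vector of chromosomal offsets per amplicon id
#'   (default 0: amplicon-local coordinates).
#' @param chrom named vector of chromosome names per amplicon id (default:
#'   the amplicon id itself).
#' @return `path`, invisibly.
#' @export
write_deletions_bed <- function(reports, path, offsets = NULL, chrom = NULL) {
  tab <- breakpoint_table(reports)
  off <- if (is.null(offsets)) rep(0L, nrow(tab)) else
    as.integer(offsets[tab$amplicon_id])
  chr <- if (is.null(chrom)) tab$amplicon_id else
    as.character(chrom[tab$amplicon_id])
  bed <- data.frame(chrom = chr, start = tab$left0 + off,
                    end = tab$right0 + off, name = tab$allele_id,
                    score = tab$ambiguity_width,
                    strand = ".", stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: coordinates 0-based half-open", con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
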