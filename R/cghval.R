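# Deletion validation: array-CGH copy-loss calling on probe log2-ratio
# tracks, and the diagnostic-PCR presence/absence test.
#
# The loss caller is a deliberate run/threshold method rather than a full
# segmentation: heterozygous (one-copy) losses sit near log2 = -1 and
# homozygous (two-copy) losses at the signal floor, so maximal runs of
# consecutive probes below a het cutoff, long enough to be trusted, are
# called and graded by their run mean against a hom cutoff.

#' Simulate an aCGH probe track with planted deletions
#'
#' Probes tile the genome at fixed spacing. Neutral probes have mean log2
#' ratio 0; probes inside a heterozygous (one-copy) loss have mean -1, and
#' probes inside a homozygous (two-copy) loss have mean -4, a finite proxy
#' for the hybridization signal floor - only the ordering hom << het < 0
#' matters to the caller. Per-probe noise is Gaussian.
#'
#' @param genome_len simulated chromosome length, bp.
#' @param probe_spacing distance between probe starts, bp.
#' @param deletions data.frame with columns `start`, `end`, `copy_state`
#'   (`"one_copy_loss"`/`"two_copy_loss"`); intervals 0-based half-open and
#'   non-overlapping. `NULL` or zero rows plants nothing.
#' @param noise_sd standard deviation of the per-probe log2 noise.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param probe_len probe length, bp (capped at the spacing). A probe takes
#'   a deletion's mean when its midpoint falls inside the interval.
#' @return a `"probe_track"`: data.frame (`chrom`, `start`, `end`,
#'   `log2ratio`) with attribute `noise_sd`.
#' @export
simulate_track <- function(genome_len, probe_spacing, deletions = NULL,
                           noise_sd = 0.2, seed = NULL, chrom = "chrI",
                           probe_len = min(probe_spacing, 60L)) {
  if (probe_spacing <= 0) {
    ds_stop("probe_spacing must be positive", "delscreen_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(deletions)) {
    deletions <- data.frame(start = integer(), end = integer(),
                            copy_state = character())
  }
  if (nrow(deletions) > 1L) {
    d <- deletions[order(deletions$start), , drop = FALSE]
    if (any(d$end[-nrow(d)] > d$start[-1L])) {
      ds_stop("planted deletions must not overlap", "delscreen_config_error")
    }
  }
  starts <- as.integer(seq.int(0L, max(0L, genome_len - probe_len),
                           by = probe_spacing))
  mid <- starts + probe_len / 2
  mu <- numeric(length(starts))
  for (i in seq_len(nrow(deletions))) {
    inside <- mid >= deletions$start[i] & mid < deletions$end[i]
    mu[inside] <- switch(deletions$copy_state[i],
                         one_copy_loss = -1, two_copy_loss = -4,
                         ds_stop("copy_state must be one_copy_loss or two_copy_loss",
                                 "delscreen_config_error"))
  }
  track <- data.frame(chrom = chrom, start = starts,
                      end = starts + as.integer(probe_len),
                      log2ratio = rnorm(length(starts), mu, noise_sd))
  attr(track, "noise_sd") <- noise_sd
  class(track) <- c("probe_track", "data.frame")
  track
}

#' Call copy-loss segments on a probe track
#'
#' Maximal runs of at least `min_probes` consecutive probes with
#' `log2ratio < het_cut` become calls spanning the first to last probe of
#' the run; a run whose mean log2 ratio is below `hom_cut` is graded
#' `two_copy_loss`, otherwise `one_copy_loss`.
#'
#' @param track a `"probe_track"` (or BED-like data.frame with `chrom`,
#'   `start`, `end`, `log2ratio`).
#' @param het_cut,hom_cut thresholds, `hom_cut < het_cut < 0`. Defaults
#'   (-0.5, -2) are standard aCGH heuristics sitting between the expected
#'   neutral/het and het/hom levels.
#' @param min_probes minimum probes per call.
#' @return a `"loss_calls"` data.frame: `chrom`, `start`, `end`,
#'   `copy_state`, `n_probes`, `mean_log2`.
#' @export
call_losses <- function(track, het_cut = -0.5, hom_cut = -2,
                        min_probes = 3L) {
  if (!(hom_cut < het_cut && het_cut < 0)) {
    ds_stop("need hom_cut < het_cut < 0", "delscreen_config_error")
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), copy_state = character(),
                      n_probes = integer(), mean_log2 = numeric())
  if (is.null(track) || nrow(track) == 0L) {
    class(empty) <- c("loss_calls", "data.frame")
    return(empty)
  }
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    below <- t$log2ratio < het_cut
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_probes)) {
      idx <- starts[j]:ends[j]
      m <- mean(t$log2ratio[idx])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = t$start[idx[1L]], end = t$end[idx[length(idx)]],
        copy_state = if (m < hom_cut) "two_copy_loss" else "one_copy_loss",
        n_probes = length(idx), mean_log2 = m)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else empty
  rownames(calls) <- NULL
  class(calls) <- c("loss_calls", "data.frame")
  calls
}

#' Validate a PCR-isolated deletion against CGH loss calls
#'
#' The deletion is confirmed iff some call covers at least half of the
#' target interval; calls elsewhere in the genome are reported as extra
#' deletions (strains frequently carry additional losses unrelated to the
#' screened target). Confirmation is unaffected by such extras.
#'
#' @param calls a `"loss_calls"` data.frame from [call_losses()].
#' @param target list or vector with `chrom`, `start`, `end` of the
#'   PCR-called deletion.
#' @return list with `status` (`"confirmed"`/`"failed"`) and `extra` (the
#'   calls not overlapping the target).
#' @export
validate_deletion <- function(calls, target) {
  tchrom <- as.character(target[["chrom"]])
  tstart <- as.numeric(target[["start"]])
  tend <- as.numeric(target[["end"]])
  stopifnot(tend > tstart)
  ov <- rep(0, nrow(calls))
  same <- calls$chrom == tchrom
  ov[same] <- pmax(0, pmin(calls$end[same], tend) -
                      pmax(calls$start[same], tstart))
  confirmed <- any(ov >= 0.5 * (tend - tstart))
  extra <- calls[ov == 0, , drop = FALSE]
  rownames(extra) <- NULL
  list(status = if (confirmed) "confirmed" else "failed", extra = extra)
}

#' Diagnostic-PCR presence/absence test for a deletion strain
#'
#' The diagnostic pair places one primer wholly inside the deleted interval
#' and one wholly outside it: a wild-type template yields the predicted
#' product, a deletion template cannot (its internal primer site is gone).
#' A product from a deletion strain therefore means the strain still
#' carries an intact copy of the target - the known rare failure mode of
#' PCR isolation - and such strains are discarded.
#'
#' @param amp the [amplicon()].
#' @param allele the [deletion_allele()] under test.
#' @param internal_primer_pos,external_primer_pos primer intervals
#'   `c(start, end)`, 0-based half-open, in amplicon coordinates.
#' @param strain_has_wildtype does the simulated strain retain an intact
#'   copy of the target region?
#' @return `"invalid_design"` if the primer geometry does not test the
#'   deletion (internal primer not wholly inside `[left, right)`, external
#'   primer not wholly outside, a primer straddling a breakpoint, or a
#'   primer outside the amplicon); otherwise `"wild_type_present"` or
#'   `"wild_type_absent"`.
#' @export
diagnostic_pcr <- function(amp, allele, internal_primer_pos,
                           external_primer_pos,
                           strain_has_wildtype = FALSE) {
  stopifnot(inherits(amp, "amplicon"), inherits(allele, "deletion_allele"))
  n <- nchar(amp$seq)
  ok_interval <- function(p) {
    length(p) == 2L && p[1L] < p[2L] && p[1L] >= 0 && p[2L] <= n
  }
  if (!ok_interval(internal_primer_pos) || !ok_interval(external_primer_pos)) {
    return("invalid_design")
  }
  inside <- function(p) p[1L] >= allele$left && p[2L] <= allele$right
  outside <- function(p) p[2L] <= allele$left || p[1L] >= allele$right
  if (!inside(internal_primer_pos) || !outside(external_primer_pos)) {
    return("invalid_design")
  }
  if (strain_has_wildtype) "wild_type_present" else "wild_type_absent"
}
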