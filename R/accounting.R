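# Project bookkeeping: gene-family knockout coverage tables, worm-yeast
# essentiality set arithmetic, and chromosome-distribution binning.

#' Gene-family knockout coverage
#'
#' Percentage of a family's genes carrying a mutation, reported as a
#' round-half-up integer percent (the convention of published coverage
#' tables: 380/416 kinases prints as 91%).
#'
#' @param total_genes genes in the family (> 0).
#' @param mutated_genes family members with a mutation
#'   (`0 <= mutated_genes <= total_genes`).
#' @return integer percent in `[0, 100]`.
#' @examples
#' family_coverage(416, 380)  # 91
#' family_coverage(12, 11)    # 92
#' @export
family_coverage <- function(total_genes, mutated_genes) {
  if (any(total_genes <= 0)) {
    ds_stop("total_genes must be positive", "delscreen_config_error")
  }
  if (any(mutated_genes < 0) || any(mutated_genes > total_genes)) {
    ds_stop("need 0 <= mutated_genes <= total_genes", "delscreen_data_error")
  }
  round_half_up(100 * mutated_genes / total_genes)
}

#' Fraction of mutated genes with a lethal knockout phenotype
#'
#' @param n_lethal genes whose knockout is lethal.
#' @param n_mutated genes mutated in total (> 0, `>= n_lethal`).
#' @return round-half-up integer percent.
#' @examples
#' lethal_fraction(1436, 6013)  # 24
#' @export
lethal_fraction <- function(n_lethal, n_mutated) {
  if (any(n_mutated <= 0)) {
    ds_stop("n_mutated must be positive", "delscreen_config_error")
  }
  if (any(n_lethal < 0) || any(n_lethal > n_mutated)) {
    ds_stop("need 0 <= n_lethal <= n_mutated", "delscreen_data_error")
  }
  round_half_up(100 * n_lethal / n_mutated)
}

#' Bundle worm-yeast essentiality sets
#'
#' Sets are given in ortholog-pair identifier space, so that the worm-side
#' and yeast-side essential sets can be intersected directly; the shared
#' set is their intersection.
#'
#' @param worm_lethal ids of all worm genes with a lethal knockout.
#' @param worm_lethal_with_yeast_ortholog subset of `worm_lethal` (as
#'   ortholog-pair ids) having a yeast ortholog.
#' @param yeast_essential_with_worm_ortholog ortholog-pair ids of yeast
#'   essential genes with a worm ortholog.
#' @return an object of class `"essentiality_sets"` with the two ortholog
#'   sets, `worm_lethal`, and the computed `shared_essential`.
#' @export
essentiality_sets <- function(worm_lethal,
                              worm_lethal_with_yeast_ortholog,
                              yeast_essential_with_worm_ortholog) {
  worm_lethal <- unique(as.character(worm_lethal))
  worm_orth <- unique(as.character(worm_lethal_with_yeast_ortholog))
  yeast_orth <- unique(as.character(yeast_essential_with_worm_ortholog))
  if (!all(worm_orth %in% worm_lethal)) {
    ds_stop("worm_lethal_with_yeast_ortholog must be a subset of worm_lethal",
            "delscreen_data_error")
  }
  structure(
    list(worm_lethal = worm_lethal,
         worm_lethal_with_yeast_ortholog = worm_orth,
         yeast_essential_with_worm_ortholog = yeast_orth,
         shared_essential = intersect(worm_orth, yeast_orth)),
    class = "essentiality_sets"
  )
}

#' Worm-yeast essentiality overlap counts
#'
#' @param sets an [essentiality_sets()] object.
#' @return list with `shared` (essential in both), `worm_only` (essential
#'   in worm, not yeast), `yeast_only` (essential in yeast, not worm),
#'   always satisfying `worm_only + shared = |worm ortholog set|` and
#'   `yeast_only + shared = |yeast ortholog set|`.
#' @export
essential_overlap <- function(sets) {
  stopifnot(inherits(sets, "essentiality_sets"))
  shared <- length(sets$shared_essential)
  list(shared = shared,
       worm_only = length(sets$worm_lethal_with_yeast_ortholog) - shared,
       yeast_only = length(sets$yeast_essential_with_worm_ortholog) - shared)
}

#' Lethal genes left after removing single-copy essentials
#'
#' @param total_lethal all genes with a lethal knockout.
#' @param single_copy those that are single-copy (no paralog).
#' @return `total_lethal - single_copy`: lethal genes with at least one
#'   paralog.
#' @examples
#' paralog_remainder(1436, 946)  # 490
#' @export
paralog_remainder <- function(total_lethal, single_copy) {
  if (any(single_copy < 0) || any(single_copy > total_lethal)) {
    ds_stop("need 0 <= single_copy <= total_lethal", "delscreen_data_error")
  }
  as.integer(total_lethal - single_copy)
}

#' Bin mutated genes along chromosomes
#'
#' Histograms of all mutated genes and of the lethal subset, per
#' chromosome, in fixed-width bins - the standard display for asking
#' whether essential genes cluster along the chromosomes.
#'
#' @param genes data.frame with columns `chrom`, `pos`, `is_lethal`.
#' @param bin_width bin width, bp.
#' @param chrom_lengths named numeric vector of chromosome lengths;
#'   positions must fall inside them and unknown chromosomes error.
#' @return data.frame (`chrom`, `bin_start`, `bin_end`, `n_all`,
#'   `n_lethal`) covering every bin of every declared chromosome;
#'   bin-wise `n_lethal <= n_all`.
#' @export
chromosome_bins <- function(genes, bin_width, chrom_lengths) {
  if (bin_width <= 0) {
    ds_stop("bin_width must be positive", "delscreen_config_error")
  }
  if (nrow(genes) > 0L) {
    unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
    if (length(unknown)) {
      ds_stop(paste("unknown chromosome(s):",
                    paste(unknown, collapse = ", ")),
              "delscreen_data_error")
    }
    bad <- genes$pos < 0 | genes$pos >= chrom_lengths[genes$chrom]
    if (any(bad)) {
      ds_stop("gene position outside declared chromosome length",
              "delscreen_data_error")
    }
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    n_bins <- ceiling(chrom_lengths[[ch]] / bin_width)
    starts <- (seq_len(n_bins) - 1L) * bin_width
    g <- genes[genes$chrom == ch, , drop = FALSE]
    bin_of <- floor(g$pos / bin_width) + 1L
    n_all <- tabulate(bin_of, nbins = n_bins)
    n_lethal <- tabulate(bin_of[as.logical(g$is_lethal)], nbins = n_bins)
    data.frame(chrom = ch, bin_start = starts,
               bin_end = pmin(starts + bin_width, chrom_lengths[[ch]]),
               n_all = n_all, n_lethal = n_lethal)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage report for a family table
#'
#' @param families data.frame with columns `family`, `total_genes`,
#'   `mutated_genes` (and optionally `consortium_mutated`, which must be
#'   `<= mutated_genes`).
#' @return the table with an added integer `percent_complete` column.
#' @export
coverage_report <- function(families) {
  need <- c("family", "total_genes", "mutated_genes")
  if (!all(need %in% names(families))) {
    ds_stop(paste("family table needs columns:", paste(need, collapse = ", ")),
            "delscreen_data_error")
  }
  if (!is.null(families$consortium_mutated) &&
      any(families$consortium_mutated > families$mutated_genes |
          families$consortium_mutated < 0)) {
    ds_stop("need 0 <= consortium_mutated <= mutated_genes",
            "delscreen_data_error")
  }
  families$percent_complete <-
    family_coverage(families$total_genes, families$mutated_genes)
  families
}

#' Read a gene-family count table (TSV)
#' @param path TSV with columns `family`, `total_genes`, `mutated_genes`,
#'   optionally `consortium_mutated`; `#` lines are comments.
#' @return data.frame.
#' @export
read_family_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a coverage report TSV (deterministic byte output)
#' @param report data.frame from [coverage_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene-family knockout coverage; percent = round-half-up", con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
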