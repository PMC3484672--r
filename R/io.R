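# Standard-format I/O: FASTA via Biostrings, exon models from a GFF3
# subset via rtracklayer, BED-like probe tracks and TSV reports, and JSON
# scenario configs via jsonlite.

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene models from a GFF3 file (gene/exon features only)
#'
#' Only `gene` and `exon` features are used; exons are grouped by their
#' `Parent` attribute (falling back to `ID`/`gene_id`). GFF3 is 1-based
#' inclusive on disk; models are converted to the package's 0-based
#' half-open convention.
#'
#' @param path GFF3 path.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) {
    ds_stop("no exon features in GFF3 input", "delscreen_data_error")
  }
  parent <- if (!is.null(ex$Parent) && any(lengths(ex$Parent) > 0)) {
    vapply(as.list(ex$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  } else if (!is.null(ex$gene_id)) {
    as.character(ex$gene_id)
  } else {
    as.character(ex$ID)
  }
  parent <- sub("^(gene|transcript):", "", parent)
  out <- lapply(split(seq_along(ex), parent), function(idx) {
    e <- ex[idx]
    ord <- order(BiocGenerics::start(e))
    gene_model(
      gene_id = parent[idx][1L],
      chrom = as.character(GenomeInfoDb::seqnames(e))[1L],
      strand = {
        s <- as.character(BiocGenerics::strand(e))[1L]
        if (s == "-") "-" else "+"
      },
      exons = cbind(start = BiocGenerics::start(e)[ord] - 1L,
                    end = BiocGenerics::end(e)[ord])
    )
  })
  out
}

#' Read a probe track from a BED-like TSV
#' @param path TSV with columns chrom, start, end, log2ratio (header
#'   optional; `#` lines are comments).
#' @return a `"probe_track"` data.frame.
#' @export
read_probe_track <- function(path) {
  first <- readLines(path, n = 10L)
  first <- first[!startsWith(first, "#")][1L]
  has_header <- grepl("chrom", first, fixed = TRUE)
  t <- read.delim(path, comment.char = "#", header = has_header,
                  stringsAsFactors = FALSE)
  if (!has_header) names(t) <- c("chrom", "start", "end", "log2ratio")
  t <- t[order(t$chrom, t$start), , drop = FALSE]
  rownames(t) <- NULL
  class(t) <- c("probe_track", "data.frame")
  t
}

#' Write a probe track as BED-like TSV
#' @param track a `"probe_track"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aCGH probe track; coordinates 0-based half-open", con)
  write.table(as.data.frame(track), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write loss calls as TSV (with a BED companion)
#' @param calls a `"loss_calls"` data.frame.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_loss_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# CGH loss calls; coordinates 0-based half-open", con)
  write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a screening scenario from a JSON config
#'
#' Flat key/value JSON whose keys are the arguments of
#' [screen_scenario()]; missing keys take the defaults.
#'
#' @param path JSON path.
#' @return a [screen_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(screen_scenario))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    ds_stop(paste("unknown scenario key(s):", paste(unknown, collapse = ", ")),
            "delscreen_config_error")
  }
  do.call(screen_scenario, cfg)
}

#' Write a screen result summary as JSON
#' @param result a `"screen_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_summary <- function(result, path) {
  jsonlite::write_json(
    list(detected = result$detected,
         addressed_well = result$addressed_well,
         recovered = result$recovered,
         reactions_used = result$reactions_used,
         lost_at_addressing = result$lost_at_addressing,
         rounds = result$rounds),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
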