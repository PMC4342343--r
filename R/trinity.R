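#' Parse Trinity-style sequence identifiers
#'
#' Trinity names assembled transcripts `comp{X}_c{Y}_seq{Z}`, encoding a
#' three-level hierarchy: component (`compX`, a putative gene locus),
#' subcomponent (`compX_cY`, a gene-like cluster of isoforms), and isoform
#' (`seqZ`). Identifiers without the `_seq` suffix are accepted and treated
#' as isoform 1, so that subcomponent-level tables (e.g. RSEM gene output)
#' parse with the same function.
#'
#' @param ids Character vector of identifiers.
#' @return A tibble with columns `transcript_id`, `component_id`,
#'   `subcomponent_id`, `isoform_index`.
#' @examples
#' parse_trinity_id(c("comp41991_c0_seq2", "comp0_c0"))
#' @export
parse_trinity_id <- function(ids) {
  stopifnot(is.character(ids))
  m <- stringr::str_match(ids, "^(comp\\d+)_(c\\d+)(?:_seq(\\d+))?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop("malformed Trinity identifier(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  iso <- ifelse(is.na(m[, 4]), 1L, suppressWarnings(as.integer(m[, 4])))
  tibble::tibble(
    transcript_id   = ids,
    component_id    = m[, 2],
    subcomponent_id = paste0(m[, 2], "_", m[, 3]),
    isoform_index   = iso
  )
}

#' Turn a named set of sequences into a transcript table
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of nucleotide sequences with Trinity-style names.
#' @return A tibble with parsed identity columns plus `sequence` and `length`.
#' @export
as_transcript_tbl <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ids <- stringr::str_extract(names(sequences), "^\\S+")
  out <- parse_trinity_id(ids)
  out$sequence <- unname(toupper(sequences))
  out$length <- nchar(out$sequence)
  out
}

#' Read a Trinity-style assembly from FASTA
#'
#' @param path Path to a nucleotide FASTA file.
#' @return A transcript tibble (see [as_transcript_tbl()]).
#' @export
read_assembly <- function(path) {
  as_transcript_tbl(Biostrings::readDNAStringSet(path))
}

#' Write a transcript table to FASTA (60-column wrapped)
#'
#' @param transcripts Transcript tibble with `transcript_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(transcripts$sequence,
                                                transcripts$transcript_id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Assembly summary metrics
#'
#' Computes the standard summary table for a transcriptome shotgun assembly:
#' transcript/subcomponent/component counts, GC content, N50, longest and
#' median/mean contig length, and total assembled bases.
#'
#' N50 is the largest contig length L such that contigs of length >= L
#' jointly cover at least half of the total assembled bases. GC content is
#' computed over unambiguous bases only (N excluded from numerator and
#' denominator); an assembly consisting solely of N returns `NaN`.
#'
#' @param transcripts Transcript tibble (see [as_transcript_tbl()]).
#' @return One-row tibble with columns `n_transcripts`, `n_subcomponents`,
#'   `n_components`, `gc_percent`, `n50`, `longest`, `median_length`,
#'   `mean_length`, `total_bases`.
#' @examples
#' tr <- as_transcript_tbl(c(comp0_c0_seq1 = "GGCC", comp1_c0_seq1 = "AATT"))
#' assembly_metrics(tr)
#' @export
assembly_metrics <- function(transcripts) {
  if (nrow(transcripts) == 0L) {
    stop("cannot summarize an empty assembly", call. = FALSE)
  }
  lens <- transcripts$length
  comp <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(transcripts$sequence), baseOnly = TRUE
  )
  gc <- sum(comp[, c("C", "G")])
  acgt <- sum(comp[, c("A", "C", "G", "T")])
  tibble::tibble(
    n_transcripts   = nrow(transcripts),
    n_subcomponents = dplyr::n_distinct(transcripts$subcomponent_id),
    n_components    = dplyr::n_distinct(transcripts$component_id),
    gc_percent      = if (acgt > 0L) 100 * gc / acgt else NaN,
    n50             = n50(lens),
    longest         = max(lens),
    median_length   = stats::median(lens),
    mean_length     = mean(lens),
    total_bases     = sum(lens)
  )
}

#' N50 of a set of contig lengths
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The largest length L such that contigs >= L cover at least 50%
#'   of total bases.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  lens <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(lens))
  lens[which(cum >= sum(as.numeric(lens)) / 2)[1L]]
}

#' Write an assembly metrics table as two-column TSV
#'
#' One metric per row (name, value), mirroring the layout of published
#' assembly summary tables.
#'
#' @param metrics One-row tibble from [assembly_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  long <- tibble::tibble(
    metric = names(metrics),
    value = vapply(metrics, function(x) format(x, trim = TRUE), character(1))
  )
  readr::write_tsv(long, path, col_names = FALSE)
  invisible(path)
}
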