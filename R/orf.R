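# Six-frame ORF discovery and completeness classification.
#
# Completeness classes follow the usual TransDecoder-style convention:
#   complete       : ATG ... stop, both inside the transcript
#   partial_5prime : frame open at the transcript 5' end (no upstream
#                    in-frame stop, no usable ATG), closed by a stop
#   partial_3prime : ATG-initiated frame running off the 3' end (no stop)
#   internal       : frame open at both ends, no ATG
.orf_classes <- c("complete", "partial_5prime", "partial_3prime", "internal")

# codon -> amino acid, with any codon containing a non-ACGT base giving "X";
# "X" counts toward peptide length but can never act as start or stop.
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Scan one frame of one oriented sequence. Returns a list of ORF stubs with
# codon-index coordinates relative to the oriented sequence.
.scan_frame <- function(seq, frame, min_len_aa) {
  L <- nchar(seq)
  if (L < frame + 3L) return(list())
  starts <- seq.int(frame + 1L, L - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .translate_codons(codons)
  is_stop <- aa == "*"
  n <- length(aa)
  stop_idx <- which(is_stop)

  # segments of consecutive non-stop codons, each possibly bounded by stops
  bounds <- c(0L, stop_idx, n + 1L)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    seg_lo <- bounds[k] + 1L
    seg_hi <- bounds[k + 1L] - 1L
    if (seg_lo > seg_hi) next
    closed5 <- bounds[k] != 0L          # preceded by an in-frame stop
    closed3 <- bounds[k + 1L] != n + 1L # terminated by a stop codon
    seg_aa <- aa[seg_lo:seg_hi]
    atg_rel <- which(codons[seg_lo:seg_hi] == "ATG")[1L]

    if (!is.na(atg_rel)) {
      orf_lo <- seg_lo + atg_rel - 1L
      class <- if (closed3) "complete" else "partial_3prime"
    } else if (!closed5) {
      orf_lo <- seg_lo
      class <- if (closed3) "partial_5prime" else "internal"
    } else {
      next # stop-bounded segment with no start codon: not a reportable ORF
    }
    pep <- seg_aa[(orf_lo - seg_lo + 1L):length(seg_aa)]
    if (length(pep) < min_len_aa) next
    out[[length(out) + 1L]] <- list(
      codon_lo = orf_lo, codon_hi = seg_hi, frame = frame,
      peptide = paste(pep, collapse = ""), completeness = class
    )
  }
  out
}

#' Find open reading frames in all six frames
#'
#' Enumerates stop-to-stop segments in each of the six reading frames of
#' each transcript and reports, per segment, the single ORF it supports:
#' from the first ATG when one exists (complete if stop-terminated,
#' 3'-partial if it runs off the end), otherwise the open 5' run
#' (5'-partial if stop-terminated, internal if open at both ends). Segments
#' bounded by stops on both sides without an ATG are not reportable.
#' Codons containing N translate to X and can serve neither as start nor
#' stop. The stop codon is excluded from the peptide and from the reported
#' coordinates.
#'
#' @param transcripts Transcript tibble (see [as_transcript_tbl()]), or any
#'   tibble with `transcript_id` and `sequence` columns.
#' @param min_len_aa Minimum peptide length in amino acids (default 100,
#'   the conventional TransDecoder cut-off).
#' @return A tibble with one row per ORF: `transcript_id`, `strand`
#'   (`"+"`/`"-"`), `frame` (0, 1, 2), `nt_start`/`nt_end` (0-based
#'   half-open, always on the forward strand of the transcript), `peptide`,
#'   `length_aa`, `completeness`.
#' @examples
#' tr <- as_transcript_tbl(c(comp0_c0_seq1 = "ATGAAATAA"))
#' find_orfs(tr, min_len_aa = 2)
#' @export
find_orfs <- function(transcripts, min_len_aa = 100L) {
  stopifnot(min_len_aa >= 1L)
  res <- purrr::map2(transcripts$transcript_id, toupper(transcripts$sequence),
                     function(id, seq) {
    L <- nchar(seq)
    rows <- list()
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") seq else .revcomp(seq)
      for (frame in 0:2) {
        for (o in .scan_frame(oriented, frame, min_len_aa)) {
          # oriented-strand nt coordinates (0-based half-open)
          s <- frame + 3L * (o$codon_lo - 1L)
          e <- frame + 3L * o$codon_hi
          if (strand == "-") { tmp <- s; s <- L - e; e <- L - tmp }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            transcript_id = id, strand = strand, frame = frame,
            nt_start = s, nt_end = e, peptide = o$peptide,
            length_aa = nchar(o$peptide), completeness = o$completeness
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      transcript_id = character(), strand = character(), frame = integer(),
      nt_start = integer(), nt_end = integer(), peptide = character(),
      length_aa = integer(), completeness = character()
    )
  }
  out
}

#' Keep the single best ORF per component or subcomponent
#'
#' Selects, within each Trinity component (or subcomponent), the ORF with
#' the longest peptide. Ties are broken by completeness class
#' (complete > 3'-partial > 5'-partial > internal), then by lexicographic
#' transcript identifier.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param group_by `"component"` or `"subcomponent"`.
#' @return One ORF row per group.
#' @export
longest_orf_per_group <- function(orfs, group_by = c("component", "subcomponent")) {
  group_by <- match.arg(group_by)
  key <- paste0(group_by, "_id")
  rank <- c(complete = 1L, partial_3prime = 2L, partial_5prime = 3L, internal = 4L)
  orfs |>
    dplyr::left_join(parse_trinity_id(unique(orfs$transcript_id)),
                     by = "transcript_id") |>
    dplyr::arrange(dplyr::desc(.data$length_aa),
                   rank[.data$completeness], .data$transcript_id) |>
    dplyr::distinct(.data[[key]], .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(names(orfs)), dplyr::all_of(key))
}

#' Tabulate ORF completeness classes
#'
#' @param orfs ORF tibble with a `completeness` column.
#' @return Tibble with one row per class plus a `total` row; `percent` is
#'   100 * count / total, rounded to one decimal.
#' @examples
#' completeness_summary(tibble::tibble(
#'   completeness = rep(c("complete", "internal"), c(3, 1))))
#' @export
completeness_summary <- function(orfs) {
  counts <- table(factor(orfs$completeness, levels = .orf_classes))
  total <- sum(counts)
  tibble::tibble(
    class = c(.orf_classes, "total"),
    count = c(as.integer(counts), total),
    percent = if (total > 0) {
      round(100 * c(as.integer(counts), total) / total, 1)
    } else {
      rep(0, 5L)
    }
  )
}

#' Bin lengths into closed-open intervals
#'
#' Histogram summary of contig or peptide lengths, optionally split by a
#' class column (e.g. ORF completeness), mirroring published assembly
#' length histograms. Bins are `[lo, lo + width)`; values below `from`
#' fall into a single underflow bin starting at the minimum value.
#'
#' @param lengths Tibble with a `length` column (use `length_aa` renamed,
#'   or any numeric lengths), optionally a `class` column.
#' @param bin_width Bin width (default 100 for nucleotides; use 50 for
#'   amino acids).
#' @param from First regular bin lower edge (default 200 nt; use 99 for
#'   amino-acid histograms).
#' @return Tibble of `bin_lo`, `bin_hi`, `count` (and `class` when present).
#' @export
length_histogram <- function(lengths, bin_width = 100L, from = 200L) {
  stopifnot(bin_width >= 1L)
  if (nrow(lengths) == 0L) {
    return(tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                          count = integer()))
  }
  x <- lengths$length
  lo <- from + bin_width * floor((x - from) / bin_width)
  lo[x < from] <- min(x[x < from], from)[1L]
  df <- tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width)
  if ("class" %in% names(lengths)) df$class <- lengths$class
  dplyr::count(df, dplyr::across(dplyr::everything()), name = "count") |>
    dplyr::arrange(.data$bin_lo)
}

#' Write predicted peptides as protein FASTA
#'
#' Headers take the form `{transcript_id}|{strand}{frame}|{completeness}`.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(orfs, path) {
  headers <- paste0(orfs$transcript_id, "|", orfs$strand, orfs$frame, "|",
                    orfs$completeness)
  x <- Biostrings::AAStringSet(stats::setNames(orfs$peptide, headers))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
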