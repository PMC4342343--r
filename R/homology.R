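# Unigene reduction over tabular homology hits (LCPC / BHPC selection) and
# E-value distribution summaries.

.blast6_cols <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Parses the de facto standard tabular alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Extra trailing columns are ignored.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return Tibble with standardized column names.
#' @export
read_hits_tab <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(ncol(raw) >= 12L)
  raw <- raw[, 1:12]
  names(raw) <- .blast6_cols
  raw |>
    dplyr::mutate(dplyr::across(c("percent_identity", "evalue", "bitscore"),
                                as.numeric),
                  dplyr::across(c("alignment_length", "mismatches",
                                  "gap_opens", "q_start", "q_end",
                                  "s_start", "s_end"), as.integer))
}

#' Select the longest contig per component (LCPC)
#'
#' The operational "unigene" sequence: within each Trinity component, the
#' longest contig; length ties are broken by the lexicographically smallest
#' transcript identifier.
#'
#' @param transcripts Transcript tibble (see [as_transcript_tbl()]).
#' @return One transcript row per component.
#' @export
select_lcpc <- function(transcripts) {
  transcripts |>
    dplyr::arrange(dplyr::desc(.data$length), .data$transcript_id) |>
    dplyr::distinct(.data$component_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$transcript_id)
}

#' Select the best hit per component (BHPC)
#'
#' Retains hits at or below the E-value cut-off, then keeps a single hit
#' per Trinity component: the one with maximal bitscore, ties broken by
#' lowest E-value, then lexicographic subject identifier.
#'
#' @param hits Hit tibble (see [read_hits_tab()]); `query_id` must be a
#'   Trinity-style identifier (a `|`-suffixed peptide header is tolerated:
#'   only the part before the first `|` is parsed).
#' @param evalue_cutoff Maximum E-value retained (default `1e-6`).
#' @return One hit row per component with a `component_id` column.
#' @export
best_hit_per_component <- function(hits, evalue_cutoff = 1e-6) {
  keep <- hits |> dplyr::filter(.data$evalue <= evalue_cutoff)
  if (nrow(keep) == 0L) {
    return(dplyr::mutate(keep, component_id = character(0)))
  }
  ids <- stringr::str_extract(keep$query_id, "^[^|]+")
  keep$component_id <- parse_trinity_id(ids)$component_id
  keep |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject_id) |>
    dplyr::distinct(.data$component_id, .keep_all = TRUE)
}

#' Summarize hits by E-value range
#'
#' Assigns every hit with E-value at or below `edges[1]` to exactly one
#' half-open range `(edges[i+1], edges[i]]`. When the final edge is 0 the
#' last range contains exact zeroes only ("approximating zero" bin);
#' otherwise the last range is everything at or below the final edge,
#' zeroes included.
#'
#' @param hits Hit tibble with an `evalue` column.
#' @param edges Strictly decreasing numeric vector of bin upper bounds,
#'   e.g. `c(1e-75, 1e-100, 1e-125, 1e-150, 1e-175, 1e-200)`.
#' @param denominator Total used for the percent column; defaults to the
#'   number of rows in `hits` (pass the full query count to reproduce
#'   percent-of-all-queries summaries).
#' @return Tibble of `range`, `count`, `percent` (one decimal).
#' @export
evalue_bin_summary <- function(hits, edges, denominator = nrow(hits)) {
  if (is.unsorted(rev(edges), strictly = TRUE)) {
    stop("`edges` must be strictly decreasing", call. = FALSE)
  }
  n <- length(edges)
  ev <- hits$evalue
  stopifnot(all(ev >= 0))
  labels <- character(n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    if (i < n) {
      counts[i] <- sum(ev <= edges[i] & ev > edges[i + 1L])
      labels[i] <- sprintf("<= %g, > %g", edges[i], edges[i + 1L])
    } else if (edges[n] == 0) {
      counts[i] <- sum(ev == 0)
      labels[i] <- "= 0"
    } else {
      counts[i] <- sum(ev <= edges[i])
      labels[i] <- sprintf("<= %g", edges[i])
    }
  }
  tibble::tibble(range = labels, count = counts,
                 percent = round(100 * counts / denominator, 1))
}

#' Summarize a reciprocal homology comparison between two sequence sets
#'
#' For each search direction, counts the query sequences whose best hit
#' passes the E-value cut-off, the distinct subjects those hits cover, and
#' (when the query identifiers are Trinity-style) the best-hit-per-component
#' unigene count, with a per-bin E-value breakdown.
#'
#' @param hits_ab,hits_ba Hit tibbles for the A-vs-B and B-vs-A searches.
#' @param cutoff E-value cut-off (default `1e-75`, the stringent
#'   near-identity threshold used for assembly-vs-EST comparisons).
#' @param edges Bin edges passed to [evalue_bin_summary()] applied to each
#'   query's best (lowest) E-value.
#' @param totals Optional length-2 numeric: total query counts for the two
#'   directions, used as percent denominators.
#' @return A list with `summary` (one row per direction: `n_queries_hit`,
#'   `n_bhpc`, `n_subjects`) and `bins` (per-direction E-value breakdown).
#' @export
reciprocal_overlap_summary <- function(hits_ab, hits_ba, cutoff = 1e-75,
                                       edges = c(1e-75, 1e-100, 1e-125,
                                                 1e-150, 1e-175, 1e-200),
                                       totals = NULL) {
  one_direction <- function(hits, direction, total) {
    keep <- dplyr::filter(hits, .data$evalue <= cutoff)
    best <- keep |>
      dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore)) |>
      dplyr::distinct(.data$query_id, .keep_all = TRUE)
    n_bhpc <- tryCatch(nrow(best_hit_per_component(keep, cutoff)),
                       error = function(e) NA_integer_)
    if (is.null(total)) total <- max(nrow(best), 1L)
    list(
      summary = tibble::tibble(
        direction = direction,
        n_queries_hit = nrow(best),
        n_bhpc = n_bhpc,
        n_subjects = dplyr::n_distinct(keep$subject_id)
      ),
      bins = dplyr::mutate(
        evalue_bin_summary(best, edges, denominator = total),
        direction = direction, .before = 1L
      )
    )
  }
  a <- one_direction(hits_ab, "a_vs_b", totals[1])
  b <- one_direction(hits_ba, "b_vs_a", totals[2])
  list(summary = dplyr::bind_rows(a$summary, b$summary),
       bins = dplyr::bind_rows(a$bins, b$bins))
}
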