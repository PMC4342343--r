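# Prohormone processing: convertase cleavage site prediction over known
# basic-residue motifs, basic-residue trimming, and C-terminal-glycine
# amidation, yielding the mature peptides a secreted precursor encodes.

#' Predict prohormone convertase cleavage sites
#'
#' A site is the position immediately after the basic residue(s) of
#' either a dibasic pair (KR, RR, KK, RK) or a monobasic arginine with an
#' additional basic residue (K/R) at offset -4, -6 or -8. Overlapping
#' dibasic matches (runs of three or more basics) merge into a single
#' site after the run. Monobasic sites immediately followed by proline
#' are suppressed (convertases disfavour cleavage before P). Sites inside
#' the signal peptide are discarded.
#'
#' @param precursor Amino-acid string (full precursor, signal peptide
#'   included).
#' @param sp_cleavage 1-based index of the last signal-peptide residue
#'   (0 when the precursor is already mature).
#' @param dibasic Character vector of dibasic motifs recognized.
#' @param mono_offsets Negative offsets at which a second basic residue
#'   licenses a monobasic arginine site (default -4, -6, -8).
#' @return Increasing integer vector of cleavage positions; cleavage is
#'   between residue `p` and `p + 1` for each reported `p`.
#' @examples
#' predict_cleavage_sites("MALSEDKRSGYL", sp_cleavage = 2)
#' @export
predict_cleavage_sites <- function(precursor, sp_cleavage = 0L,
                                   dibasic = c("KR", "RR", "KK", "RK"),
                                   mono_offsets = c(-4L, -6L, -8L)) {
  chars <- strsplit(precursor, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stopifnot(sp_cleavage < n)
  basic <- chars %in% c("K", "R")
  sites <- integer(0)

  # dibasic motifs; maximal basic runs containing one yield one site at
  # the run end (overlapping matches merged, all residues consumed)
  if (n >= 2L) {
    pair <- paste0(chars[-n], chars[-1L])
    hit2 <- which(pair %in% dibasic)
    for (h in hit2) {
      e <- h + 1L
      while (e < n && basic[e + 1L]) e <- e + 1L
      sites <- c(sites, e)
    }
  }

  # monobasic R with a basic residue at -4, -6 or -8 (counting from the R);
  # the licensing basic must itself be a lone basic - residues consumed by
  # a dibasic site do not double as spacing partners
  lone_basic <- basic &
    !(c(FALSE, basic[-n]) | c(basic[-1L], FALSE))
  mono <- which(chars == "R")
  for (p in mono) {
    if (p > 1L && basic[p - 1L]) next        # part of a basic run
    if (p < n && basic[p + 1L]) next         # handled by the dibasic rule
    prior <- p + mono_offsets
    prior <- prior[prior >= 1L]
    if (!any(lone_basic[prior])) next
    if (p < n && chars[p + 1L] == "P") next  # proline suppression
    sites <- c(sites, p)
  }

  sort(unique(sites[sites > sp_cleavage]))
}

#' Derive mature peptides from a precursor
#'
#' Splits the mature region (everything after the signal peptide) at the
#' predicted cleavage sites, trims runs of basic residues (K/R) from both
#' ends of every fragment, removes a remaining trailing glycine as the
#' amide donor (flagging the peptide amidated), and discards empty
#' fragments. Concatenating kept peptides, trimmed basics and removed
#' glycines in order reconstructs the mature region exactly.
#'
#' @param precursor Amino-acid string.
#' @param sp_cleavage 1-based index of the last signal-peptide residue
#'   (0 for none).
#' @param sites Increasing cleavage positions from
#'   [predict_cleavage_sites()]; computed automatically when `NULL`.
#' @return Tibble with one row per mature peptide: `start`, `end`
#'   (0-based half-open coordinates in the precursor of the peptide
#'   including its amide-donor glycine), `sequence`, `amidated`.
#' @examples
#' derive_peptides("MAEDKRSGYLARFPRMGKR", sp_cleavage = 2)
#' @export
derive_peptides <- function(precursor, sp_cleavage = 0L, sites = NULL) {
  if (is.null(sites)) {
    sites <- predict_cleavage_sites(precursor, sp_cleavage)
  }
  chars <- strsplit(precursor, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stopifnot(all(sites > sp_cleavage), all(sites <= n),
            !is.unsorted(sites, strictly = TRUE))
  bounds <- unique(c(sp_cleavage, sites, n))
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L  # 1-based inclusive fragment range
    hi <- bounds[k + 1L]
    s <- lo
    e <- hi
    while (s <= e && chars[s] %in% c("K", "R")) s <- s + 1L
    while (e >= s && chars[e] %in% c("K", "R")) e <- e - 1L
    if (s > e) next
    amidated <- chars[e] == "G" && e > s
    core_end <- if (amidated) e - 1L else e
    if (core_end < s) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start = s - 1L, end = e,
      sequence = paste(chars[s:core_end], collapse = ""),
      amidated = amidated
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), amidated = logical())
  }
  res
}

#' Count repeats of a mature peptide motif in a precursor
#'
#' Number of derived mature peptides equal to `motif`; the comparison is
#' amidation-normalized (an amidated peptide matches by its sequence
#' without the donor glycine, which [derive_peptides()] already removes).
#'
#' @param precursor Amino-acid string.
#' @param motif Mature peptide sequence to count (e.g. `"FMRF"`).
#' @param sp_cleavage 1-based index of the last signal-peptide residue.
#' @return Integer count.
#' @export
count_peptide_repeats <- function(precursor, motif, sp_cleavage = 0L) {
  stopifnot(nchar(motif) >= 1L)
  peptides <- derive_peptides(precursor, sp_cleavage)
  sum(peptides$sequence == motif)
}

#' Process a table of secreted precursors
#'
#' Applies [derive_peptides()] to every precursor in a secretome call
#' table, yielding one tidy table of mature peptides.
#'
#' @param proteins Tibble with `protein_id`, `peptide`.
#' @param calls Secretome call tibble from [secretome_filter()]; only
#'   `secreted` verdicts are processed, using their predicted
#'   signal-peptide cleavage position.
#' @return Tibble of mature peptides with a `precursor_id` column.
#' @export
derive_secretome_peptides <- function(proteins, calls) {
  secreted <- dplyr::filter(calls, .data$verdict == "secreted")
  joined <- dplyr::inner_join(secreted, proteins, by = "protein_id")
  purrr::map2(joined$protein_id, seq_len(nrow(joined)), function(id, i) {
    dplyr::mutate(
      derive_peptides(joined$peptide[i],
                      sp_cleavage = joined$sp_cleavage_pos[i]),
      precursor_id = id, .before = 1L
    )
  }) |>
    dplyr::bind_rows()
}
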