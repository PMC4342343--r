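# Neurosecretome prediction cascade.
#
# The three external predictors used in classical secretome pipelines
# (signal peptide, transmembrane helix, mitochondrial presequence) are
# implemented here as transparent, deterministic scorers built on the
# classical sequence features each tool formalizes: the tripartite n/h/c
# signal-peptide architecture with the (-3,-1) small-residue cleavage rule,
# window-17 Kyte-Doolittle hydropathy for membrane-spanning segments, and
# the arginine-rich, acid-poor, hydroxylated composition of mitochondrial
# presequences. Each scorer honours the published decision contract: a
# probability-like score in [0,1] compared to 0.5, residue intervals for
# membrane helices, and a boolean mitochondrial flag.

# Kyte & Doolittle hydropathy scale; X (ambiguous) scores 0.
.kd_scale <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

.aa_scores <- function(peptide) {
  v <- .kd_scale[strsplit(peptide, "", fixed = TRUE)[[1L]]]
  v[is.na(v)] <- 0
  unname(v)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of the standard Kyte-Doolittle residue hydropathy
#' scores; the value at each center position is the arithmetic mean over
#' the window. Positions lacking a full window are omitted, so a peptide
#' shorter than the window yields an empty profile.
#'
#' @param peptide Amino-acid string over the 20 standard residues plus X
#'   (X scores 0).
#' @param window Odd window size (default 17, the classical choice for
#'   membrane-helix detection).
#' @return Tibble with `center` (1-based residue index of the window
#'   center) and `hydropathy`.
#' @examples
#' kyte_doolittle_profile(strrep("I", 17))
#' @export
kyte_doolittle_profile <- function(peptide, window = 17L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  v <- .aa_scores(peptide)
  n <- length(v)
  if (n < window) {
    return(tibble::tibble(center = integer(), hydropathy = numeric()))
  }
  means <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half + 1L, n - half)
  tibble::tibble(center = centers, hydropathy = means[centers])
}

#' Predict transmembrane helices from a hydropathy profile
#'
#' Maximal runs of window centers whose mean hydropathy exceeds
#' `threshold` and that span at least `min_span` centers are reported as
#' candidate membrane-spanning segments; runs separated by fewer than 5
#' centers are merged first. Each run is extended by half a window on each
#' side to convert center positions into residue intervals.
#'
#' @param x A peptide string or a profile tibble from
#'   [kyte_doolittle_profile()].
#' @param threshold Hydropathy threshold (default 1.6, the classical
#'   hydropathy-analysis convention).
#' @param min_span Minimum run length in window centers (default 15).
#' @param window Window size used when `x` is a peptide (default 17).
#' @return Tibble with `start`, `end` residue intervals (1-based,
#'   inclusive); zero rows when no helix is predicted.
#' @export
predict_tm_helices <- function(x, threshold = 1.6, min_span = 15L,
                               window = 17L) {
  profile <- if (is.character(x)) kyte_doolittle_profile(x, window) else x
  empty <- tibble::tibble(start = integer(), end = integer())
  if (nrow(profile) == 0L) return(empty)
  hot <- profile$center[profile$hydropathy > threshold]
  if (length(hot) == 0L) return(empty)
  # maximal runs of consecutive centers, then merge runs < 5 positions apart
  brk <- which(diff(hot) > 1L)
  runs <- tibble::tibble(lo = hot[c(1L, brk + 1L)], hi = hot[c(brk, length(hot))])
  merged <- runs[1L, ]
  for (k in seq_len(nrow(runs))[-1L]) {
    if (runs$lo[k] - merged$hi[nrow(merged)] < 5L) {
      merged$hi[nrow(merged)] <- runs$hi[k]
    } else {
      merged <- dplyr::bind_rows(merged, runs[k, ])
    }
  }
  merged <- merged[merged$hi - merged$lo + 1L >= min_span, ]
  if (nrow(merged) == 0L) return(empty)
  half <- (window - 1L) %/% 2L
  L <- max(profile$center) + half
  tibble::tibble(start = pmax(1L, merged$lo - half),
                 end = pmin(L, merged$hi + half))
}

# (-3,-1) signal-peptidase site rule: residue sets for the two positions.
.c1_set <- c("A", "G", "S", "C", "T", "Q")
.c3_set <- c("A", "G", "S", "C", "T", "V", "I", "L")
.c_small <- c("A", "G", "S")

# All candidate cleavage positions p (cleavage after residue p) in
# [lo, hi] obeying the (-3,-1) rule, with a canonical-smallness score:
# 2 points for -1 in {A,G,S}, 1 point for -3 in {A,G,S}.
.cleavage_candidates <- function(chars, lo = 15L, hi = 45L) {
  n <- length(chars)
  if (min(hi, n) < max(lo, 3L)) {
    return(tibble::tibble(pos = integer(), score = integer()))
  }
  p <- seq.int(max(lo, 3L), min(hi, n))
  ok <- chars[p] %in% .c1_set & chars[p - 2L] %in% .c3_set
  p <- p[ok]
  tibble::tibble(
    pos = p,
    score = 2L * (chars[p] %in% .c_small) + (chars[p - 2L] %in% .c_small)
  )
}

# Best mean hydropathy over any `span`-residue window inside residues
# [lo, hi] of the peptide.
.best_h_window <- function(scores, lo = 5L, hi = 30L, span = 7L) {
  hi <- min(hi, length(scores))
  if (hi - lo + 1L < span) return(-Inf)
  v <- scores[lo:hi]
  max(as.numeric(stats::filter(v, rep(1 / span, span), sides = 2)),
      na.rm = TRUE)
}

# Logistic weights for the signal-peptide score. Chosen so that the
# decision contract holds exactly: all three features present implies
# score >= 0.5, and a missing h-region (or a missing cleavage site)
# implies score < 0.5.
.sp_weights <- c(intercept = -4.3, n_region = 0.9, h_region = 2.6,
                 c_region = 1.9)

#' Score an N-terminal signal peptide
#'
#' A transparent logistic scorer over the three classical regions of a
#' signal peptide, evaluated on residues 1-45:
#' * n-region basicity: at least one K/R within residues 2-8;
#' * h-region hydrophobicity: some 7-residue window within residues 5-30
#'   with mean Kyte-Doolittle hydropathy >= 1.8;
#' * c-region cleavage site: a position in 15-45 obeying the (-3,-1)
#'   small-residue rule (-1 in {A,G,S,C,T,Q}, -3 in {A,G,S,C,T,V,I,L}).
#'
#' The three binary features are combined with fixed logistic weights
#' (see `sp_weights()`) such that all three present guarantees a score of
#' at least 0.5 while a missing h-region or missing cleavage site
#' guarantees a score below 0.5. The reported cleavage position is the
#' best-scoring (-3,-1) site, ranking sites by how canonical (small) the
#' -1 and -3 residues are and breaking ties toward the N-terminus.
#'
#' @param peptide Amino-acid string starting with M.
#' @return One-row tibble: `sp_score` in `[0, 1]`, `sp_cleavage_pos`
#'   (1-based index of the last signal-peptide residue, `NA` when no site
#'   qualifies), and the three logical feature columns `n_region`,
#'   `h_region`, `c_region`.
#' @examples
#' predict_signal_peptide(paste0("MKTLLILAVLAAVSSA", "EFDDRLQEHEAPKVED"))
#' @export
predict_signal_peptide <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  stopifnot(length(chars) >= 1L, chars[1L] == "M")
  scores <- .aa_scores(peptide)
  n_feat <- any(chars[seq.int(2L, min(8L, length(chars)))] %in% c("K", "R"))
  h_feat <- .best_h_window(scores) >= 1.8
  sites <- .cleavage_candidates(chars)
  c_feat <- nrow(sites) > 0L
  w <- .sp_weights
  eta <- w["intercept"] + w["n_region"] * n_feat + w["h_region"] * h_feat +
    w["c_region"] * c_feat
  cleave <- if (c_feat) {
    sites$pos[order(-sites$score, sites$pos)][1L]
  } else NA_integer_
  tibble::tibble(
    sp_score = unname(stats::plogis(eta)),
    sp_cleavage_pos = cleave,
    n_region = n_feat, h_region = h_feat, c_region = c_feat
  )
}

#' Fixed weights of the signal-peptide logistic scorer
#'
#' @return Named numeric vector of the intercept and the three feature
#'   weights.
#' @export
sp_weights <- function() .sp_weights

#' Predict an N-terminal mitochondrial targeting presequence
#'
#' Flags the composition characteristic of mitochondrial presequences:
#' residues 2-30 must contain at least 4 arginines, at most 1 acidic
#' residue (D/E), and at least 2 hydroxylated residues (S/T). A protein
#' whose N-terminus looks more like a secretory signal peptide - a
#' fully canonical (-3,-1) cleavage site (both -1 and -3 in {A,G,S})
#' together with a qualifying hydrophobic h-region - is not flagged,
#' mirroring how targeting predictors arbitrate between the two
#' competing N-terminal signals.
#'
#' @param peptide Amino-acid string starting with M.
#' @return `TRUE` if a mitochondrial presequence is predicted.
#' @export
predict_mito_targeting <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  stopifnot(length(chars) >= 1L, chars[1L] == "M")
  pre <- chars[seq.int(2L, min(30L, length(chars)))]
  composition_ok <- sum(pre == "R") >= 4L &&
    sum(pre %in% c("D", "E")) <= 1L &&
    sum(pre %in% c("S", "T")) >= 2L
  if (!composition_ok) return(FALSE)
  sites <- .cleavage_candidates(chars)
  sp_like <- any(sites$score >= 3L) &&
    .best_h_window(.aa_scores(peptide)) >= 1.8
  !sp_like
}

#' Remove redundant protein sequences
#'
#' Drops exact duplicates and sequences that are exact substrings of a
#' longer sequence, keeping the longest representative (ties broken by
#' lexicographically smallest id). Output order follows protein id.
#'
#' @param proteins Tibble with `protein_id` and `peptide` columns.
#' @return The non-redundant subset of rows.
#' @export
deduplicate_proteins <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  ord <- order(-nchar(proteins$peptide), proteins$protein_id)
  sorted <- proteins[ord, ]
  kept_seqs <- character(0)
  keep <- logical(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    s <- sorted$peptide[i]
    if (length(kept_seqs) == 0L ||
        !any(stringr::str_detect(kept_seqs, stringr::fixed(s)))) {
      keep[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
    }
  }
  out <- sorted[keep, ]
  out[order(out$protein_id), ]
}

#' Run the secreted-protein filtering cascade
#'
#' Applies the classical secretome filter to start-bearing proteins: a
#' protein is called secreted when it has a signal-peptide score of at
#' least 0.5, lacks a mitochondrial targeting presequence, and either has
#' no predicted transmembrane helix or a single one ending within the
#' first 60 residues (such early helices mostly are signal peptides
#' mis-called as membrane spans). Every protein receives exactly one
#' verdict; proteins not starting with M are `rejected_incomplete`.
#' Secreted proteins are partitioned into `full_length` (stop codon
#' present) and `c_terminal_truncated` precursors.
#'
#' @param proteins Tibble with `protein_id`, `peptide`, and optionally
#'   `completeness` (ORF completeness class; `complete` maps to
#'   `full_length`, `partial_3prime` to `c_terminal_truncated`).
#' @param sp_threshold Signal-peptide score threshold (default 0.5).
#' @param tm_first_aa Bound for the permitted single N-terminal helix:
#'   the helix must end at or before this residue (default 60).
#' @param tm_threshold,tm_min_span,window Passed to
#'   [predict_tm_helices()] / [kyte_doolittle_profile()].
#' @return Tibble with one row per protein: scores, cleavage position,
#'   number of predicted helices (`n_tm`), end of the first helix
#'   (`tm1_end`), `mito_flag`, `verdict`, `completeness_class`.
#' @export
secretome_filter <- function(proteins, sp_threshold = 0.5,
                             tm_first_aa = 60L, tm_threshold = 1.6,
                             tm_min_span = 15L, window = 17L) {
  stopifnot(all(c("protein_id", "peptide") %in% names(proteins)))
  completeness <- if ("completeness" %in% names(proteins)) {
    proteins$completeness
  } else rep("complete", nrow(proteins))
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    pep <- proteins$peptide[i]
    base <- tibble::tibble(
      protein_id = proteins$protein_id[i],
      sp_score = NA_real_, sp_cleavage_pos = NA_integer_,
      n_tm = NA_integer_, tm1_end = NA_integer_, mito_flag = NA,
      verdict = NA_character_,
      completeness_class = dplyr::case_when(
        completeness[i] == "complete" ~ "full_length",
        completeness[i] == "partial_3prime" ~ "c_terminal_truncated",
        .default = NA_character_
      )
    )
    if (!stringr::str_starts(pep, "M") || is.na(base$completeness_class)) {
      base$verdict <- "rejected_incomplete"
      return(base)
    }
    sp <- predict_signal_peptide(pep)
    tm <- predict_tm_helices(pep, threshold = tm_threshold,
                             min_span = tm_min_span, window = window)
    base$sp_score <- sp$sp_score
    base$sp_cleavage_pos <- sp$sp_cleavage_pos
    base$n_tm <- nrow(tm)
    base$tm1_end <- if (nrow(tm) > 0L) tm$end[1L] else NA_integer_
    base$mito_flag <- predict_mito_targeting(pep)
    base$verdict <- if (sp$sp_score < sp_threshold) {
      "rejected_no_signal"
    } else if (base$mito_flag) {
      "rejected_mito"
    } else if (nrow(tm) == 0L ||
               (nrow(tm) == 1L && tm$end[1L] <= tm_first_aa)) {
      "secreted"
    } else {
      "rejected_tm"
    }
    base
  })
  dplyr::bind_rows(rows)
}
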