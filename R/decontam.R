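# Cross-assembly contamination detection: a k-mer seeded, greedily
# extended local aligner (the only alignment regime the removal rule
# consults is near-identity), plus the expression-ratio removal rule.

# Greedy gapped extension from a seeded exact match. Sequences are
# integer vectors (utf8ToInt). Scoring: match +1, mismatch -2, gap -2.5,
# X-drop 20. At a mismatch the three edit options (substitution, gap in
# query, gap in subject) are compared by how long an exact-match run each
# re-synchronizes to (lookahead 10), preferring substitution on ties.
.extend_dir <- function(q, s, qi, si, step, xdrop = 20, lookahead = 10L) {
  nq <- length(q)
  ns <- length(s)
  score <- 0
  best <- list(score = 0, matches = 0L, columns = 0L)
  matches <- 0L
  columns <- 0L
  run_len <- function(i, j) {
    r <- 0L
    while (r < lookahead && i >= 1L && j >= 1L && i <= nq && j <= ns &&
           q[i] == s[j]) {
      r <- r + 1L; i <- i + step; j <- j + step
    }
    r
  }
  while (qi >= 1L && qi <= nq && si >= 1L && si <= ns) {
    if (q[qi] == s[si]) {
      score <- score + 1
      matches <- matches + 1L
      columns <- columns + 1L
      qi <- qi + step; si <- si + step
    } else {
      r_sub <- run_len(qi + step, si + step)
      r_gq <- run_len(qi, si + step)     # gap in query (consume subject)
      r_gs <- run_len(qi + step, si)     # gap in subject (consume query)
      if (r_sub >= r_gq && r_sub >= r_gs) {
        score <- score - 2
        columns <- columns + 1L
        qi <- qi + step; si <- si + step
      } else if (r_gq >= r_gs) {
        score <- score - 2.5
        columns <- columns + 1L
        si <- si + step
      } else {
        score <- score - 2.5
        columns <- columns + 1L
        qi <- qi + step
      }
    }
    if (score > best$score) {
      best <- list(score = score, matches = matches, columns = columns)
    }
    if (score < best$score - xdrop) break
  }
  best
}

.align_seeded <- function(q, s, qpos, spos, k, xdrop = 20) {
  right <- .extend_dir(q, s, qpos + k, spos + k, step = 1L, xdrop = xdrop)
  left <- .extend_dir(q, s, qpos - 1L, spos - 1L, step = -1L, xdrop = xdrop)
  matches <- k + left$matches + right$matches
  columns <- k + left$columns + right$columns
  list(score = k + left$score + right$score,
       alignment_length = columns,
       percent_identity = 100 * matches / columns)
}

.kmer_table <- function(seqs, ids, k) {
  purrr::map2(seqs, ids, function(s, id) {
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    tibble::tibble(id = id, pos = starts,
                   kmer = substring(s, starts, starts + k - 1L))
  }) |> dplyr::bind_rows()
}

#' Find near-identical matches between two assemblies
#'
#' A k-mer seeded local aligner: every shared k-mer between a query and a
#' subject sequence seeds a (query, subject, diagonal) candidate; for
#' each query-subject pair the best-supported diagonal is extended
#' greedily in both directions with match +1, mismatch -2, gap -2.5 and
#' an X-drop of 20, and the single best alignment is reported. Identity
#' is 100 * matches / alignment columns (gap columns included).
#'
#' @param assembly_a,assembly_b Transcript tibbles (query and subject).
#' @param k Seed length (default 21).
#' @param xdrop X-drop termination parameter (default 20).
#' @return Tibble of `query_id`, `subject_id`, `alignment_length`,
#'   `percent_identity`, `score`.
#' @export
find_cross_matches <- function(assembly_a, assembly_b, k = 21L, xdrop = 20) {
  stopifnot(nrow(assembly_a) > 0L, nrow(assembly_b) > 0L)
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          alignment_length = integer(),
                          percent_identity = numeric(), score = numeric())
  subj_kmers <- .kmer_table(assembly_b$sequence, assembly_b$transcript_id, k)
  query_kmers <- .kmer_table(assembly_a$sequence, assembly_a$transcript_id, k)
  if (nrow(subj_kmers) == 0L || nrow(query_kmers) == 0L) return(empty)
  seeds <- dplyr::inner_join(
    dplyr::rename(query_kmers, query_id = "id", qpos = "pos"),
    dplyr::rename(subj_kmers, subject_id = "id", spos = "pos"),
    by = "kmer", relationship = "many-to-many"
  )
  if (nrow(seeds) == 0L) return(empty)
  qseq <- stats::setNames(lapply(assembly_a$sequence, utf8ToInt),
                          assembly_a$transcript_id)
  sseq <- stats::setNames(lapply(assembly_b$sequence, utf8ToInt),
                          assembly_b$transcript_id)
  seeds |>
    dplyr::mutate(diag = .data$qpos - .data$spos) |>
    dplyr::group_by(.data$query_id, .data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      # best-supported diagonal, seed nearest the middle of its support
      top <- df |>
        dplyr::count(.data$diag, sort = TRUE) |>
        dplyr::slice(1L)
      on_diag <- df[df$diag == top$diag, ]
      seed <- on_diag[ceiling(nrow(on_diag) / 2), ]
      aln <- .align_seeded(qseq[[key$query_id]], sseq[[key$subject_id]],
                           seed$qpos, seed$spos, k = k, xdrop = xdrop)
      tibble::tibble(alignment_length = aln$alignment_length,
                     percent_identity = aln$percent_identity,
                     score = aln$score)
    }) |>
    dplyr::ungroup()
}

#' Apply the contamination removal rule
#'
#' A query component is removed when any of its member sequences has a
#' cross-assembly match of at least `min_len` aligned nucleotides, at
#' least `min_identity` percent identity, and a query TPM at or below
#' `max_tpm_ratio` times the subject TPM (all three comparisons
#' inclusive). An unexpressed subject (TPM 0) cannot certify
#' contamination. Removal is component-atomic: every transcript of a
#' flagged component is dropped together.
#'
#' @param matches Match tibble from [find_cross_matches()] with
#'   `query_tpm` and `subject_tpm` columns attached.
#' @param min_len Minimum alignment length (default 50 nt).
#' @param min_identity Minimum percent identity (default 97).
#' @param max_tpm_ratio Maximum query/subject TPM ratio (default 0.1).
#' @return Tibble with one row per query component: `component_id`,
#'   `removed`, and the triggering match columns (`NA` when kept).
#' @export
flag_contaminants <- function(matches, min_len = 50L, min_identity = 97,
                              max_tpm_ratio = 0.1) {
  stopifnot(all(c("query_tpm", "subject_tpm") %in% names(matches)))
  flagged <- matches |>
    dplyr::mutate(
      component_id = parse_trinity_id(.data$query_id)$component_id,
      triggers = .data$alignment_length >= min_len &
        .data$percent_identity >= min_identity &
        .data$subject_tpm > 0 &
        .data$query_tpm <= max_tpm_ratio * .data$subject_tpm
    )
  flagged |>
    dplyr::arrange(dplyr::desc(.data$triggers),
                   dplyr::desc(.data$percent_identity)) |>
    dplyr::distinct(.data$component_id, .keep_all = TRUE) |>
    dplyr::transmute(
      component_id = .data$component_id,
      removed = .data$triggers,
      triggering_query = dplyr::if_else(.data$triggers, .data$query_id,
                                        NA_character_),
      triggering_subject = dplyr::if_else(.data$triggers, .data$subject_id,
                                          NA_character_),
      alignment_length = dplyr::if_else(.data$triggers,
                                        .data$alignment_length, NA_integer_),
      percent_identity = dplyr::if_else(.data$triggers,
                                        .data$percent_identity, NA_real_),
      query_tpm = dplyr::if_else(.data$triggers, .data$query_tpm, NA_real_),
      subject_tpm = dplyr::if_else(.data$triggers, .data$subject_tpm,
                                   NA_real_)
    ) |>
    dplyr::arrange(.data$component_id)
}

#' Remove cross-assembly contamination from an assembly
#'
#' Composes [find_cross_matches()] and [flag_contaminants()]: aligns the
#' focal assembly against another co-sequenced assembly, attaches
#' subcomponent-level TPM values to both sides of every match, applies
#' the removal rule, and drops flagged components in their entirety.
#'
#' @param assembly_a Focal transcript tibble (cleaned).
#' @param assembly_b Other transcript tibble (contamination source).
#' @param expr_a,expr_b Expression tibbles (`subcomponent_id`, `tpm`)
#'   covering the matched sequences of each assembly.
#' @param min_len,min_identity,max_tpm_ratio Removal rule parameters, see
#'   [flag_contaminants()].
#' @param k Seed length for the aligner.
#' @param matches Optional pre-computed match tibble (e.g. from an
#'   external aligner's tabular output via [read_hits_tab()], renamed to
#'   `query_id`/`subject_id`/`alignment_length`/`percent_identity`);
#'   when supplied the internal aligner is skipped.
#' @return List with `clean` (the retained transcript tibble) and
#'   `verdicts` (per-component removal table).
#' @export
decontaminate <- function(assembly_a, assembly_b, expr_a, expr_b,
                          min_len = 50L, min_identity = 97,
                          max_tpm_ratio = 0.1, k = 21L, matches = NULL) {
  if (nrow(assembly_b) == 0L) {
    return(list(clean = assembly_a,
                verdicts = tibble::tibble(component_id = character(),
                                          removed = logical())))
  }
  if (is.null(matches)) {
    matches <- find_cross_matches(assembly_a, assembly_b, k = k)
  }
  if (nrow(matches) == 0L) {
    return(list(clean = assembly_a,
                verdicts = tibble::tibble(component_id = character(),
                                          removed = logical())))
  }
  tpm_of <- function(ids, expr, side) {
    sub <- parse_trinity_id(ids)$subcomponent_id
    hit <- match(sub, expr$subcomponent_id)
    if (anyNA(hit)) {
      stop("no TPM value for matched ", side, " sequence(s): ",
           paste(utils::head(ids[is.na(hit)], 5L), collapse = ", "),
           call. = FALSE)
    }
    expr$tpm[hit]
  }
  matches$query_tpm <- tpm_of(matches$query_id, expr_a, "query")
  matches$subject_tpm <- tpm_of(matches$subject_id, expr_b, "subject")
  verdicts <- flag_contaminants(matches, min_len = min_len,
                                min_identity = min_identity,
                                max_tpm_ratio = max_tpm_ratio)
  drop <- verdicts$component_id[verdicts$removed]
  list(clean = dplyr::filter(assembly_a, !.data$component_id %in% drop),
       verdicts = verdicts)
}
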