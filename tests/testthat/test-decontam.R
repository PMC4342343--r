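two_seqs <- function(q, s) {
  list(a = as_transcript_tbl(c(comp1_c0_seq1 = q)),
       b = as_transcript_tbl(c(comp2_c0_seq1 = s)))
}

test_that("identical sequences align end to end at 100% identity", {
  set.seed(71)
  s <- random_dna(200)
  x <- two_seqs(s, s)
  m <- find_cross_matches(x$a, x$b)
  expect_equal(nrow(m), 1)
  expect_equal(m$alignment_length, 200)
  expect_equal(m$percent_identity, 100)
})

test_that("sequences sharing no seed k-mer produce no match", {
  x <- two_seqs(strrep("AC", 100), strrep("GT", 100))
  expect_equal(nrow(find_cross_matches(x$a, x$b)), 0)
})

test_that("identity agrees with a full local-alignment oracle", {
  set.seed(72)
  mat <- matrix(-2, 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
  diag(mat) <- 1
  for (i in 1:10) {
    s <- random_dna(200)
    qc <- strsplit(s, "")[[1]]
    for (p in sample(30:170, 3)) {
      qc[p] <- sample(setdiff(c("A", "C", "G", "T"), qc[p]), 1)
    }
    q <- paste(qc, collapse = "")
    x <- two_seqs(q, s)
    m <- find_cross_matches(x$a, x$b)
    sw <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2.5)
    expect_lte(abs(m$percent_identity - Biostrings::pid(sw)), 0.5)
  }
})

test_that("the removal rule is inclusive at all three boundaries", {
  base <- tibble::tibble(
    query_id = "comp1_c0_seq1", subject_id = "comp2_c0_seq1",
    alignment_length = 60L, percent_identity = 98,
    query_tpm = 1, subject_tpm = 50)
  expect_true(flag_contaminants(base)$removed)

  ratio_above <- dplyr::mutate(base, query_tpm = 10)
  expect_false(flag_contaminants(ratio_above)$removed)

  too_short <- dplyr::mutate(base, alignment_length = 49L,
                             percent_identity = 100, query_tpm = 0.1,
                             subject_tpm = 100)
  expect_false(flag_contaminants(too_short)$removed)

  # all three thresholds exactly at their bounds: still removed
  boundary <- tibble::tibble(
    query_id = "comp1_c0_seq1", subject_id = "comp2_c0_seq1",
    alignment_length = 50L, percent_identity = 97,
    query_tpm = 5, subject_tpm = 50)
  expect_true(flag_contaminants(boundary)$removed)

  # an unexpressed subject cannot certify contamination
  dead <- dplyr::mutate(base, query_tpm = 0, subject_tpm = 0)
  expect_false(flag_contaminants(dead)$removed)
})

test_that("removal is component-atomic and swaps with the TPM roles", {
  matches <- tibble::tibble(
    query_id = c("comp1_c0_seq1", "comp1_c1_seq1"),
    subject_id = c("comp9_c0_seq1", "comp9_c0_seq1"),
    alignment_length = c(80L, 40L), percent_identity = c(99, 99),
    query_tpm = c(1, 500), subject_tpm = c(50, 50))
  v <- flag_contaminants(matches)
  expect_equal(nrow(v), 1)
  expect_true(v$removed)  # one triggering member suffices

  swapped <- dplyr::mutate(matches,
                           query_tpm = c(500, 500), subject_tpm = c(1, 1))
  expect_false(flag_contaminants(swapped)$removed)
})

test_that("decontaminate removes planted contaminants and keeps orthologs", {
  g <- generate_transcriptome(sim_config(
    seed = 73, n_components = 50, n_orfs = 20, n_secreted = 5, n_tm = 3,
    n_mito = 3, n_cytosolic = 5))
  A <- g$assembly
  gB <- generate_transcriptome(sim_config(
    seed = 74, n_components = 40, n_orfs = 15, n_secreted = 4, n_tm = 2,
    n_mito = 2, n_cytosolic = 4))
  B <- gB$assembly
  set.seed(75)
  exprA <- tibble::tibble(
    subcomponent_id = unique(A$subcomponent_id),
    tpm = stats::runif(dplyr::n_distinct(A$subcomponent_id), 50, 500))
  exprB <- tibble::tibble(
    subcomponent_id = unique(B$subcomponent_id),
    tpm = stats::runif(dplyr::n_distinct(B$subcomponent_id), 50, 500))

  n_comp_a <- dplyr::n_distinct(A$component_id)
  contam <- inject_contamination(A, B, exprA, exprB,
                                 fraction = 20 / n_comp_a,
                                 expression_ratio = 0.01,
                                 mutation_rate = 0.01, seed = 76)
  expect_equal(nrow(contam$truth), 20)
  # high-expression near-orthologs at ~85% identity must not be removed
  ortho <- inject_contamination(A, contam$assembly, exprA, contam$expr,
                                fraction = 8 / n_comp_a,
                                expression_ratio = 1,
                                mutation_rate = 0.15, seed = 77)
  dec <- decontaminate(ortho$assembly, A, ortho$expr, exprA)
  removed <- dec$verdicts$component_id[dec$verdicts$removed]
  expect_gte(sum(contam$truth$component_id %in% removed), 19)
  expect_equal(sum(ortho$truth$component_id %in% removed), 0)
  # component-atomic: no removed component survives partially
  expect_equal(
    length(intersect(unique(dec$clean$component_id), removed)), 0)
})

test_that("degenerate inputs pass through unchanged", {
  g <- generate_transcriptome(sim_config(
    seed = 78, n_components = 10, n_orfs = 0, n_secreted = 0, n_tm = 0,
    n_mito = 0, n_cytosolic = 0))
  A <- g$assembly
  expr <- tibble::tibble(subcomponent_id = unique(A$subcomponent_id),
                         tpm = 10)
  # identical assemblies with equal TPM: ratio 1 > 0.1, nothing removed
  self <- decontaminate(A, A, expr, expr)
  expect_equal(nrow(self$clean), nrow(A))
  expect_false(any(self$verdicts$removed))
  # empty other assembly: input returned unchanged
  none <- decontaminate(A, A[0, ], expr, expr[0, ])
  expect_equal(none$clean, A)
})

test_that("a matched sequence without a TPM value is reported by id", {
  set.seed(79)
  s <- random_dna(120)
  a <- as_transcript_tbl(c(comp1_c0_seq1 = s))
  b <- as_transcript_tbl(c(comp2_c0_seq1 = s))
  expr_a <- tibble::tibble(subcomponent_id = "comp1_c0", tpm = 1)
  expect_error(
    decontaminate(a, b, expr_a,
                  tibble::tibble(subcomponent_id = character(),
                                 tpm = numeric())),
    "comp2_c0_seq1")
})
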