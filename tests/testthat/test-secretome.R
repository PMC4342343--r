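# A canonical tripartite signal peptide used across the cascade tests:
# basic n-region, hydrophobic h-region, c-region ending at an A with the
# (-3,-1) small-residue site at position 16.
canonical_sp <- "MKTLLILAVLAAVSSA"
mature_tail <- "EFDDRLQEHEAPKVEDWNTKYEHQNNMFDDLTKNMDD"

test_that("hydropathy profile equals the windowed mean of the standard scale", {
  expect_equal(kyte_doolittle_profile(strrep("I", 17))$hydropathy, 4.5)
  expect_equal(kyte_doolittle_profile(strrep("G", 17))$hydropathy, -0.4,
               tolerance = 1e-12)
  expect_equal(nrow(kyte_doolittle_profile(strrep("A", 16))), 0)

  set.seed(51)
  for (i in 1:50) {
    pep <- paste(sample(names(tsapipe:::.kd_scale), 100, TRUE),
                 collapse = "")
    got <- kyte_doolittle_profile(pep)
    expect_equal(got$hydropathy, kd_oracle(pep), tolerance = 1e-12)
    expect_equal(nrow(got), 100 - 17 + 1)
  }
})

test_that("membrane helices are called from sustained hydrophobic runs", {
  one <- predict_tm_helices(paste0(strrep("S", 40), strrep("L", 30),
                                   strrep("S", 40)))
  expect_equal(nrow(one), 1)
  expect_gt(one$start, 30)
  expect_lt(one$end, 82)

  expect_equal(nrow(predict_tm_helices(strrep("S", 120))), 0)

  two <- predict_tm_helices(paste0(strrep("S", 30), strrep("L", 28),
                                   strrep("D", 40), strrep("I", 28),
                                   strrep("S", 30)))
  expect_equal(nrow(two), 2)
})

test_that("signal peptide scoring honours its decision contract", {
  full <- predict_signal_peptide(paste0(canonical_sp, mature_tail))
  expect_gte(full$sp_score, 0.5)
  expect_equal(full$sp_cleavage_pos, 16)

  # no h-region implies score < 0.5 regardless of the other features
  polyS <- predict_signal_peptide(paste0("MK", strrep("S", 20),
                                         mature_tail))
  expect_lt(polyS$sp_score, 0.5)
  # no (-3,-1) site in range implies score < 0.5
  no_c <- predict_signal_peptide(paste0("MK", strrep("L", 9),
                                        strrep("D", 40)))
  expect_false(no_c$c_region)
  expect_lt(no_c$sp_score, 0.5)
})

test_that("generator-planted signal peptides all score as secreted", {
  set.seed(52)
  g <- generate_transcriptome(sim_config(
    seed = 52, n_components = 5, n_orfs = 0, n_secreted = 100, n_tm = 0,
    n_mito = 0, n_cytosolic = 100))
  pt <- g$protein_truth
  sp_scores <- vapply(pt$peptide, function(p) {
    predict_signal_peptide(p)$sp_score
  }, numeric(1))
  expect_true(all(sp_scores[pt$category == "secreted"] >= 0.5))
  expect_gte(mean(sp_scores[pt$category == "cytosolic"] < 0.5), 0.95)
})

test_that("mitochondrial presequence rule separates the planted categories", {
  expect_true(predict_mito_targeting("MLSRLARRSFSTSAQLLRGGAARGLFAPRA"))
  expect_false(predict_mito_targeting(paste0("MDEDEDSST", strrep("A", 30))))

  g <- generate_transcriptome(sim_config(
    seed = 53, n_components = 5, n_orfs = 0, n_secreted = 60, n_tm = 0,
    n_mito = 60, n_cytosolic = 0))
  pt <- g$protein_truth
  mito_calls <- vapply(pt$peptide, predict_mito_targeting, logical(1))
  expect_gte(mean(mito_calls[pt$category == "mito"]), 0.9)
  expect_lte(mean(mito_calls[pt$category == "secreted"]), 0.05)
})

test_that("deduplication removes exact duplicates and substrings", {
  prot <- tibble::tibble(
    protein_id = c("p1", "p2", "p3", "p4"),
    peptide = c("MKLV", "MKLV", "MKLVVA", "KLVV"))
  out <- deduplicate_proteins(prot)
  expect_equal(out$peptide, "MKLVVA")

  set.seed(54)
  prot2 <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:20),
    peptide = replicate(20, paste(sample(c("A", "C", "D", "M"), 30, TRUE),
                                  collapse = "")))
  shuffled <- prot2[sample(nrow(prot2)), ]
  expect_equal(deduplicate_proteins(prot2), deduplicate_proteins(shuffled))
})

test_that("the cascade assigns each protein exactly one verdict per the rules", {
  proteins <- tibble::tibble(
    protein_id = sprintf("comp%d_c0_seq1", 1:5),
    peptide = c(
      paste0(canonical_sp, mature_tail),                        # secreted
      paste0(canonical_sp, strrep("D", 10), strrep("L", 26),
             strrep(mature_tail, 3)),                           # early TM
      paste0(canonical_sp, strrep("D", 90), strrep("L", 26),
             strrep("S", 40)),                                  # late TM
      paste0("MK", strrep("S", 20), mature_tail),               # no signal
      paste0(canonical_sp, mature_tail)),                       # truncated
    completeness = c("complete", "complete", "complete", "complete",
                     "internal"))
  calls <- secretome_filter(proteins)
  expect_equal(calls$verdict,
               c("secreted", "secreted", "rejected_tm",
                 "rejected_no_signal", "rejected_incomplete"))
  # single TM helix entirely within the first 60 residues is tolerated
  expect_equal(calls$n_tm[2], 1)
  expect_lte(calls$tm1_end[2], 60)
  expect_equal(calls$completeness_class[1], "full_length")
  # verdicts partition the input
  expect_true(all(table(calls$protein_id) == 1))
})

test_that("ablating the signal or inserting a helix flips the verdict", {
  g <- generate_transcriptome(sim_config(
    seed = 55, n_components = 5, n_orfs = 0, n_secreted = 25, n_tm = 0,
    n_mito = 0, n_cytosolic = 0))
  pt <- g$protein_truth
  calls <- secretome_filter(tibble::tibble(
    protein_id = pt$protein_id, peptide = pt$peptide,
    completeness = pt$completeness))
  secreted <- which(calls$verdict == "secreted")
  expect_gte(length(secreted), 20)
  for (i in secreted[1:10]) {
    pep <- pt$peptide[i]
    # delete the detected signal peptide (restore a start M)
    ablated <- paste0("M", substring(pep, calls$sp_cleavage_pos[i] + 1))
    v1 <- secretome_filter(tibble::tibble(
      protein_id = "x", peptide = ablated, completeness = "complete"))
    expect_equal(v1$verdict, "rejected_no_signal")
    # insert a 25-residue poly-Leu block at residue 100, keeping polar
    # context on both sides of the block
    padded <- if (nchar(pep) < 100) {
      paste0(pep, strrep("N", 100 - nchar(pep)))
    } else {
      pep
    }
    with_tm <- paste0(substring(padded, 1, 100), strrep("L", 25),
                      substring(padded, 101), strrep("N", 30))
    v2 <- secretome_filter(tibble::tibble(
      protein_id = "x", peptide = with_tm, completeness = "complete"))
    expect_equal(v2$verdict, "rejected_tm")
  }
})

test_that("secreted calls always carry a cleavage site within 45 residues", {
  g <- generate_transcriptome(sim_config(
    seed = 56, n_components = 5, n_orfs = 0, n_secreted = 40, n_tm = 10,
    n_mito = 10, n_cytosolic = 40))
  pt <- g$protein_truth
  calls <- secretome_filter(tibble::tibble(
    protein_id = pt$protein_id, peptide = pt$peptide,
    completeness = pt$completeness))
  secreted <- calls[calls$verdict == "secreted", ]
  expect_true(all(!is.na(secreted$sp_cleavage_pos)))
  expect_true(all(secreted$sp_cleavage_pos <= 45))
})
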