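test_that("TPM normalizes length-corrected counts to one million", {
  out <- compute_tpm(tibble::tibble(
    subcomponent_id = c("comp0_c0", "comp1_c0"),
    est_count = c(10, 10), effective_length = c(100, 200)))
  expect_equal(out$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  single <- compute_tpm(tibble::tibble(
    subcomponent_id = "comp0_c0", est_count = 7, effective_length = 123))
  expect_equal(single$tpm, 1e6)

  zero <- compute_tpm(tibble::tibble(
    subcomponent_id = c("comp0_c0", "comp1_c0"),
    est_count = c(0, 5), effective_length = c(100, 100)))
  expect_equal(zero$tpm, c(0, 1e6))

  expect_error(compute_tpm(tibble::tibble(
    subcomponent_id = "a", est_count = 1, effective_length = 0)),
    "positive")
})

test_that("TPM sums to one million and is scaling-invariant", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    expr <- tibble::tibble(
      subcomponent_id = sprintf("comp%d_c0", seq_len(n)),
      est_count = stats::rpois(n, 40),
      effective_length = sample(200:2000, n, replace = TRUE))
    if (sum(expr$est_count) == 0) expr$est_count[1] <- 1
    out <- compute_tpm(expr)
    expect_equal(sum(out$tpm), 1e6, tolerance = 1e-3)
    scaled <- expr
    scaled$est_count <- scaled$est_count * 7.5
    expect_equal(compute_tpm(scaled)$tpm, out$tpm, tolerance = 1e-9)
  }
})

test_that("EM with uniquely mapping reads reproduces direct TPM exactly", {
  set.seed(42)
  lens <- c(comp1_c0 = 150, comp2_c0 = 300, comp3_c0 = 600)
  counts <- c(30, 50, 20)
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", seq_len(sum(counts))),
    subcomponent_id = rep(names(lens), counts))
  fit <- em_allocate(reads, lens)
  direct <- compute_tpm(tibble::tibble(
    subcomponent_id = names(lens), est_count = counts,
    effective_length = unname(lens)))
  got <- tidy(fit)
  expect_equal(got$tpm[match(direct$subcomponent_id, got$subcomponent_id)],
               direct$tpm, tolerance = 1e-6)
  expect_equal(got$est_count[match(direct$subcomponent_id,
                                   got$subcomponent_id)],
               counts, tolerance = 1e-9)
})

test_that("fully ambiguous reads split evenly between identical twins", {
  reads <- tidyr::expand_grid(
    read_id = sprintf("r%02d", 1:40),
    subcomponent_id = c("comp1_c0", "comp1_c1"))
  fit <- em_allocate(reads, c(comp1_c0 = 200, comp1_c1 = 200))
  expect_equal(tidy(fit)$tpm, c(5e5, 5e5), tolerance = 1e-6)
})

test_that("the EM log-likelihood is non-decreasing at every step", {
  set.seed(43)
  g <- generate_transcriptome(sim_config(
    seed = 5, n_components = 30, n_orfs = 0, n_secreted = 0, n_tm = 0,
    n_mito = 0, n_cytosolic = 0))
  subs <- unique(g$assembly$subcomponent_id)
  theta <- as.numeric(stats::rmultinom(1, 5000, rep(1, length(subs))))
  theta <- theta / sum(theta)
  names(theta) <- subs
  reads <- generate_reads(g$assembly, theta, n_reads = 4000,
                          ambiguity = 0.3, seed = 44)
  lens <- dplyr::summarise(dplyr::group_by(g$assembly, subcomponent_id),
                           effective_length = max(length),
                           .groups = "drop")
  fit <- em_allocate(reads, lens)
  diffs <- diff(fit$log_likelihood)
  expect_true(all(diffs >= -1e-9))
})

test_that("EM recovers simulated proportions within binomial error", {
  theta <- c(comp1_c0 = 0.7, comp1_c1 = 0.2, comp1_c2 = 0.1)
  assembly <- as_transcript_tbl(stats::setNames(
    replicate(3, random_dna(500)),
    c("comp1_c0_seq1", "comp1_c1_seq1", "comp1_c2_seq1")))
  n_reads <- 20000
  reads <- generate_reads(assembly, theta, n_reads = n_reads,
                          ambiguity = 0.25, seed = 45)
  fit <- em_allocate(reads, stats::setNames(rep(500, 3), names(theta)))
  got <- tidy(fit)
  rec <- got$tpm[match(names(theta), got$subcomponent_id)] / 1e6
  se <- sqrt(theta * (1 - theta) / n_reads)
  expect_true(all(abs(rec - theta) <= 3 * se))
  expect_true(glance(fit)$converged)
})

test_that("unknown read targets are rejected by name", {
  reads <- tibble::tibble(read_id = "r1", subcomponent_id = "comp9_c9")
  expect_error(em_allocate(reads, c(comp1_c0 = 100)), "comp9_c9")
})

test_that("expression share reproduces subset sums, share and fold", {
  set.seed(46)
  expr <- tibble::tibble(
    subcomponent_id = sprintf("comp%d_c0", 1:100),
    tpm = c(rep(800, 10), rep(20, 90)))
  share <- expression_share(expr, sprintf("comp%d_c0", 1:10))
  expect_equal(share$sum_subset, 8000)
  expect_equal(share$percent_share, 100 * 8000 / (8000 + 1800))
  expect_equal(share$fold, 800 / 20)

  all_in <- expression_share(expr, expr$subcomponent_id)
  expect_equal(all_in$percent_share, 100)
  expect_true(is.nan(all_in$fold))
  none <- expression_share(expr, character(0))
  expect_equal(none$sum_subset, 0)
  expect_true(is.nan(none$fold))
})

test_that("top expressed ranks by TPM with stable id tie order", {
  expr <- tibble::tibble(
    subcomponent_id = c("comp3_c0", "comp1_c0", "comp2_c0", "comp4_c0"),
    tpm = c(5, 10, 1, 5))
  top <- top_expressed(expr, n = 3)
  expect_equal(top$subcomponent_id, c("comp1_c0", "comp3_c0", "comp4_c0"))
  expect_equal(nrow(top_expressed(expr, n = 99)), 4)
  annotated <- top_expressed(
    expr, tibble::tibble(subcomponent_id = "comp1_c0", name = "actin"),
    n = 1)
  expect_equal(annotated$name, "actin")
})

test_that("RSEM-style expression tables round-trip", {
  expr <- tibble::tibble(
    subcomponent_id = c("comp1_c0", "comp2_c0"),
    est_count = c(10.5, 3), effective_length = c(100, 220),
    tpm = c(910000, 90000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(expr, path)
  back <- read_expression_tsv(path)
  expect_equal(back$tpm, expr$tpm)
  expect_equal(back$effective_length, expr$effective_length)
})
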