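# Synthetic transcriptome generator with ground-truth labels.
#
# The generator emulates the statistical structure every pipeline stage
# assumes: a multi-component Trinity-style assembly whose contig length
# distribution is log-normal with the bulk between 200 and 399 nt and a
# heavy right tail, an AT-rich base composition, open reading frames of
# all four completeness classes in configurable proportions, planted
# secreted precursors (tripartite signal peptide, convertase-flanked
# peptide repeats with amide-donor glycines), transmembrane and
# mitochondrial proteins, cytosolic controls, and cross-contaminated
# component pairs with strongly asymmetric expression. All templates are
# parameterized families randomized within rule-satisfying bounds, so the
# surrogate predictors are exercised on varied instances rather than a
# fixed string.

#' Configuration for the synthetic transcriptome generator
#'
#' Defaults describe a small assembly with the summary characteristics of
#' a molluscan CNS transcriptome: median contig length 363 nt with a
#' log-normal tail reaching ~20 knt, GC content 39.4%, and an ORF
#' completeness mix of 51.3% complete, 19.6% 5'-partial, 12.7% 3'-partial
#' and 16.4% internal.
#'
#' @param seed Integer RNG seed.
#' @param n_components Number of background (non-coding) components.
#' @param isoform_probs Probabilities of 1, 2, 3 isoforms per background
#'   component.
#' @param n_orfs Number of transcripts carrying a planted ORF.
#' @param class_mix Named proportions over the four completeness classes
#'   (must sum to 1).
#' @param length_meanlog,length_sdlog Log-normal contig length parameters.
#' @param gc_target Target GC percent.
#' @param orf_len_range Planted ORF length range in amino acids.
#' @param n_secreted,n_tm,n_mito,n_cytosolic Protein-category counts.
#' @param repeat_range Range of peptide repeat counts per secreted
#'   precursor (sampled uniformly unless `repeat_counts` is given).
#' @param repeat_counts Optional explicit repeat counts, recycled across
#'   secreted precursors.
#' @param contamination List with `fraction` of components copied,
#'   `expression_ratio` of contaminant to source TPM, and per-base
#'   substitution `mutation_rate`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_components = 150L,
                       isoform_probs = c(0.75, 0.18, 0.07),
                       n_orfs = 150L,
                       class_mix = c(complete = 0.513,
                                     partial_5prime = 0.196,
                                     partial_3prime = 0.127,
                                     internal = 0.164),
                       length_meanlog = log(363),
                       length_sdlog = 1.1,
                       gc_target = 39.4,
                       orf_len_range = c(100L, 250L),
                       n_secreted = 30L, n_tm = 20L, n_mito = 20L,
                       n_cytosolic = 30L,
                       repeat_range = c(2L, 10L),
                       repeat_counts = NULL,
                       contamination = list(fraction = 0.1,
                                            expression_ratio = 0.01,
                                            mutation_rate = 0.01)) {
  cfg <- as.list(environment())[names(formals(sim_config))]
  stopifnot(abs(sum(cfg$class_mix) - 1) < 1e-8,
            all(c(n_components, n_orfs, n_secreted, n_tm, n_mito,
                  n_cytosolic) >= 0),
            gc_target > 0, gc_target < 100,
            contamination$fraction >= 0, contamination$fraction <= 1)
  for (nm in c("seed", "n_components", "n_orfs", "n_secreted", "n_tm",
               "n_mito", "n_cytosolic", "orf_len_range", "repeat_range",
               "repeat_counts")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  structure(cfg, class = "sim_config")
}

# ---- base/codon sampling at a target GC ------------------------------

.base_probs <- function(gc) {
  g <- gc / 100
  c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
}

.sample_bases <- function(n, gc, alphabet = c("A", "C", "G", "T")) {
  p <- .base_probs(gc)[alphabet]
  paste(sample(alphabet, n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# A-free spacer: contains neither ATG nor stop codons in any frame.
.sample_utr <- function(n, gc) {
  if (n <= 0L) return("")
  .sample_bases(n, gc, alphabet = c("C", "G", "T"))
}

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.codon_weights <- function(codons, gc) {
  p <- .base_probs(gc)
  w <- vapply(strsplit(codons, "", fixed = TRUE),
              function(x) prod(p[x]), numeric(1))
  w / sum(w)
}

.sample_codons <- function(n, gc, exclude_atg = FALSE) {
  codons <- setdiff(.all_codons(), c("TAA", "TAG", "TGA"))
  if (exclude_atg) codons <- setdiff(codons, "ATG")
  if (n <= 0L) return("")
  paste(sample(codons, n, replace = TRUE,
               prob = .codon_weights(codons, gc)), collapse = "")
}

# Reverse-translate a peptide, choosing synonymous codons weighted toward
# the target base composition. The initial M keeps its ATG.
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc_code <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc_code), unname(gc_code))
    }
    tab
  }
})

.reverse_translate <- function(peptide, gc) {
  tab <- .codon_table()
  probs <- lapply(tab, .codon_weights, gc = gc)
  aas <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  codons <- vapply(aas, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1L) return(opts)
    sample(opts, 1L, prob = probs[[a]])
  }, character(1))
  paste(codons, collapse = "")
}

.sample_stop <- function() sample(c("TAA", "TAG", "TGA"), 1L)

.rlnorm_len <- function(n, meanlog, sdlog, lo = 200L, hi = 20000L) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

# ---- protein template families ---------------------------------------

.polar_nonbasic <- c("N", "Q", "S", "T", "H", "D", "E", "P", "Y", "G")
.hydrophobic <- c("L", "I", "V", "F")

# Tripartite signal peptide: n-region (basic), h-region (hydrophobic
# core), c-region ending in a canonical (-3,-1) site [S x A]. Total
# length 15-22 so the cleavage position always falls in the scorer's
# 15-45 search range.
.sample_signal_peptide <- function() {
  n_reg <- paste(c(sample(c("K", "R"), sample(1:2, 1L), replace = TRUE),
                   sample(c("N", "Q", "S", "T"), sample(1:2, 1L),
                          replace = TRUE)), collapse = "")
  h_reg <- paste(sample(.hydrophobic, sample(8:10, 1L), replace = TRUE),
                 collapse = "")
  c_reg <- paste0(sample(c("P", "N", "Q", "H"), 1L), "S",
                  sample(c("V", "Q", "N", "H", "E"), 1L), "A")
  sp <- paste0("M", n_reg, h_reg, c_reg)
  if (nchar(sp) < 15L) {
    sp <- paste0(substr(sp, 1L, nchar(sp) - 4L),
                 paste(sample(c("N", "Q", "T"), 15L - nchar(sp),
                              replace = TRUE), collapse = ""),
                 substr(sp, nchar(sp) - 3L, nchar(sp)))
  }
  sp
}

# Residues usable inside mature peptide repeats and spacers: no basics
# (would create spurious convertase sites), no G at the end ambiguity.
.mature_alphabet <- c("A", "D", "E", "F", "H", "I", "L", "M", "N", "P",
                      "Q", "S", "T", "V", "W", "Y")

.sample_secreted_protein <- function(n_repeats) {
  sp <- .sample_signal_peptide()
  spacer <- paste(c("E", sample(c("D", "E", "N", "Q", "S", "T", "H", "Y"),
                                sample(5:12, 1L), replace = TRUE)),
                  collapse = "")
  motif <- paste(c(sample(setdiff(.mature_alphabet, "P"), 1L),
                   sample(.mature_alphabet, sample(3:8, 1L),
                          replace = TRUE)), collapse = "")
  tail <- paste(sample(setdiff(.mature_alphabet, "P"),
                       sample(3:8, 1L), replace = TRUE), collapse = "")
  peptide <- paste0(sp, spacer, "KR",
                    strrep(paste0(motif, "G", "KR"), n_repeats), tail)
  list(peptide = peptide, sp_end = nchar(sp), motif = motif,
       n_repeats = n_repeats)
}

.sample_tm_protein <- function() {
  sp <- .sample_signal_peptide()
  loop1 <- paste(sample(.polar_nonbasic, sample(50:70, 1L),
                        replace = TRUE), collapse = "")
  block <- paste(sample(.hydrophobic, sample(24:30, 1L), replace = TRUE),
                 collapse = "")
  loop2 <- paste(sample(.polar_nonbasic, sample(30:60, 1L),
                        replace = TRUE), collapse = "")
  list(peptide = paste0(sp, loop1, block, loop2), sp_end = nchar(sp))
}

# Mitochondrial presequence: 29 residues covering positions 2-30,
# arginine-rich, acid-free, with hydroxylated residues, hydrophobic
# filler interleaved so no 7-residue window becomes h-region-like.
.sample_mito_protein <- function() {
  n_r <- sample(5:7, 1L)
  n_st <- sample(4:7, 1L)
  filler <- sample(c("A", "G", "P", "L", "F"), 29L - n_r - n_st,
                   replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
  pre <- character(29L)
  # evenly spaced arginines: every 7-residue window in the presequence
  # contains a basic residue, the amphipathic signature of a presequence
  slots <- round(seq(2L, 28L, length.out = n_r))
  pre[slots] <- "R"
  pre[setdiff(seq_len(29L), slots)] <-
    sample(c(rep(c("S", "T"), length.out = n_st), filler))
  mature <- paste(sample(names(.natural_aa_freq), sample(80:200, 1L),
                         replace = TRUE, prob = .natural_aa_freq),
                  collapse = "")
  list(peptide = paste0("M", paste(pre, collapse = ""), mature))
}

# Approximate vertebrate/invertebrate average amino-acid frequencies.
.natural_aa_freq <- c(
  A = 0.083, R = 0.057, N = 0.041, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.062, G = 0.072, H = 0.022, I = 0.060, L = 0.097, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.069
)

# Cytosolic proteins: natural composition overall, but with the
# N-terminal ~40 residues drawn hydrophilic-leaning - cytosolic
# N-termini lack the committed hydrophobic h-region that defines a
# signal peptide, and that contrast is precisely what the scorer uses.
.sample_cytosolic_protein <- function() {
  w <- .natural_aa_freq
  w[.hydrophobic] <- w[.hydrophobic] / 4
  w[c("M", "C", "A")] <- w[c("M", "C", "A")] / 2
  nterm <- paste(sample(names(w), 39L, replace = TRUE, prob = w / sum(w)),
                 collapse = "")
  rest <- paste(sample(names(.natural_aa_freq), sample(100:300, 1L),
                       replace = TRUE, prob = .natural_aa_freq),
                collapse = "")
  list(peptide = paste0("M", nterm, rest))
}

# ---- transcript construction -----------------------------------------

# Wrap a peptide as a complete ORF inside a transcript: A-free 5' UTR,
# ATG-initiated coding sequence, stop, A-free 3' UTR.
.embed_complete <- function(peptide, gc, utr5 = NULL, utr3 = NULL) {
  if (is.null(utr5)) utr5 <- sample(10:120, 1L)
  if (is.null(utr3)) utr3 <- sample(10:200, 1L)
  cds <- .reverse_translate(peptide, gc)
  seq <- paste0(.sample_utr(utr5, gc), cds, .sample_stop(),
                .sample_utr(utr3, gc))
  list(sequence = seq, nt_start = utr5, nt_end = utr5 + nchar(cds))
}

.build_orf_transcript <- function(class, aa_len, gc) {
  if (class == "complete") {
    utr5 <- sample(10:120, 1L)
    utr3 <- sample(10:200, 1L)
    cds <- paste0("ATG", .sample_codons(aa_len - 1L, gc,
                                        exclude_atg = FALSE))
    seq <- paste0(.sample_utr(utr5, gc), cds, .sample_stop(),
                  .sample_utr(utr3, gc))
    s <- utr5
  } else if (class == "partial_5prime") {
    utr3 <- sample(10:200, 1L)
    cds <- .sample_codons(aa_len, gc, exclude_atg = TRUE)
    seq <- paste0(cds, .sample_stop(), .sample_utr(utr3, gc))
    s <- 0L
  } else if (class == "partial_3prime") {
    utr5 <- sample(10:120, 1L)
    cds <- paste0("ATG", .sample_codons(aa_len - 1L, gc,
                                        exclude_atg = FALSE))
    seq <- paste0(.sample_utr(utr5, gc), cds)
    s <- utr5
  } else { # internal
    cds <- .sample_codons(aa_len, gc, exclude_atg = TRUE)
    seq <- cds
    s <- 0L
  }
  list(sequence = seq, nt_start = s, nt_end = s + 3L * aa_len,
       length_aa = aa_len)
}

# ---- top-level generator ---------------------------------------------

#' Generate a truth-labelled synthetic assembly
#'
#' Produces a Trinity-style transcript table together with ground-truth
#' labels for every planted feature: ORF coordinates and completeness
#' class, protein category (secreted / tm / mito / cytosolic), signal
#' peptide ends, peptide repeat motifs and counts. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List with `assembly` (transcript tibble), `orf_truth`
#'   (per-planted-ORF tibble: `transcript_id`, `completeness`,
#'   `nt_start`, `nt_end`, `length_aa`), and `protein_truth`
#'   (per-protein tibble: `transcript_id`, `protein_id`, `category`,
#'   `peptide`, `sp_end`, `repeat_motif`, `n_repeats`).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_target
  seqs <- character(0)
  ids <- character(0)
  comp <- 0L

  new_id <- function(iso = 1L, sub = 0L) {
    sprintf("comp%d_c%d_seq%d", comp, sub, iso)
  }

  # background components: non-coding contigs, occasionally with extra
  # isoforms made by internal deletion of the first isoform. Their base
  # composition is solved after the coding transcripts are built, so that
  # the realized whole-assembly GC hits the target; only the skeleton
  # (lengths, isoform structure) is drawn here.
  n_iso <- sample(seq_along(config$isoform_probs), config$n_components,
                  replace = TRUE, prob = config$isoform_probs)
  bg <- vector("list", config$n_components)
  for (i in seq_len(config$n_components)) {
    comp <- comp + 1L
    L <- .rlnorm_len(1L, config$length_meanlog, config$length_sdlog)
    cuts <- NULL
    if (n_iso[i] > 1L && L >= 450L) {
      cuts <- lapply(seq_len(n_iso[i] - 1L), function(j) {
        cut_len <- sample(50:(L - 400L), 1L)
        cut_at <- sample(100:(L - cut_len - 100L), 1L)
        c(cut_at, cut_len)
      })
    }
    bg[[i]] <- list(comp = comp, L = L, cuts = cuts)
  }

  # ORF-bearing transcripts of the four completeness classes
  classes <- sample(names(config$class_mix), config$n_orfs, replace = TRUE,
                    prob = config$class_mix)
  orf_truth <- vector("list", config$n_orfs)
  for (i in seq_len(config$n_orfs)) {
    comp <- comp + 1L
    aa <- sample(config$orf_len_range[1]:config$orf_len_range[2], 1L)
    tr <- .build_orf_transcript(classes[i], aa, gc)
    id <- new_id()
    ids <- c(ids, id)
    seqs <- c(seqs, tr$sequence)
    orf_truth[[i]] <- tibble::tibble(
      transcript_id = id, completeness = classes[i],
      nt_start = tr$nt_start, nt_end = tr$nt_end, length_aa = aa
    )
  }

  # protein-category transcripts (all embedded as complete ORFs except
  # that a third of secreted precursors are left 3'-truncated)
  protein_truth <- list()
  add_protein <- function(category, built, truncate3 = FALSE) {
    comp <<- comp + 1L
    id <- new_id()
    if (truncate3) {
      utr5 <- sample(10:60, 1L)
      cds <- .reverse_translate(built$peptide, gc)
      seq <- paste0(.sample_utr(utr5, gc), cds)
    } else {
      emb <- .embed_complete(built$peptide, gc)
      seq <- emb$sequence
    }
    ids <<- c(ids, id)
    seqs <<- c(seqs, seq)
    protein_truth[[length(protein_truth) + 1L]] <<- tibble::tibble(
      transcript_id = id, protein_id = id, category = category,
      peptide = built$peptide,
      sp_end = built$sp_end %||% NA_integer_,
      repeat_motif = built$motif %||% NA_character_,
      n_repeats = built$n_repeats %||% NA_integer_,
      completeness = if (truncate3) "partial_3prime" else "complete"
    )
  }
  if (config$n_secreted > 0L) {
    reps <- if (!is.null(config$repeat_counts)) {
      rep_len(config$repeat_counts, config$n_secreted)
    } else {
      sample(config$repeat_range[1]:config$repeat_range[2],
             config$n_secreted, replace = TRUE)
    }
    for (i in seq_len(config$n_secreted)) {
      add_protein("secreted", .sample_secreted_protein(reps[i]),
                  truncate3 = i %% 3L == 0L)
    }
  }
  for (i in seq_len(config$n_tm)) add_protein("tm", .sample_tm_protein())
  for (i in seq_len(config$n_mito)) add_protein("mito", .sample_mito_protein())
  for (i in seq_len(config$n_cytosolic)) {
    add_protein("cytosolic", .sample_cytosolic_protein())
  }

  # solve the background GC so the assembly-wide GC lands on target
  coding_chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  gc_coding <- sum(coding_chars %in% c("G", "C"))
  b_coding <- length(coding_chars)
  b_bg <- sum(vapply(bg, function(x) {
    x$L * (1L + length(x$cuts)) -
      sum(vapply(x$cuts, `[`, numeric(1), 2L))
  }, numeric(1)))
  g_bg <- if (b_bg > 0) {
    (gc / 100 * (b_coding + b_bg) - gc_coding) / b_bg
  } else gc / 100
  g_bg <- 100 * min(max(g_bg, 0.2), 0.6)

  for (x in bg) {
    comp_save <- comp
    comp <- x$comp
    base_seq <- .sample_bases(x$L, g_bg)
    ids <- c(ids, new_id(1L))
    seqs <- c(seqs, base_seq)
    for (j in seq_along(x$cuts)) {
      cut_at <- x$cuts[[j]][1L]
      cut_len <- x$cuts[[j]][2L]
      ids <- c(ids, new_id(j + 1L))
      seqs <- c(seqs, paste0(substr(base_seq, 1L, cut_at),
                             substr(base_seq, cut_at + cut_len + 1L, x$L)))
    }
    comp <- comp_save
  }

  list(
    assembly = as_transcript_tbl(stats::setNames(seqs, ids)),
    orf_truth = dplyr::bind_rows(orf_truth),
    protein_truth = dplyr::bind_rows(protein_truth)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Simulate reads with known abundances and controlled ambiguity
#'
#' Draws reads from subcomponents with probability proportional to
#' `theta * length` (so `theta` is the molar / TPM-scale proportion), and
#' makes a configurable fraction of reads additionally compatible with a
#' random sibling subcomponent, emulating multi-mapping.
#'
#' @param assembly Transcript tibble; subcomponent effective length is
#'   taken as its longest member transcript.
#' @param theta Named numeric vector of true proportions over
#'   subcomponent ids (must sum to 1).
#' @param n_reads Number of reads.
#' @param ambiguity Fraction of reads made ambiguous (default 0).
#' @param seed RNG seed.
#' @return Long tibble (`read_id`, `subcomponent_id`), one row per
#'   compatible subcomponent.
#' @export
generate_reads <- function(assembly, theta, n_reads, ambiguity = 0,
                           seed = 1L) {
  stopifnot(abs(sum(theta) - 1) < 1e-8, ambiguity >= 0, ambiguity <= 1)
  set.seed(seed)
  if (n_reads == 0L) {
    return(tibble::tibble(read_id = character(),
                          subcomponent_id = character()))
  }
  lens <- assembly |>
    dplyr::group_by(.data$subcomponent_id) |>
    dplyr::summarise(len = max(.data$length), .groups = "drop")
  ids <- names(theta)
  stopifnot(all(ids %in% lens$subcomponent_id))
  l <- lens$len[match(ids, lens$subcomponent_id)]
  p <- theta * l
  origin <- sample(ids, n_reads, replace = TRUE, prob = p / sum(p))
  reads <- tibble::tibble(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    subcomponent_id = origin
  )
  if (ambiguity > 0 && length(ids) > 1L) {
    amb <- which(stats::runif(n_reads) < ambiguity)
    comp_of <- parse_trinity_id(ids)$component_id
    extra <- purrr::map_chr(origin[amb], function(sc) {
      sibs <- ids[comp_of == comp_of[match(sc, ids)] & ids != sc]
      if (length(sibs) == 0L) sibs <- setdiff(ids, sc)
      sample(sibs, 1L)
    })
    reads <- dplyr::bind_rows(
      reads,
      tibble::tibble(read_id = reads$read_id[amb], subcomponent_id = extra)
    )
  }
  dplyr::arrange(reads, .data$read_id, .data$subcomponent_id)
}

#' Plant cross-assembly contamination
#'
#' Copies a fraction of source-assembly components into a recipient
#' assembly with per-base substitutions, and assigns each copy a TPM
#' equal to `expression_ratio` times its source subcomponent TPM -
#' reproducing the signature of carried-over material: near-identical
#' sequence at strongly asymmetric expression.
#'
#' @param assembly_from Source transcript tibble (the organism the
#'   material really comes from).
#' @param assembly_into Recipient transcript tibble (gains contaminants).
#' @param expr_from,expr_into Expression tibbles (`subcomponent_id`,
#'   `tpm`) for the two assemblies.
#' @param fraction Fraction of source components copied.
#' @param expression_ratio Contaminant TPM as a fraction of source TPM.
#' @param mutation_rate Per-base substitution probability in the copy.
#' @param seed RNG seed.
#' @return List with `assembly` (recipient plus contaminants), `expr`
#'   (recipient expression plus contaminant rows), and `truth` (tibble of
#'   `component_id` of each planted contaminant and its
#'   `source_component`).
#' @export
inject_contamination <- function(assembly_from, assembly_into,
                                 expr_from, expr_into,
                                 fraction = 0.1, expression_ratio = 0.01,
                                 mutation_rate = 0.01, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  if (fraction == 0) {
    return(list(assembly = assembly_into, expr = expr_into,
                truth = tibble::tibble(component_id = character(),
                                       source_component = character())))
  }
  src_components <- unique(assembly_from$component_id)
  n_pick <- max(1L, round(fraction * length(src_components)))
  picked <- sample(src_components, n_pick)
  # fresh component numbers, clash-free across both assemblies
  next_comp <- max(as.integer(stringr::str_extract(
    c(assembly_into$component_id, assembly_from$component_id),
    "\\d+"))) + 1L

  mutate_seq <- function(seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(chars)) < mutation_rate)
    for (h in hit) {
      chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1L)
    }
    paste(chars, collapse = "")
  }

  new_rows <- list()
  expr_rows <- list()
  truth <- list()
  for (i in seq_along(picked)) {
    src <- dplyr::filter(assembly_from, .data$component_id == picked[i]) |>
      dplyr::slice_max(.data$length, n = 1L, with_ties = FALSE)
    new_comp_id <- sprintf("comp%d", next_comp)
    new_tid <- sprintf("comp%d_c0_seq1", next_comp)
    next_comp <- next_comp + 1L
    new_rows[[i]] <- as_transcript_tbl(
      stats::setNames(mutate_seq(src$sequence), new_tid))
    src_tpm <- expr_from$tpm[match(src$subcomponent_id,
                                   expr_from$subcomponent_id)]
    stopifnot(!is.na(src_tpm))
    expr_rows[[i]] <- tibble::tibble(
      subcomponent_id = sprintf("%s_c0", new_comp_id),
      tpm = expression_ratio * src_tpm
    )
    truth[[i]] <- tibble::tibble(component_id = new_comp_id,
                                 source_component = picked[i])
  }
  list(
    assembly = dplyr::bind_rows(assembly_into, dplyr::bind_rows(new_rows)),
    expr = dplyr::bind_rows(expr_into, dplyr::bind_rows(expr_rows)),
    truth = dplyr::bind_rows(truth)
  )
}
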