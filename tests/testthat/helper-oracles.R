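# Independent oracle implementations used to cross-check the package:
# deliberately written with different mechanics (string scans, direct
# definition loops) than the implementation paths they verify.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# N50 by direct definition: largest L such that contigs >= L cover at
# least half the total bases.
n50_oracle <- function(lengths) {
  total <- sum(as.numeric(lengths))
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Six-frame ORF enumeration via translated-string scanning.
orf_oracle <- function(seq, min_len_aa) {
  gc_code <- Biostrings::GENETIC_CODE
  translate_str <- function(s) {
    n_cod <- nchar(s) %/% 3L
    if (n_cod == 0L) return("")
    cods <- substring(s, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    aa <- ifelse(grepl("[^ACGT]", cods), "X", gc_code[cods])
    paste(aa, collapse = "")
  }
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  out <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      pep <- translate_str(substring(oriented, frame + 1L))
      if (nchar(pep) == 0L) next
      # split into stop-bounded segments, keeping track of closure
      stops <- which(strsplit(pep, "")[[1L]] == "*")
      seg_lo <- c(1L, stops + 1L)
      seg_hi <- c(stops - 1L, nchar(pep))
      for (si in seq_along(seg_lo)) {
        lo <- seg_lo[si]; hi <- seg_hi[si]
        if (lo > hi) next
        closed5 <- si > 1L
        closed3 <- si <= length(stops)
        segment <- substring(pep, lo, hi)
        m_rel <- regexpr("M", segment, fixed = TRUE)
        # an M in the oracle's translated string marks an ATG codon only
        # when the underlying codon is literally ATG (X never is M)
        has_atg <- m_rel > 0L
        if (has_atg) {
          p_lo <- lo + m_rel - 1L
          class <- if (closed3) "complete" else "partial_3prime"
        } else if (!closed5) {
          p_lo <- lo
          class <- if (closed3) "partial_5prime" else "internal"
        } else next
        peptide <- substring(pep, p_lo, hi)
        if (nchar(peptide) < min_len_aa) next
        s_nt <- frame + 3L * (p_lo - 1L)
        e_nt <- frame + 3L * hi
        if (strand == "-") {
          L <- nchar(seq)
          tmp <- s_nt; s_nt <- L - e_nt; e_nt <- L - tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, frame = frame, nt_start = s_nt, nt_end = e_nt,
          peptide = peptide, completeness = class,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(strand = character(), frame = integer(),
                     nt_start = integer(), nt_end = integer(),
                     peptide = character(), completeness = character())
  }
  df[order(df$strand, df$frame, df$nt_start), , drop = FALSE]
}

# Naive O(n * w) windowed mean of Kyte-Doolittle scores.
kd_oracle <- function(peptide, window = 17L) {
  scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
             E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
             M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
             Y = -1.3, V = 4.2, X = 0)
  chars <- strsplit(peptide, "")[[1L]]
  n <- length(chars)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1L), function(i) {
    mean(scale[chars[i:(i + window - 1L)]])
  }, numeric(1))
}

# Convertase site oracle: regex scan for basic runs and spaced monobasic
# arginines.
cleavage_oracle <- function(precursor, sp_cleavage = 0L) {
  chars <- strsplit(precursor, "")[[1L]]
  n <- length(chars)
  basic <- chars %in% c("K", "R")
  runs <- stringr::str_locate_all(precursor, "[KR]{2,}")[[1L]]
  sites <- if (nrow(runs) > 0L) runs[, "end"] else integer(0)
  left <- c(FALSE, basic[-n])
  right <- c(basic[-1L], FALSE)
  lone <- which(basic & !left & !right)
  for (p in which(chars == "R")) {
    if (!(p %in% lone)) next
    partners <- intersect(p + c(-4L, -6L, -8L), lone)
    if (length(partners) == 0L) next
    if (p < n && chars[p + 1L] == "P") next
    sites <- c(sites, p)
  }
  sites <- sort(unique(sites))
  sites[sites > sp_cleavage]
}

# Best hit per component by an explicit split-apply loop.
bhpc_oracle <- function(hits, cutoff) {
  keep <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  comp <- sub("^(comp\\d+)_.*$", "\\1", keep$query_id)
  picked <- lapply(split(seq_len(nrow(keep)), comp), function(idx) {
    block <- keep[idx, , drop = FALSE]
    block <- block[order(-block$bitscore, block$evalue, block$subject_id), ,
                   drop = FALSE]
    block[1L, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out[order(out$query_id), , drop = FALSE]
}

# Sort an ORF table into oracle-comparable form.
orf_comparable <- function(orfs) {
  df <- as.data.frame(orfs[, c("strand", "frame", "nt_start", "nt_end",
                               "peptide", "completeness")])
  df <- df[order(df$strand, df$frame, df$nt_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
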