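# Transcripts-per-million quantification and EM allocation of ambiguously
# mapped reads. Quantification is done at the Trinity subcomponent ("gene")
# level; effective length is the sequence length (no fragment-length model,
# since only relative abundances are consumed downstream).

#' Compute transcripts per million from counts and lengths
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`. A table with all-zero
#' counts yields all-zero TPM; otherwise TPM sums to one million.
#'
#' @param expr Tibble with columns `subcomponent_id` (or any id column named
#'   `subcomponent_id`), `est_count` and `effective_length`.
#' @return The input with a `tpm` column appended.
#' @examples
#' compute_tpm(tibble::tibble(
#'   subcomponent_id = c("comp0_c0", "comp1_c0"),
#'   est_count = c(10, 10), effective_length = c(100, 200)))
#' @export
compute_tpm <- function(expr) {
  stopifnot(all(c("subcomponent_id", "est_count", "effective_length")
                %in% names(expr)))
  if (any(expr$effective_length <= 0)) {
    stop("effective_length must be positive for all records", call. = FALSE)
  }
  stopifnot(all(expr$est_count >= 0))
  rate <- expr$est_count / expr$effective_length
  total <- sum(rate)
  expr$tpm <- if (total > 0) 1e6 * rate / total else rep(0, nrow(expr))
  expr
}

#' Allocate ambiguous reads by expectation-maximization
#'
#' A lightweight EM allocator in the spirit of RSEM's model: reads
#' compatible with several subcomponents are fractionally assigned in the
#' E-step proportionally to `theta_i / l_i` over their compatible set, and
#' abundances are re-estimated in the M-step from the expected counts,
#' until the largest TPM change falls below `tol` or `max_iter` is reached.
#' Uniquely mapping reads reproduce [compute_tpm()] on the implied counts
#' exactly. The observed-data log-likelihood is non-decreasing across
#' iterations (a property the test suite asserts per step).
#'
#' @param reads Tibble in long form with columns `read_id` and
#'   `subcomponent_id`: one row per (read, compatible subcomponent) pair.
#' @param lengths Named numeric vector or tibble (`subcomponent_id`,
#'   `effective_length`) giving the effective length of every referenced id.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on the largest absolute TPM change
#'   (default 1e-3).
#' @return An object of class `em_fit`; use [tidy()] for the per-
#'   subcomponent expression table and [glance()] for fit diagnostics.
#' @export
em_allocate <- function(reads, lengths, max_iter = 1000L, tol = 1e-3) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$effective_length,
                               lengths$subcomponent_id)
  }
  ids <- names(lengths)
  missing <- setdiff(unique(reads$subcomponent_id), ids)
  if (length(missing) > 0L) {
    stop("read(s) reference unknown subcomponent id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(lengths > 0))
  n_ids <- length(ids)

  # collapse reads into equivalence classes of identical compatibility sets
  classes <- reads |>
    dplyr::distinct(.data$read_id, .data$subcomponent_id) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(key = paste(sort(.data$subcomponent_id),
                                 collapse = "\r"), .groups = "drop") |>
    dplyr::count(.data$key, name = "n_reads")
  class_members <- strsplit(classes$key, "\r", fixed = TRUE)
  class_idx <- lapply(class_members, match, table = ids)
  n_reads_total <- sum(classes$n_reads)

  theta <- rep(1 / n_ids, n_ids)
  inv_len <- 1 / unname(lengths)
  ll_trace <- numeric(0)
  tpm_of <- function(theta) {
    # theta is the read-generating proportion; abundance per copy ~ theta/l
    rate <- theta * inv_len
    1e6 * rate / sum(rate)
  }
  tpm_prev <- tpm_of(theta)
  converged <- FALSE
  iter <- 0L
  expected <- rep(0, n_ids)
  repeat {
    iter <- iter + 1L
    expected[] <- 0
    ll <- 0
    for (k in seq_along(class_idx)) {
      idx <- class_idx[[k]]
      w <- theta[idx] * inv_len[idx]
      s <- sum(w)
      ll <- ll + classes$n_reads[k] * log(s)
      expected[idx] <- expected[idx] + classes$n_reads[k] * w / s
    }
    ll_trace <- c(ll_trace, ll)
    theta <- expected / n_reads_total
    tpm_now <- tpm_of(theta)
    if (max(abs(tpm_now - tpm_prev)) < tol) { converged <- TRUE; break }
    tpm_prev <- tpm_now
    if (iter >= max_iter) break
  }
  expression <- tibble::tibble(
    subcomponent_id = ids,
    est_count = expected,
    effective_length = unname(lengths),
    tpm = tpm_of(theta),
    theta = theta
  )
  structure(
    list(expression = expression, log_likelihood = ll_trace,
         iterations = iter, converged = converged, tol = tol,
         n_reads = n_reads_total),
    class = "em_fit"
  )
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf(
    "EM read allocation: %d reads over %d subcomponents, %d iteration(s)%s\n",
    x$n_reads, nrow(x$expression), x$iterations,
    if (x$converged) " (converged)" else " (max_iter reached)"))
  print(x$expression, ...)
  invisible(x)
}

#' Tidy an EM allocation fit
#'
#' @param x An `em_fit` object from [em_allocate()].
#' @param ... Unused.
#' @return Per-subcomponent tibble: `subcomponent_id`, `est_count`,
#'   `effective_length`, `tpm`, `theta` (read-generating proportion).
#' @export
tidy.em_fit <- function(x, ...) x$expression

#' One-row summary of an EM allocation fit
#'
#' @param x An `em_fit` object.
#' @param ... Unused.
#' @return Tibble with `iterations`, `converged`, `log_likelihood`
#'   (final), `n_reads`.
#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    log_likelihood = x$log_likelihood[length(x$log_likelihood)],
    n_reads = x$n_reads
  )
}

#' Expression share of a subset of genes
#'
#' Sums and means of TPM over a subset versus the remainder of the table
#' (the remainder excludes the subset), as used to express how large a
#' fraction of total expression a predicted secretome accounts for.
#'
#' @param expr Expression tibble with `subcomponent_id` and `tpm`.
#' @param subset_ids Character vector of subcomponent ids (must be a subset
#'   of the table's ids).
#' @return One-row tibble: `sum_subset`, `sum_rest`, `percent_share`
#'   (of the whole table), `mean_subset`, `mean_rest`, `fold`
#'   (`mean_subset / mean_rest`; `NaN` for an empty subset).
#' @export
expression_share <- function(expr, subset_ids) {
  stopifnot(all(subset_ids %in% expr$subcomponent_id))
  in_set <- expr$subcomponent_id %in% subset_ids
  sum_subset <- sum(expr$tpm[in_set])
  sum_rest <- sum(expr$tpm[!in_set])
  tibble::tibble(
    sum_subset = sum_subset,
    sum_rest = sum_rest,
    percent_share = if (sum_subset + sum_rest > 0) {
      100 * sum_subset / (sum_subset + sum_rest)
    } else 0,
    mean_subset = if (any(in_set)) mean(expr$tpm[in_set]) else NaN,
    mean_rest = if (any(!in_set)) mean(expr$tpm[!in_set]) else NaN,
    fold = if (any(in_set) && any(!in_set)) {
      mean(expr$tpm[in_set]) / mean(expr$tpm[!in_set])
    } else NaN
  )
}

#' Rank genes by expression
#'
#' @param expr Expression tibble with `subcomponent_id` and `tpm`.
#' @param annotations Optional tibble keyed by `subcomponent_id` with
#'   annotation columns to join.
#' @param n Number of rows to keep (default 30).
#' @return Top-`n` rows in descending TPM; ties keep lexicographic id order.
#' @export
top_expressed <- function(expr, annotations = NULL, n = 30L) {
  out <- expr |>
    dplyr::arrange(dplyr::desc(.data$tpm), .data$subcomponent_id) |>
    utils::head(n)
  if (!is.null(annotations)) {
    out <- dplyr::left_join(out, annotations, by = "subcomponent_id")
  }
  out
}

#' Read or write an RSEM-like expression table
#'
#' Four tab-separated columns: id, length, expected count, TPM.
#'
#' @param path Path to a TSV file with header
#'   `subcomponent_id length expected_count TPM`.
#' @return Expression tibble with standardized names (`subcomponent_id`,
#'   `effective_length`, `est_count`, `tpm`).
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    stats::setNames(c("subcomponent_id", "effective_length", "est_count",
                      "tpm")) |>
    dplyr::mutate(subcomponent_id = as.character(.data$subcomponent_id))
}

#' @rdname read_expression_tsv
#' @param expr Expression tibble.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(
    tibble::tibble(subcomponent_id = expr$subcomponent_id,
                   length = expr$effective_length,
                   expected_count = expr$est_count,
                   TPM = expr$tpm),
    path, progress = FALSE)
  invisible(path)
}
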