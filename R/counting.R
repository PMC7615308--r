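#' Tally isoform calls per cell
#'
#' Collapses read-level isoform calls into per-cell counts of +KTS, -KTS and
#' ambiguous units. `NON_JUNCTION` calls are excluded from all counts. With
#' UMI deduplication on, reads sharing a `(cell, umi)` pair collapse to one
#' unit whose call is the majority call among its reads (ties, including
#' PLUS/MINUS ties, become `AMBIGUOUS`), which prevents PCR duplicates from
#' inflating the ratio denominator; reads without a UMI each count as their
#' own unit.
#'
#' @param calls data.frame from [classify_reads()] (read_id, cell, umi, call)
#' @param dedup_umi `NULL` (default: deduplicate iff any UMI is present),
#'   `TRUE` or `FALSE`
#' @param labels optional data.frame of per-cell labels (genotype, sex,
#'   stage, ...) with a `cell_id` column, merged onto the output; labelled
#'   cells with no junction reads appear with zero counts
#' @return data.frame with one row per cell: cell_id, n_plus, n_minus,
#'   n_ambiguous, plus any label columns
#' @export
count_cells <- function(calls, dedup_umi = NULL, labels = NULL) {
  stopifnot(all(c("cell", "call") %in% names(calls)))
  keep <- calls$call != "NON_JUNCTION"
  calls <- calls[keep, , drop = FALSE]
  if (is.null(dedup_umi))
    dedup_umi <- "umi" %in% names(calls) && any(!is.na(calls$umi))

  if (dedup_umi && nrow(calls) > 0L) {
    has_umi <- !is.na(calls$umi)
    key <- ifelse(has_umi,
                  paste(calls$cell, calls$umi, sep = "\r"),
                  paste(calls$cell, calls$read_id, "noumi", sep = "\r"))
    units <- vapply(split(calls$call, key), majority_call, character(1))
    cell_of <- vapply(split(calls$cell, key), `[[`, character(1), 1L)
    calls <- data.frame(cell = cell_of, call = units,
                        stringsAsFactors = FALSE)
  }

  cells <- unique(c(calls$cell,
                    if (!is.null(labels)) as.character(labels$cell_id)))
  counts <- data.frame(
    cell_id = cells,
    n_plus = as.integer(table(factor(calls$cell[calls$call == "PLUS_KTS"],
                                     levels = cells))),
    n_minus = as.integer(table(factor(calls$cell[calls$call == "MINUS_KTS"],
                                      levels = cells))),
    n_ambiguous = as.integer(table(
      factor(calls$cell[calls$call == "AMBIGUOUS"], levels = cells))),
    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot("cell_id" %in% names(labels))
    counts <- merge(counts, labels, by = "cell_id", all.x = TRUE,
                    sort = FALSE)
  }
  counts[order(counts$cell_id), , drop = FALSE]
}

#' @noRd
majority_call <- function(x) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) top else "AMBIGUOUS"
}

#' Per-cell -KTS fraction with a binomial confidence interval
#'
#' The -KTS fraction of a cell is `n_minus / (n_plus + n_minus)`; ambiguous
#' units are excluded from the denominator. The 95% interval is either the
#' Wilson score interval (default; good coverage at moderate counts) or the
#' exact Clopper-Pearson interval. Cells with no informative units get an
#' undefined estimate flagged by `defined = FALSE`.
#'
#' @param counts data.frame from [count_cells()]
#' @param ci_method `"wilson"` or `"clopper_pearson"`
#' @param conf confidence level
#' @return `counts` with added columns n_informative, minus_fraction,
#'   ci_low, ci_high, defined
#' @examples
#' counts <- data.frame(cell_id = "c1", n_plus = 2, n_minus = 8,
#'                      n_ambiguous = 0)
#' estimate_ratio(counts, ci_method = "clopper_pearson")
#' @export
estimate_ratio <- function(counts, ci_method = c("wilson",
                                                 "clopper_pearson"),
                           conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("n_plus", "n_minus") %in% names(counts)))
  n <- counts$n_plus + counts$n_minus
  k <- counts$n_minus
  counts$n_informative <- n
  counts$minus_fraction <- ifelse(n > 0, k / n, NA_real_)
  ci <- matrix(NA_real_, nrow(counts), 2L)
  pos <- which(n > 0)
  if (length(pos) > 0L) {
    ci[pos, ] <- switch(ci_method,
      wilson = wilson_ci(k[pos], n[pos], conf),
      clopper_pearson = clopper_pearson_ci(k[pos], n[pos], conf))
  }
  counts$ci_low <- ci[, 1L]
  counts$ci_high <- ci[, 2L]
  counts$defined <- n > 0
  counts
}

#' Aggregate per-cell isoform counts by label groups
#'
#' Summarises [count_cells()] output per combination of label columns:
#' number of cells, mean +KTS / -KTS units per cell, and the pooled -KTS
#' fraction `sum(n_minus) / sum(n_minus + n_plus)` (the n_informative-
#' weighted mean of per-cell fractions). Groups with no cells do not appear.
#'
#' @param counts data.frame from [count_cells()] carrying label columns
#' @param keys character vector of label column names to group by
#' @return data.frame with one row per key combination
#' @export
aggregate_groups <- function(counts, keys) {
  miss <- setdiff(keys, names(counts))
  if (length(miss) > 0L)
    stop("unknown grouping key(s): ", paste(miss, collapse = ", "))
  if (length(keys) == 0L) stop("'keys' must name at least one label column")
  grp <- interaction(counts[keys], drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(counts)), grp), function(i) {
    g <- counts[i, , drop = FALSE]
    inf <- sum(g$n_minus + g$n_plus)
    cbind(g[1L, keys, drop = FALSE],
          data.frame(n_cells = length(i),
                     mean_minus_units = mean(g$n_minus),
                     mean_plus_units = mean(g$n_plus),
                     pooled_minus_fraction =
                       if (inf > 0) sum(g$n_minus) / inf else NA_real_,
                     n_informative = inf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
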