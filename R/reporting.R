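#' Genomic inflation factor
#'
#' Median-based lambda: each p-value is mapped to a 1-df chi-squared quantile
#' `qchisq(1 - p, 1)` and the median is divided by the null median
#' `qchisq(0.5, 1)` (about 0.4549). Lambda near 1 indicates calibrated
#' p-values; lambda above 1, inflation. Zero p-values are mapped to the
#' add-one floor implied by `b` permutation replicates before the transform.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param b replicate count defining the floor `1/(1+b)` applied to any
#'   `p = 0` (default `1e6`).
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(pvalues, b = 1e6) {
  stopifnot(length(pvalues) >= 1L, all(pvalues >= 0), all(pvalues <= 1))
  if (any(pvalues == 0)) {
    message(sum(pvalues == 0), " zero p-value(s) mapped to the add-one floor")
    pvalues[pvalues == 0] <- 1 / (1 + b)
  }
  stats::median(stats::qchisq(1 - pvalues, df = 1)) / stats::qchisq(0.5, df = 1)
}

#' QQ-plot coordinates
#'
#' Sorted observed p-values against uniform expected quantiles
#' `(i - 0.5) / G`, both on the `-log10` scale.
#'
#' @param pvalues numeric vector in `(0, 1]`.
#' @return data.frame with columns `expected`, `observed` (both `-log10`),
#'   ascending in `expected`.
#' @export
qq_coordinates <- function(pvalues) {
  stopifnot(length(pvalues) >= 1L)
  G <- length(pvalues)
  d <- data.frame(expected = -log10((G:1 - 0.5) / G),
                  observed = -log10(sort(pvalues, decreasing = TRUE)))
  rownames(d) <- NULL
  d
}

#' QQ plot of association p-values
#'
#' Base-graphics QQ plot with the identity line; points above the diagonal
#' indicate smaller-than-expected p-values.
#'
#' @param pvalues numeric vector in `(0, 1]`.
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return the coordinates, invisibly.
#' @export
plot_qq <- function(pvalues, main = "QQ plot", ...) {
  d <- qq_coordinates(pvalues)
  plot(d$expected, d$observed, xlab = expression(-log[10] ~ P[expected]),
       ylab = expression(-log[10] ~ P[observed]), main = main, pch = 20, ...)
  abline(0, 1, col = "grey50")
  invisible(d)
}

#' Attach min-tie ranks to a results table
#'
#' Rank 1 is the smallest p-value; tied p-values (common under permutation
#' discreteness) share the minimum rank, so several genes can all be rank 1.
#'
#' @param results data.frame with columns `gene` and `p_value`.
#' @return the table with a `rank` column added.
#' @export
method_ranks <- function(results) {
  stopifnot(all(c("gene", "p_value") %in% names(results)))
  results$rank <- rank(results$p_value, ties.method = "min")
  results
}

#' Top genes at a p-value cutoff
#'
#' @param results data.frame with `gene` and `p_value` columns.
#' @param cutoff inclusive p-value cutoff (e.g. the 1.55e-4 used for
#'   flagging stand-out genes on a QQ plot).
#' @return character vector of gene symbols with `p <= cutoff`, ordered by
#'   p-value then symbol.
#' @export
top_genes <- function(results, cutoff = 1.55e-4) {
  stopifnot(cutoff > 0, cutoff <= 1)
  hit <- results[results$p_value <= cutoff, , drop = FALSE]
  hit <- hit[order(hit$p_value, hit$gene), , drop = FALSE]
  hit$gene
}

#' Cross-method comparison table
#'
#' One row per gene in the union of each method's top set (at `cutoff`),
#' with that gene's p-value and min-tie rank under every method — so a gene
#' top-ranked by one method shows its (possibly unremarkable) p and rank
#' under the others.
#'
#' @param results_by_method named list of per-method results data.frames
#'   (columns `gene`, `p_value`) over a shared gene universe.
#' @param cutoff top-set p-value cutoff.
#' @return data.frame with `gene` plus `<method>_p` and `<method>_rank`
#'   columns, ordered by the minimum p-value across methods.
#' @export
cross_method_table <- function(results_by_method, cutoff = 1.55e-4) {
  if (length(results_by_method) == 0L) return(data.frame(gene = character(0)))
  tops <- unique(unlist(lapply(results_by_method, top_genes, cutoff = cutoff)))
  out <- data.frame(gene = tops, stringsAsFactors = FALSE)
  for (mth in names(results_by_method)) {
    r <- method_ranks(results_by_method[[mth]])
    i <- match(tops, r$gene)
    out[[paste0(mth, "_p")]] <- r$p_value[i]
    out[[paste0(mth, "_rank")]] <- r$rank[i]
  }
  if (nrow(out) > 0L) {
    pcols <- grep("_p$", names(out), value = TRUE)
    minp <- do.call(pmin, c(out[pcols], list(na.rm = TRUE)))
    out <- out[order(minp, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
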