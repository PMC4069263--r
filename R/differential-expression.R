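# Time-paired differential expression and pooled FDR.

#' Benjamini-Hochberg q-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`. Used for
#' the pooled correction over all genes and all three cohort comparisons, and
#' by the enrichment module.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length; monotone in `p` and capped at 1.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided paired t-test on time-matched cohort series
#'
#' Cohort values are paired by their time of collection: per matched time
#' point the difference `A - B` is formed (replicates are averaged within
#' cohort and time before pairing) and a one-sample t-test is applied to the
#' differences.
#'
#' Degenerate cases follow a fixed convention: zero-variance differences with
#' zero mean give `p = 1`; zero-variance differences with nonzero mean give
#' the limiting `p = 0` with `zero_variance = TRUE` flagged.
#'
#' @param a,b numeric vectors of per-time values, named by time point (or
#'   aligned in the same time order).
#' @return list with `t`, `p`, `mean_diff`, `df`, `zero_variance`.
#' @export
paired_t <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("cohorts must share an identical set of time points", call. = FALSE)
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("cohorts must share an identical set of time points", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  if (n < 2) stop("need >= 2 matched time points", call. = FALSE)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, df = n - 1, zero_variance = TRUE))
    }
    return(list(t = sign(md) * Inf, p = 0, mean_diff = md, df = n - 1,
                zero_variance = TRUE))
  }
  tt <- md / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), mean_diff = md,
       df = n - 1, zero_variance = FALSE)
}

# genes x timepoints matrix of within-(cohort, time) replicate means
cohort_time_means <- function(x, cohort) {
  meta <- x$metadata
  keep <- meta$cohort == cohort
  if (!any(keep)) stop("cohort ", cohort, " absent from the matrix", call. = FALSE)
  sub <- x$values[, keep, drop = FALSE]
  tim <- meta$time_h[keep]
  tp <- sort(unique(tim))
  out <- vapply(tp, function(t0) {
    rowMeans(sub[, tim == t0, drop = FALSE])
  }, numeric(nrow(sub)))
  out <- matrix(out, nrow = nrow(sub),
                dimnames = list(rownames(sub), as.character(tp)))
  out
}

# vectorized paired t over the rows of a genes x timepoints difference matrix
row_paired_t <- function(d) {
  n <- ncol(d)
  md <- rowMeans(d)
  s <- sqrt(rowSums((d - md)^2) / (n - 1))
  tt <- md / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  zv <- s == 0
  tt[zv] <- ifelse(md[zv] == 0, 0, sign(md[zv]) * Inf)
  p[zv] <- ifelse(md[zv] == 0, 1, 0)
  data.frame(mean_diff_log2 = md, t = tt, p = p, zero_variance = zv)
}

#' Run the three cohort comparisons with pooled BH correction
#'
#' For every gene, time-paired two-sided t-tests of RF vs CF, SF vs CF and
#' SF vs RF across all sampled time points; one Benjamini-Hochberg
#' correction is then applied to the pooled vector of all p-values from all
#' genes and all three comparisons jointly.
#'
#' @param x an [expression_matrix()] containing all three cohorts on a
#'   common time grid.
#' @return a `comparison_table`: data.frame with columns `gene_id`,
#'   `comparison` (one of "RF_vs_CF", "SF_vs_CF", "SF_vs_RF"),
#'   `mean_diff_log2`, `fold_change` (`2^diff`), `t`, `p`, `q`,
#'   `zero_variance`.
#' @export
run_comparisons <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  missing_cohort <- setdiff(c("CF", "RF", "SF"), unique(x$metadata$cohort))
  if (length(missing_cohort)) {
    stop("missing cohort: ", paste(missing_cohort, collapse = ", "), call. = FALSE)
  }
  cf <- cohort_time_means(x, "CF")
  rf <- cohort_time_means(x, "RF")
  sf <- cohort_time_means(x, "SF")
  if (!identical(colnames(cf), colnames(rf)) ||
      !identical(colnames(cf), colnames(sf))) {
    stop("cohorts must share an identical time grid", call. = FALSE)
  }
  pieces <- list(RF_vs_CF = rf - cf, SF_vs_CF = sf - cf, SF_vs_RF = sf - rf)
  out <- do.call(rbind, lapply(names(pieces), function(nm) {
    res <- row_paired_t(pieces[[nm]])
    data.frame(gene_id = rownames(x$values), comparison = nm, res,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$fold_change <- 2^out$mean_diff_log2
  out$q <- bh_fdr(out$p)
  out <- out[, c("gene_id", "comparison", "mean_diff_log2", "fold_change",
                 "t", "p", "q", "zero_variance")]
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table to TSV
#' @param ct a `comparison_table` from [run_comparisons()].
#' @param path output path.
#' @export
write_comparisons <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ct)
}
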