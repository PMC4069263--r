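# Temporal-response categories from the three-comparison significance
# pattern, switch-time estimation and fast-switcher curation.

#' Rules for the indeterminate categories VI-VIII
#'
#' Categories I-V follow directly from the significance pattern of the three
#' cohort comparisons. Genes that are diet-dependent but significant in
#' neither SF comparison (and leftover diet-independent patterns) are
#' resolved into VI (non-responding), VII (slow/partial switch) or VIII
#' (high-variability residual) using the position of the SF late-time mean
#' along the CF-to-RF gap and the gene's within-condition variability. These
#' rules stand in for criteria published only as supplementary material and
#' are deliberately configurable.
#'
#' @param vi_max_progress SF late-time progress at or below which a
#'   diet-dependent indeterminate gene is called VI (stayed at CF level).
#' @param vii_max_progress progress at or below which (and above
#'   `vi_max_progress`) it is called VII (partial/slow switch); progress
#'   beyond this goes to VIII.
#' @param viii_sd_mult a gene whose within-condition SD exceeds this
#'   multiple of the median within-condition SD is sent to VIII regardless
#'   of progress.
#' @param late_times sampled hours averaged for the "late-time mean"
#'   (default: the last three of the standard grid).
#' @return list of class `category_rules`.
#' @export
category_rules <- function(vi_max_progress = 0.25,
                           vii_max_progress = 0.75,
                           viii_sd_mult = 3,
                           late_times = c(48, 56, 72)) {
  stopifnot(vi_max_progress > 0, vii_max_progress > vi_max_progress,
            viii_sd_mult > 0)
  structure(list(vi_max_progress = vi_max_progress,
                 vii_max_progress = vii_max_progress,
                 viii_sd_mult = viii_sd_mult,
                 late_times = late_times),
            class = "category_rules")
}

#' Per-gene level statistics needed by the indeterminate rules
#'
#' @param x an [expression_matrix()].
#' @param rules a [category_rules()] (for `late_times`).
#' @return data.frame `gene_id`, `cf_mean`, `rf_mean`, `sf_late_mean`,
#'   `within_sd` (pooled within cohort x time SD).
#' @export
gene_level_stats <- function(x, rules = category_rules()) {
  stopifnot(inherits(x, "expression_matrix"))
  meta <- x$metadata
  grp <- interaction(meta$cohort, meta$time_h, drop = TRUE)
  centered <- x$values
  for (g in levels(grp)) {
    cols <- grp == g
    centered[, cols] <- x$values[, cols, drop = FALSE] -
      rowMeans(x$values[, cols, drop = FALSE])
  }
  ngrp <- nlevels(grp)
  within_sd <- sqrt(rowSums(centered^2) / max(ncol(centered) - ngrp, 1))
  sf_late <- meta$cohort == "SF" & meta$time_h %in% rules$late_times
  if (!any(sf_late)) {
    # fall back to the latest available SF hour
    sf_late <- meta$cohort == "SF" & meta$time_h == max(meta$time_h[meta$cohort == "SF"])
  }
  data.frame(
    gene_id = rownames(x$values),
    cf_mean = rowMeans(x$values[, meta$cohort == "CF", drop = FALSE]),
    rf_mean = rowMeans(x$values[, meta$cohort == "RF", drop = FALSE]),
    sf_late_mean = rowMeans(x$values[, sf_late, drop = FALSE]),
    within_sd = within_sd,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign temporal-response categories
#'
#' With `S(c)` meaning "comparison c significant at the FDR threshold" and
#' `D = S(RF_vs_CF)` (diet-dependent), the main categories are:
#' \describe{
#'   \item{I (switching)}{`D` and `S(SF_vs_CF)` and not `S(SF_vs_RF)` -- the
#'     switched cohort left the CF level and matches the RF level.}
#'   \item{II (refractory)}{`D`, not `S(SF_vs_CF)`, `S(SF_vs_RF)` -- SF kept
#'     the CF level.}
#'   \item{III (responsive, non-switching)}{`D`, `S(SF_vs_CF)`,
#'     `S(SF_vs_RF)` -- SF left CF but did not reach RF.}
#'   \item{IV (deviating)}{not `D`, `S(SF_vs_CF)` -- diet-independent gene
#'     that departs from both constant-food levels.}
#'   \item{V (null)}{no comparison significant.}
#' }
#' Diet-dependent genes significant in neither SF comparison, and the
#' leftover diet-independent pattern (`SF_vs_RF` only), go to VI/VII/VIII
#' per [category_rules()]; without `stats` they default to VI and VIII
#' respectively.
#'
#' Direction is the sign of the RF-minus-CF mean difference for I-III and of
#' the SF-minus-CF difference for IV ("up" = higher in the
#' restricted/switched state); categories V-VIII have direction "none".
#'
#' @param comparisons a `comparison_table` from [run_comparisons()].
#' @param fdr FDR threshold on the pooled q-values.
#' @param rules a [category_rules()].
#' @param stats optional [gene_level_stats()] output; enables the
#'   progress-based VI/VII/VIII resolution.
#' @return a `category_assignment`: data.frame `gene_id`, `category`
#'   (factor with levels I-VIII), `direction` ("up"/"down"/"none"),
#'   plus the significance pattern columns `sig_rf_cf`, `sig_sf_cf`,
#'   `sig_sf_rf`.
#' @export
assign_categories <- function(comparisons, fdr = 0.05,
                              rules = category_rules(), stats = NULL) {
  stopifnot(fdr > 0, fdr < 1)
  need <- c("RF_vs_CF", "SF_vs_CF", "SF_vs_RF")
  wide <- lapply(need, function(cm) {
    sub <- comparisons[comparisons$comparison == cm, ]
    sub[match(unique(comparisons$gene_id), sub$gene_id), ]
  })
  genes <- unique(comparisons$gene_id)
  for (i in seq_along(need)) {
    missing <- genes[is.na(wide[[i]]$gene_id)]
    if (length(missing)) {
      stop("missing ", need[i], " comparison for gene(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  d  <- wide[[1]]$q < fdr   # diet-dependent
  s2 <- wide[[2]]$q < fdr   # SF vs CF
  s3 <- wide[[3]]$q < fdr   # SF vs RF

  cat_ <- character(length(genes))
  cat_[d & s2 & !s3]  <- "I"
  cat_[d & !s2 & s3]  <- "II"
  cat_[d & s2 & s3]   <- "III"
  cat_[!d & s2]       <- "IV"
  cat_[!d & !s2 & !s3] <- "V"
  indeterminate_dep   <- d & !s2 & !s3       # diet-dependent, SF pattern silent
  indeterminate_indep <- !d & !s2 & s3       # SF differs from RF only

  if (is.null(stats)) {
    cat_[indeterminate_dep] <- "VI"
    cat_[indeterminate_indep] <- "VIII"
  } else {
    st <- stats[match(genes, stats$gene_id), ]
    gap <- st$rf_mean - st$cf_mean
    progress <- ifelse(abs(gap) > 0, (st$sf_late_mean - st$cf_mean) / gap, 0)
    high_var <- st$within_sd > rules$viii_sd_mult * stats::median(st$within_sd)
    idx <- which(indeterminate_dep)
    cat_[idx] <- ifelse(high_var[idx], "VIII",
                   ifelse(progress[idx] <= rules$vi_max_progress, "VI",
                     ifelse(progress[idx] <= rules$vii_max_progress, "VII",
                            "VIII")))
    cat_[indeterminate_indep] <- "VIII"
  }

  dir_ <- rep("none", length(genes))
  main13 <- cat_ %in% c("I", "II", "III")
  dir_[main13] <- ifelse(wide[[1]]$mean_diff_log2[main13] > 0, "up", "down")
  is4 <- cat_ == "IV"
  dir_[is4] <- ifelse(wide[[2]]$mean_diff_log2[is4] > 0, "up", "down")

  out <- data.frame(gene_id = genes,
                    category = factor(cat_, levels = c("I", "II", "III", "IV",
                                                       "V", "VI", "VII", "VIII")),
                    direction = dir_,
                    sig_rf_cf = d, sig_sf_cf = s2, sig_sf_rf = s3,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' Per-category up/down counts
#'
#' @param assignments a [assign_categories()] result.
#' @return data.frame `category`, `n`, `n_up`, `n_down`.
#' @export
category_counts <- function(assignments) {
  sp <- split(assignments$direction, assignments$category)
  data.frame(category = names(sp),
             n = vapply(sp, length, integer(1)),
             n_up = vapply(sp, function(x) sum(x == "up"), integer(1)),
             n_down = vapply(sp, function(x) sum(x == "down"), integer(1)),
             row.names = NULL)
}

#' Estimate the switch-completion time of one gene
#'
#' Earliest sampled hour at which the SF time course has crossed
#' `completion_fraction` of the CF-to-RF gap and stays within
#' `1 - completion_fraction` of the RF level at every later sampled hour.
#'
#' @param sf_series numeric vector of SF per-time means, named by hour.
#' @param cf_level,rf_level scalar CF and RF reference levels.
#' @param completion_fraction fraction of the gap that must be crossed.
#' @param gap_tol gaps smaller than this (absolute log2) are degenerate:
#'   returns `NA` with a warning.
#' @return the completion hour, or `NA` if the gene never completes.
#' @export
estimate_switch_time <- function(sf_series, cf_level, rf_level,
                                 completion_fraction = 0.9, gap_tol = 1e-8) {
  gap <- rf_level - cf_level
  if (abs(gap) < gap_tol) {
    warning("degenerate CF-to-RF gap; switch time undefined")
    return(NA_real_)
  }
  hours <- as.numeric(names(sf_series))
  if (any(is.na(hours))) stop("sf_series must be named by hour", call. = FALSE)
  o <- order(hours)
  hours <- hours[o]
  within <- abs(sf_series[o] - rf_level) <= (1 - completion_fraction) * abs(gap)
  # earliest hour from which `within` holds at every later sampled hour
  ok_from <- rev(cumprod(rev(within))) == 1
  if (!any(ok_from)) return(NA_real_)
  hours[which(ok_from)[1]]
}

#' Switch-completion times for all genes in a matrix
#'
#' Convenience wrapper: SF per-time means per gene against the gene's CF and
#' RF overall means.
#'
#' @param x an [expression_matrix()].
#' @param completion_fraction,gap_tol passed to [estimate_switch_time()].
#' @return data.frame `gene_id`, `switch_time_h` (NA when never/degenerate).
#' @export
switch_times <- function(x, completion_fraction = 0.9, gap_tol = 1e-8) {
  sf <- cohort_time_means(x, "SF")
  meta <- x$metadata
  cf_mean <- rowMeans(x$values[, meta$cohort == "CF", drop = FALSE])
  rf_mean <- rowMeans(x$values[, meta$cohort == "RF", drop = FALSE])
  st <- vapply(seq_len(nrow(sf)), function(i) {
    if (abs(rf_mean[i] - cf_mean[i]) < gap_tol) return(NA_real_)
    estimate_switch_time(sf[i, ], cf_mean[i], rf_mean[i],
                         completion_fraction, gap_tol)
  }, numeric(1))
  data.frame(gene_id = rownames(sf), switch_time_h = st,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Curate fast-switching genes
#'
#' Category I genes whose switch completed within `cutoff_h` hours, split by
#' direction of the diet effect.
#'
#' @param assignments a [assign_categories()] result.
#' @param switch_times a [switch_times()] data.frame.
#' @param cutoff_h completion-time cutoff in hours.
#' @return list with character vectors `up` and `down`.
#' @export
curate_fast_switchers <- function(assignments, switch_times, cutoff_h = 8) {
  st <- switch_times$switch_time_h[match(assignments$gene_id,
                                         switch_times$gene_id)]
  fast <- assignments$category == "I" & !is.na(st) & st <= cutoff_h
  list(up = assignments$gene_id[fast & assignments$direction == "up"],
       down = assignments$gene_id[fast & assignments$direction == "down"])
}
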