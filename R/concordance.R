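# Cross-study comparison of directed differentially-expressed gene lists.

#' Construct a directed gene list
#'
#' @param gene_id character vector.
#' @param direction "up" or "down" per gene (regulation in that study).
#' @param study study label.
#' @return data.frame of class `directed_gene_list`.
#' @export
directed_gene_list <- function(gene_id, direction, study = "study") {
  if (length(gene_id) != length(direction)) {
    stop("gene_id and direction must have equal length", call. = FALSE)
  }
  if (!all(direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  tab <- unique(data.frame(gene_id = gene_id, direction = direction,
                           stringsAsFactors = FALSE))
  conflicted <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(conflicted)) {
    stop("gene(s) listed with both directions: ",
         paste(utils::head(conflicted, 5), collapse = ", "), call. = FALSE)
  }
  attr(tab, "study") <- study
  class(tab) <- c("directed_gene_list", "data.frame")
  tab
}

#' Read a directed gene list from TSV
#' @param path TSV with columns `gene_id`, `direction`.
#' @param study study label.
#' @return a [directed_gene_list()].
#' @export
read_directed_list <- function(path, study = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  directed_gene_list(tab$gene_id, tab$direction, study)
}

#' Overlap significance between two gene lists
#'
#' Upper-tail hypergeometric test of the observed intersection size given
#' the two list sizes and the universe size.
#'
#' @param list_a,list_b character vectors of gene ids (or
#'   [directed_gene_list()]s).
#' @param universe_size number of genes both studies could have detected;
#'   must be at least `|A union B|`.
#' @return list with `n_shared` and `p`.
#' @export
overlap_test <- function(list_a, list_b, universe_size) {
  a <- unique(if (is.data.frame(list_a)) list_a$gene_id else list_a)
  b <- unique(if (is.data.frame(list_b)) list_b$gene_id else list_b)
  if (universe_size < length(union(a, b))) {
    stop("universe_size (", universe_size, ") smaller than |A union B| (",
         length(union(a, b)), ")", call. = FALSE)
  }
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  list(n_shared = k, p = p)
}

#' Direction concordance between two directed gene lists
#'
#' Shared genes are partitioned into same-direction and opposite-direction;
#' percentages are rounded to the nearest integer. Genes present in only
#' one list are counted but excluded from the concordance partition.
#'
#' @param list_a,list_b [directed_gene_list()]s.
#' @return a `concordance_summary`: list with `n_shared`,
#'   `n_same_direction`, `n_opposite`, `pct_same`, `pct_opposite`,
#'   `only_a`, `only_b`, `table` (2x2 counts, A direction x B direction)
#'   and `shared` (data.frame `gene_id`, `direction_a`, `direction_b`,
#'   `pattern`).
#' @export
direction_concordance <- function(list_a, list_b) {
  shared_ids <- intersect(list_a$gene_id, list_b$gene_id)
  da <- list_a$direction[match(shared_ids, list_a$gene_id)]
  db <- list_b$direction[match(shared_ids, list_b$gene_id)]
  same <- da == db
  tab <- table(factor(da, levels = c("up", "down")),
               factor(db, levels = c("up", "down")),
               dnn = c("A", "B"))
  n <- length(shared_ids)
  shared <- data.frame(
    gene_id = shared_ids, direction_a = da, direction_b = db,
    pattern = ifelse(same, paste0("same_", da),
                     paste0("A_", da, "_B_", db)),
    stringsAsFactors = FALSE)
  out <- list(n_shared = n,
              n_same_direction = sum(same),
              n_opposite = sum(!same),
              pct_same = if (n) round(100 * sum(same) / n) else NA_real_,
              pct_opposite = if (n) round(100 * sum(!same) / n) else NA_real_,
              only_a = setdiff(list_a$gene_id, shared_ids),
              only_b = setdiff(list_b$gene_id, shared_ids),
              table = tab, shared = shared)
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("shared genes: %d (%d same direction [%s%%], %d opposite [%s%%])\n",
              x$n_shared, x$n_same_direction, x$pct_same,
              x$n_opposite, x$pct_opposite))
  print(x$table)
  invisible(x)
}

#' Up/down ratio of a directed gene list
#'
#' @param x a [directed_gene_list()].
#' @return `100 * n_up / n_down` rounded to the nearest integer.
#' @export
updown_ratio <- function(x) {
  n_up <- sum(x$direction == "up")
  n_down <- sum(x$direction == "down")
  if (n_down == 0) stop("no down-regulated genes: ratio undefined", call. = FALSE)
  round(100 * n_up / n_down)
}

#' Cross-tabulate shared genes by direction pattern and category
#'
#' @param summary a [direction_concordance()] result.
#' @param assignments a [assign_categories()] result covering every shared
#'   gene.
#' @return data.frame `pattern`, `category`, `n`, `row_pct` (percentage of
#'   the pattern's genes in that category, rounded).
#' @export
concordance_by_category <- function(summary, assignments) {
  sh <- summary$shared
  if (!nrow(sh)) {
    return(data.frame(pattern = character(0), category = character(0),
                      n = integer(0), row_pct = numeric(0)))
  }
  idx <- match(sh$gene_id, assignments$gene_id)
  if (anyNA(idx)) {
    stop("shared gene(s) without category assignment: ",
         paste(utils::head(sh$gene_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  cat_ <- as.character(assignments$category[idx])
  tab <- as.data.frame(table(pattern = sh$pattern, category = cat_),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  totals <- tapply(tab$n, tab$pattern, sum)
  tab$row_pct <- round(100 * tab$n / as.numeric(totals[tab$pattern]))
  rownames(tab) <- NULL
  tab
}
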