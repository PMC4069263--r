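# Gene-set collections (GMT) and hypergeometric over-representation.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are deduplicated.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection`: named list of character vectors, with
#'   per-set descriptions in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    out <- list()
    class(out) <- "gene_set_collection"
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " in ", path,
         " (need name, description and >= 1 member)", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), names(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Restrict a gene-set collection to a universe
#'
#' Drops members outside the universe and removes (with a warning) sets
#' left empty.
#'
#' @param collection a `gene_set_collection` or plain named list.
#' @param universe character vector of testable gene ids.
#' @return the restricted collection.
#' @export
restrict_collection <- function(collection, universe) {
  sets <- lapply(collection, intersect, universe)
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) empty after universe restriction: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    sets <- sets[!empty]
  }
  class(sets) <- "gene_set_collection"
  sets
}

#' Hypergeometric over-representation of a query list
#'
#' Upper-tail hypergeometric test per set: with universe size `N`, set size
#' `K`, query size `n` and overlap `k`, `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. BH correction is applied across all sets
#' tested; results are sorted by q.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param collection gene sets (restricted to the universe internally).
#' @param universe character vector of all testable gene ids.
#' @return data.frame `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, sorted by `q` then `p`.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  sets <- suppressWarnings(restrict_collection(collection, universe))
  N <- length(unique(universe))
  n <- length(query)
  res <- data.frame(
    set = names(sets),
    overlap = vapply(sets, function(s) length(intersect(s, query)), integer(1)),
    set_size = vapply(sets, length, integer(1)),
    query_size = n, universe_size = N,
    stringsAsFactors = FALSE, row.names = NULL)
  res$p <- stats::phyper(res$overlap - 1, res$set_size, N - res$set_size, n,
                         lower.tail = FALSE)
  res$q <- if (nrow(res)) bh_fdr(res$p) else numeric(0)
  res[order(res$q, res$p), , drop = FALSE]
}

#' Direction-aware enrichment for category gene lists
#'
#' For each requested category, tests the up- and down-regulated gene lists
#' separately against the collection (mirroring per-table corrections: BH is
#' applied within each category x direction family). An empty query yields
#' an empty table with a warning ("no enrichment found").
#'
#' @param assignments a [assign_categories()] result.
#' @param collection gene sets.
#' @param universe character vector of testable gene ids (default: all
#'   assigned genes, i.e. everything measured).
#' @param categories categories to test.
#' @return data.frame with `category` and `direction` columns prepended to
#'   the [hypergeom_enrich()] output.
#' @export
enrich_by_direction <- function(assignments, collection,
                                universe = assignments$gene_id,
                                categories = "I") {
  out <- list()
  for (cat_ in categories) {
    for (dir_ in c("up", "down")) {
      query <- assignments$gene_id[assignments$category == cat_ &
                                     assignments$direction == dir_]
      query <- intersect(query, universe)
      if (!length(query)) {
        warning("no ", dir_, "-regulated genes in category ", cat_,
                ": no enrichment found")
        next
      }
      res <- hypergeom_enrich(query, collection, universe)
      if (nrow(res)) {
        out[[length(out) + 1L]] <- cbind(category = cat_, direction = dir_,
                                         res, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(category = character(0), direction = character(0),
                      set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
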