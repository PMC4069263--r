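# The worked examples replicate the arithmetic of the chronic-DR vs
# starvation comparison: 45 shared genes, 10 concordant, 35 discordant,
# and a starvation list of 65 up / 48 down.

dr_vs_starvation_lists <- function() {
  shared <- paste0("s", 1:45)
  # 4 up in both, 6 down in both, 8 down-DR/up-starvation,
  # 27 up-DR/down-starvation
  dir_a <- c(rep("up", 4), rep("down", 6), rep("down", 8), rep("up", 27))
  dir_b <- c(rep("up", 4), rep("down", 6), rep("up", 8), rep("down", 27))
  a_only <- paste0("a", 1:20)
  b_only <- paste0("b", 1:68)
  list(
    dr = directed_gene_list(c(shared, a_only),
                            c(dir_a, rep("up", 20)), study = "chronic_dr"),
    starv = directed_gene_list(c(shared, b_only),
                               c(dir_b, rep("up", 53), rep("down", 15)),
                               study = "starvation"))
}

test_that("directed lists reject conflicting directions", {
  expect_error(directed_gene_list(c("g1", "g1"), c("up", "down")), "both")
  expect_error(directed_gene_list("g1", "sideways"), "direction")
  # an exact duplicate row is deduplicated, not an error
  ok <- directed_gene_list(c("g1", "g1"), c("up", "up"))
  expect_equal(nrow(ok), 1)
})

test_that("concordance partition reproduces the 22% / 78% split", {
  ls <- dr_vs_starvation_lists()
  cc <- direction_concordance(ls$dr, ls$starv)
  expect_equal(cc$n_shared, 45)
  expect_equal(cc$n_same_direction, 10)
  expect_equal(cc$n_opposite, 35)
  expect_equal(cc$pct_same, 22)
  expect_equal(cc$pct_opposite, 78)
  expect_equal(cc$n_same_direction + cc$n_opposite, cc$n_shared)
  # 2x2 marginals match per-study direction counts on the shared genes
  expect_equal(unname(rowSums(cc$table)), c(4 + 27, 6 + 8))   # DR up / down
  expect_equal(unname(colSums(cc$table)), c(4 + 8, 6 + 27))   # starv up / down
})

test_that("concordance is symmetric in its two arguments", {
  ls <- dr_vs_starvation_lists()
  ab <- direction_concordance(ls$dr, ls$starv)
  ba <- direction_concordance(ls$starv, ls$dr)
  expect_equal(ab$n_same_direction, ba$n_same_direction)
  expect_equal(ab$n_opposite, ba$n_opposite)
  expect_equal(ab$table, t(ba$table), ignore_attr = TRUE)
})

test_that("all-concordant and disjoint edge cases", {
  a <- directed_gene_list(c("g1", "g2"), c("up", "down"))
  expect_equal(direction_concordance(a, a)$pct_same, 100)
  b <- directed_gene_list(c("h1", "h2"), c("up", "down"))
  cc <- direction_concordance(a, b)
  expect_equal(cc$n_shared, 0)
  expect_true(is.na(cc$pct_same))
})

test_that("up/down ratio: 65 up and 48 down give 135%", {
  ls <- dr_vs_starvation_lists()
  expect_equal(sum(ls$starv$direction == "up"), 65)
  expect_equal(sum(ls$starv$direction == "down"), 48)
  expect_equal(updown_ratio(ls$starv), 135)
  expect_equal(updown_ratio(directed_gene_list(c("g1", "g2"), c("up", "down"))), 100)
  expect_equal(updown_ratio(directed_gene_list(paste0("g", 1:5),
                                               c(rep("up", 3), rep("down", 2)))),
               150)
  expect_error(updown_ratio(directed_gene_list("g1", "up")), "undefined")
})

test_that("overlap test: combinatorial worked example and monotonicity in the universe", {
  a <- paste0("g", 1:5)
  got <- overlap_test(a, a, universe_size = 20)
  expect_equal(got$n_shared, 5)
  expect_equal(got$p, 1 / choose(20, 5), tolerance = 1e-12)
  # brute-force enumeration at small universes
  set.seed(3)
  universe <- paste0("g", 1:18)
  x <- sample(universe, 7); y <- sample(universe, 6)
  k <- length(intersect(x, y))
  expect_equal(overlap_test(x, y, 18)$p, hyper_brute(k, 7, 6, 18),
               tolerance = 1e-12)
  # disjoint lists: the whole tail, p = 1
  expect_equal(overlap_test(paste0("g", 1:3), paste0("g", 4:6), 50)$p, 1)
  # a larger universe makes a nonzero overlap strictly more surprising
  p1 <- overlap_test(x, y, 18)$p
  p2 <- overlap_test(x, y, 36)$p
  expect_lt(p2, p1)
  expect_error(overlap_test(paste0("g", 1:9), paste0("g", 5:12), 10),
               "universe_size")
})

test_that("category cross-tab reproduces the 52% switching-gene share", {
  ls <- dr_vs_starvation_lists()
  cc <- direction_concordance(ls$dr, ls$starv)
  # 14 of the 27 up-in-DR / down-in-starvation genes are switching genes
  opp <- cc$shared$gene_id[cc$shared$pattern == "A_up_B_down"]
  expect_length(opp, 27)
  cats <- rep("V", 45)
  names(cats) <- cc$shared$gene_id
  cats[opp[1:14]] <- "I"
  assigns <- data.frame(gene_id = names(cats),
                        category = factor(cats, levels = c("I", "II", "III", "IV",
                                                           "V", "VI", "VII", "VIII")),
                        direction = "none", stringsAsFactors = FALSE)
  tab <- concordance_by_category(cc, assigns)
  row <- tab[tab$pattern == "A_up_B_down" & tab$category == "I", ]
  expect_equal(row$n, 14)
  expect_equal(row$row_pct, 52)
  # rows for a pattern sum to the number of genes with that pattern
  expect_equal(sum(tab$n[tab$pattern == "A_up_B_down"]), 27)
  # unassigned shared gene errors by name
  expect_error(concordance_by_category(cc, assigns[-1, ]),
               assigns$gene_id[1])
})

test_that("cross-tab edge cases: empty shared set and a single category", {
  a <- directed_gene_list(c("g1", "g2"), c("up", "down"))
  b <- directed_gene_list(c("h1"), "up")
  empty <- concordance_by_category(direction_concordance(a, b),
                                   data.frame(gene_id = character(0),
                                              category = factor(character(0)),
                                              direction = character(0)))
  expect_equal(nrow(empty), 0)
  cc <- direction_concordance(a, a)
  assigns <- data.frame(gene_id = c("g1", "g2"),
                        category = factor(c("V", "V"),
                                          levels = c("I", "II", "III", "IV", "V",
                                                     "VI", "VII", "VIII")),
                        direction = "none")
  tab <- concordance_by_category(cc, assigns)
  expect_equal(sum(tab$n), 2)
})
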