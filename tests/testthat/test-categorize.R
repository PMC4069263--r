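test_that("every significance pattern maps to its category (exhaustive truth table)", {
  pat <- expand.grid(d = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                     s3 = c(TRUE, FALSE))
  pat$gene_id <- sprintf("g%d", seq_len(nrow(pat)))
  comp <- pattern_comparisons(pat)
  got <- assign_categories(comp, fdr = 0.05)
  expected <- function(d, s2, s3) {
    if (d && s2 && !s3) "I"            # left CF, matches RF: switching
    else if (d && !s2 && s3) "II"      # kept CF level: refractory
    else if (d && s2 && s3) "III"      # left CF, short of RF: responsive
    else if (!d && s2) "IV"            # diet-independent deviator
    else if (!d && !s2 && !s3) "V"     # nothing significant
    else if (d && !s2 && !s3) "VI"     # indeterminate diet-dependent
    else "VIII"                        # leftover diet-independent pattern
  }
  for (i in seq_len(nrow(pat))) {
    expect_equal(as.character(got$category[got$gene_id == pat$gene_id[i]]),
                 expected(pat$d[i], pat$s2[i], pat$s3[i]),
                 info = sprintf("pattern d=%d s2=%d s3=%d",
                                pat$d[i], pat$s2[i], pat$s3[i]))
  }
  # partition: each gene exactly one category
  expect_equal(sum(table(got$category)), nrow(pat))
})

test_that("direction follows RF-CF for I-III and SF-CF for IV, none otherwise", {
  pat <- data.frame(gene_id = c("a", "b", "c", "d"),
                    d = c(TRUE, TRUE, FALSE, FALSE),
                    s2 = c(TRUE, FALSE, TRUE, FALSE),
                    s3 = c(FALSE, TRUE, FALSE, FALSE))
  comp <- pattern_comparisons(pat, diff_rf_cf = -2, diff_sf_cf = 1.5)
  got <- assign_categories(comp)
  expect_equal(got$direction[got$gene_id == "a"], "down")  # I, RF below CF
  expect_equal(got$direction[got$gene_id == "b"], "down")  # II
  expect_equal(got$direction[got$gene_id == "c"], "up")    # IV, SF above CF
  expect_equal(got$direction[got$gene_id == "d"], "none")  # V
  expect_true(all((got$direction != "none") ==
                    (got$category %in% c("I", "II", "III", "IV"))))
})

test_that("a stricter FDR never promotes a gene out of category V", {
  cfg <- expr_sim_config(n_genes = 150, seed = 23)
  comp <- run_comparisons(simulate_expression(cfg)$expr)
  loose <- assign_categories(comp, fdr = 0.05)
  strict <- assign_categories(comp, fdr = 0.005)
  was_v <- loose$gene_id[loose$category == "V"]
  now <- strict$category[match(was_v, strict$gene_id)]
  expect_false(any(now %in% c("I", "II", "III", "IV")))
})

test_that("indeterminate diet-dependent genes split into VI/VII/VIII by SF progress", {
  pat <- data.frame(gene_id = c("stay", "partial", "noisy"),
                    d = TRUE, s2 = FALSE, s3 = FALSE)
  comp <- pattern_comparisons(pat)
  st <- data.frame(gene_id = c("stay", "partial", "noisy"),
                   cf_mean = 5, rf_mean = 7,
                   sf_late_mean = c(5.1, 6, 6),
                   within_sd = c(0.2, 0.2, 5))
  got <- assign_categories(comp, stats = st)
  expect_equal(as.character(got$category),
               c("VI", "VII", "VIII")[match(got$gene_id, pat$gene_id)])
})

test_that("switch time is the earliest hour with a completed, sustained switch", {
  hours <- c(2, 4, 6, 8, 12, 18, 24, 32, 40, 48, 56, 72)
  # instantaneous switch completes at the first sampled hour
  inst <- setNames(rep(1, 12), hours)
  expect_equal(estimate_switch_time(inst, cf_level = 0, rf_level = 1), 2)
  # logistic with midpoint 6 h and unit time constant crosses 90% of the
  # gap at 6 + log(9) ~ 8.2 h; the first sampled hour past that is 12 h
  lg <- setNames(plogis((hours - 6) / 1), hours)
  expect_equal(estimate_switch_time(lg, 0, 1), 12)
  # refractory series never completes
  expect_true(is.na(estimate_switch_time(setNames(rep(0, 12), hours), 0, 1)))
  # degenerate gap warns and returns NA
  expect_warning(got <- estimate_switch_time(inst, 1, 1), "degenerate")
  expect_true(is.na(got))
  # a transient excursion back out of the completion band is not a switch
  bounce <- setNames(c(1, 1, 0.5, 1, 1, 1, 1, 1, 1, 1, 1, 1), hours)
  expect_equal(estimate_switch_time(bounce, 0, 1), 8)
})

test_that("fast-switcher curation keeps only quick category I genes", {
  assigns <- data.frame(
    gene_id = c("fast_up", "fast_down", "slow", "refractory"),
    category = factor(c("I", "I", "I", "II"),
                      levels = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")),
    direction = c("up", "down", "up", "down"))
  st <- data.frame(gene_id = assigns$gene_id,
                   switch_time_h = c(4, 6, 40, NA))
  got <- curate_fast_switchers(assigns, st, cutoff_h = 8)
  expect_equal(got$up, "fast_up")
  expect_equal(got$down, "fast_down")
  expect_equal(curate_fast_switchers(assigns, st, cutoff_h = 0),
               list(up = character(0), down = character(0)))
  none <- assigns[assigns$category == "II", ]
  expect_equal(lengths(curate_fast_switchers(none, st)), c(up = 0L, down = 0L))
})

test_that("synthetic fast and slow switchers are separated by the curation", {
  tp <- c(2, 4, 6, 8, 12, 18, 24, 32, 40, 48, 56, 72)
  cfg_fast <- expr_sim_config(n_genes = 20, sigma = 0, t0 = 2, tau = 1,
                              archetype_mix = c(switch_up = 1), seed = 1,
                              replicates_per_point = 1)
  cfg_slow <- expr_sim_config(n_genes = 20, sigma = 0, slow_t0 = 40,
                              slow_tau = 10,
                              archetype_mix = c(slow_switch = 1), seed = 1,
                              replicates_per_point = 1)
  st_fast <- switch_times(simulate_expression(cfg_fast)$expr)
  st_slow <- switch_times(simulate_expression(cfg_slow)$expr)
  expect_true(all(st_fast$switch_time_h <= 8))
  expect_true(all(is.na(st_slow$switch_time_h) | st_slow$switch_time_h > 8))
})
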