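#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a 2,000-gene three-cohort
# expression time course (CF, RF, SF over the 12 post-switch hours) and
# three Gompertz survival cohorts of 3,000 flies with the diet switch at
# day 40 and sampling censoring on the collection days.

library(dietswitch)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

expr_cfg <- expr_sim_config(n_genes = 2000, delta = 2, sigma = 0.25,
                            replicates_per_point = 3, seed = 2014L)
sim <- simulate_expression(expr_cfg)
write_expression(sim$expr,
                 "results/data/expression.tsv", "results/data/samples.tsv",
                 truth = sim$truth, truth_path = "results/data/expression_truth.tsv")
message(sprintf("expression: %d genes x %d samples; archetype mix: %s",
                nrow(sim$expr$values), ncol(sim$expr$values),
                paste(names(table(sim$truth$archetype)),
                      table(sim$truth$archetype), sep = "=", collapse = ", ")))

cohort_cfg <- cohort_sim_config(
  n_flies = 3000, dr_hazard_fold = 0.5, switch_day = 40, convergence_lag = 3,
  censor_schedule = sampling_censor_schedule(switch_day = 40, per_sample = 75),
  seed = 2014L)
cs <- simulate_cohorts(cohort_cfg)
write_events(cs$events, "results/data/events.tsv")
deaths <- tapply(cs$events$status == "death", cs$events$cohort, sum)
message(sprintf("cohorts: 3 x %d flies; deaths: %s", cohort_cfg$n_flies,
                paste(names(deaths), deaths, sep = "=", collapse = ", ")))
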