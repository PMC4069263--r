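#!/usr/bin/env Rscript
# Stage 5: direction-aware over-representation of the switching genes.
# No pathway database ships with the package (those are versioned
# snapshots), so this driver builds a synthetic GMT collection in which
# one set is deliberately seeded with down-switching genes and the rest
# are random draws -- the planted set should surface, the rest should not.

library(dietswitch)
set.seed(2014)

assign <- read.delim("results/categories.tsv", stringsAsFactors = FALSE)
assign$category <- factor(assign$category,
                          levels = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
universe <- assign$gene_id

down_I <- assign$gene_id[assign$category == "I" & assign$direction == "down"]
planted <- sample(down_I, min(20, length(down_I)))
sets <- c(list(planted_down_pathway = c(planted, sample(universe, 15))),
          lapply(1:12, function(i) sample(universe, 30)))
names(sets)[-1] <- sprintf("random_set_%02d", 1:12)

gmt <- "results/data/synthetic_sets.gmt"
writeLines(vapply(names(sets), function(nm) {
  paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t")
}, character(1)), gmt)

coll <- read_gmt(gmt)
res <- enrich_by_direction(assign, coll, universe = universe, categories = "I")
write.table(res, "results/enrichment_category_I.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- res[res$q < 0.05, ]
message(sprintf("tested %d set x direction combinations; %d significant at q < 0.05",
                nrow(res), nrow(sig)))
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %s (%s): overlap %d/%d, q = %.2e", sig$set[i],
                  sig$direction[i], sig$overlap[i], sig$set_size[i], sig$q[i]))
}
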