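#!/usr/bin/env Rscript
# Occurrence thinning, collinearity filtering, pseudo-absence sampling
# and the train/validation split that feed the model registry.

suppressMessages(library(pairedSDM))
dir.create("results", showWarnings = FALSE)

seed <- 1
land <- simulate_landscape(100, 100, 1, seed = seed)
stack <- land$stack
occ_raw <- read_occurrences("results/landscape/occurrences_raw.csv")

occ <- thin_occurrences(occ_raw, 3, seed = seed + 600)
cat(sprintf("thinning at 3 km: %d raw -> %d retained\n",
            nrow(occ_raw), nrow(occ)))
write_occurrences(occ, "results/occurrences_thinned.csv")

vars <- pearson_filter(stack, 0.8)
cat(sprintf("collinearity filter |r| <= 0.8: %d of %d predictors kept\n",
            length(vars), length(stack$layers) + length(stack$categorical)))
writeLines(vars, "results/selected_variables.txt")
cat("  ", paste(vars, collapse = ", "), "\n")

pa <- sample_pseudo_absences(stack, occ, 500, seed = seed + 700)
tab <- build_model_table(stack, occ, pa, vars)
tab <- split_rows(tab, c(0.8, 0.2), seed = seed + 800)
cat(sprintf("model table: %d presences + %d pseudo-absences, %d train / %d valid\n",
            sum(tab$response == 1), sum(tab$response == 0),
            sum(tab$split == "train"), sum(tab$split == "valid")))
write.csv(tab[, c("lon", "lat", "response", "split")],
          "results/model_points.csv", row.names = FALSE)
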