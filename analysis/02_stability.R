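#!/usr/bin/env Rscript
# Stability analysis of the simulated ensemble: reads the TSVs written by
# 01_simulate.R, builds loss webs and Jacobians, computes s*, the heaviest
# 2-link loop, and the hierarchy/asymmetry indices per assemblage, and fits
# the regression of s* on w2max that summarises how pairwise feedback
# governs relative instability.

library(compstab)

data_dir <- "results/data"
files <- list.files(data_dir, pattern = "_contests\\.tsv$", full.names = TRUE)
stopifnot(length(files) > 0)

ens <- lapply(files, function(f) {
  read_contacts(f, sub("_contests\\.tsv$", "_abundance.tsv", f),
                assemblage_id = sub("_contests\\.tsv$", "", basename(f)))
})

an <- analyze(ens)
write.csv(an$records, "results/02_stability_records.csv", row.names = FALSE)
jsonlite::write_json(an$regression, "results/02_s_star_w2max_regression.json",
                     auto_unbox = TRUE, digits = NA)

r <- an$records
cat(sprintf("Analysed %d assemblages: %d unstable (s* > 1), s* %.2f-%.2f\n",
            nrow(r), sum(r$s_star > 1), min(r$s_star), max(r$s_star)))
cat(sprintf("s* ~ w2max: slope %.3f, intercept %.3f, R^2 %.3f\n",
            an$regression$slope, an$regression$intercept,
            an$regression$r_squared))
cat(sprintf("shortcut vs bisection s*: median relative gap %.3g, max %.3g\n",
            median(r$agreement_gap / r$s_star),
            max(r$agreement_gap / r$s_star)))
cat(sprintf("win index %.2f-%.2f; intransitivity %.2f-%.2f (transitive < 0)\n",
            min(r$win_index), max(r$win_index),
            min(r$intransitivity, na.rm = TRUE),
            max(r$intransitivity, na.rm = TRUE)))
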