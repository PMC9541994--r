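#!/usr/bin/env Rscript
# Deterministic sensitivity analysis: one-way excursions over every declared
# parameter range, tornado ordering of the swings, a two-way grid over the
# two ultrasound-arm task times, and break-even thresholds. Writes CSV
# tables under results/sensitivity/.

library(cvccost)

params <- load_parameters(system.file("extdata", "default_parameters.json",
                                      package = "cvccost"))
out_dir <- file.path("results", "sensitivity")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ow <- one_way_all(params, include_wages = TRUE)
write.csv(ow, file.path(out_dir, "one_way.csv"), row.names = FALSE)

tor <- tornado(params)                          # times + probabilities
tor_wages <- tornado(params, include_wages = TRUE)
write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
write.csv(tor_wages, file.path(out_dir, "tornado_with_wages.csv"),
          row.names = FALSE)

cat("Tornado (savings swing per parameter, wages excluded):\n")
print(tor, digits = 4)

flips <- ow[ow$diff_low < 0 | ow$diff_high < 0, "parameter"]
cat(sprintf("\nParameters whose extreme flips the savings: %s\n",
            paste(flips, collapse = ", ")))
ow_md <- ow[ow$parameter == "mdTimeB", ]
cat(sprintf("At the upper extreme of bedside-physician ultrasound time (%.1f min),\n",
            ow_md$highInput))
cat(sprintf("protocol B is %.0f%% more costly than protocol A.\n",
            100 * (ow_md$costB_high - ow_md$costA_high) / ow_md$costA_high))

tw <- two_way(params, "mdTimeB", "rnTimeB", gridPoints = 11)
write.csv(two_way_long(tw), file.path(out_dir, "two_way_mdTimeB_rnTimeB.csv"),
          row.names = FALSE)
cat(sprintf("\nTwo-way grid (mdTimeB x rnTimeB): savings range $%.2f to $%.2f\n",
            min(tw$diff), max(tw$diff)))

cat("\nBreak-even thresholds (value at which the protocols cost the same):\n")
for (lab in parameter_labels(include_wages = FALSE)) {
  root <- break_even(params, lab)
  cat(sprintf("  %-16s %s\n", lab,
              if (is.na(root)) "none within the extended range"
              else sprintf("%.3f", root)))
}
cat("\nWrote one_way.csv, tornado*.csv, two_way_mdTimeB_rnTimeB.csv to",
    paste0(out_dir, "/\n"))
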