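#!/usr/bin/env Rscript
# Generate the four synthetic study datasets: a monthly open-ocean series
# (BATS-like), a weekly coastal series (WEC-like, 7 years, 10% missed
# weeks), and a pair of 2-year weekly series in which the community either
# tracks the same-week environment ("coupled", calm weather) or follows a
# smoothed seasonal signal ("decoupled", stormy weather).
# Writes TSV/CSV inputs plus ground truth under results/data/<name>/.

library(ecocycle)

seed <- 1
out_root <- "results/data"

for (name in c("bats_like", "wec_like", "coupled_year", "decoupled_year")) {
  ds <- simulate_dataset(name, seed = seed)
  dir <- file.path(out_root, name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(ds$counts, file.path(dir, "counts.tsv"), "tsv")
  write_taxonomy(ds$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_env_table(ds$env, file.path(dir, "environment.csv"))
  jsonlite::write_json(ds$truth[c("asv", "years", "params")],
                       file.path(dir, "groundtruth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("%-14s %4d samples x %d ASVs -> %s",
                  name, nrow(ds$counts$counts), ncol(ds$counts$counts), dir))
}
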