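#!/usr/bin/env Rscript
# Ecotype-level composition of the weekly coastal dataset: relative
# contribution of each SAR11 ecotype and the SAR11 share of the whole
# amplicon pool per sample. Writes tables and a composition figure.

library(ecocycle)

dir <- "results/data/wec_like"
cm <- read_count_table(file.path(dir, "counts.tsv"), "tsv")
tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))

eco <- collapse_by_ecotype(cm, tax)
ra <- relative_abundance(eco)
frac <- sar11_fraction(cm, tax)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(sample_id = eco$sample_ids, date = eco$dates, ra$values,
                     check.names = FALSE),
          "results/wec_ecotype_composition.csv", row.names = FALSE)
write.csv(data.frame(sample_id = names(frac), date = cm$dates,
                     sar11_fraction = frac),
          "results/wec_sar11_fraction.csv", row.names = FALSE)

message(sprintf("SAR11 fraction: %.1f%% to %.1f%% (median %.1f%%)",
                100 * min(frac), 100 * max(frac), 100 * median(frac)))
dom <- names(sort(colMeans(ra$values), decreasing = TRUE))[1:3]
message("dominant ecotypes: ", paste(dom, collapse = ", "))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long <- do.call(rbind, lapply(colnames(ra$values), function(e)
    data.frame(date = eco$dates, ecotype = e, prop = ra$values[, e])))
  p <- ggplot(long, aes(date, prop, fill = ecotype)) +
    geom_area() +
    labs(y = "relative contribution", x = NULL,
         title = "Ecotype composition, weekly coastal simulation") +
    theme_minimal()
  ggsave("results/wec_ecotype_composition.png", p, width = 10, height = 4,
         dpi = 150)
}
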