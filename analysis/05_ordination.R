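#!/usr/bin/env Rscript
# Constrained ordination (db-RDA) of the weekly coastal SAR11 community on
# the environmental table, PERMANOVA of the warm/cold split, and
# hierarchical clustering of samples.

library(ecocycle)

seed <- 1
dir <- "results/data/wec_like"
cm <- read_count_table(file.path(dir, "counts.tsv"), "tsv")
tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
env <- read_env_table(file.path(dir, "environment.csv"))

sar11 <- subset_count_matrix(cm, asvs = tax[cm$asv_ids] != "other")
rar <- rarefy(sar11, seed = seed)
bc <- pairwise_distance(rar$counts, "bray_curtis")

keep <- as.Date(env$date) %in% rar$dates
env_m <- env[keep, ]
idx <- match(as.Date(env_m$date), rar$dates)
bc_m <- bc[idx, idx]

capres <- cap(bc_m, env_m, n_perm = 999, seed = seed)
message(sprintf(
  "environmental variables explain %.0f%% (adjusted %.0f%%) of SAR11 community variance",
  100 * capres$constrained_proportion, 100 * capres$adjusted_R2))

cl <- hierarchical_clusters(bc_m, rar$dates[idx], k = 2)
prm <- permanova(bc_m, cl$season, n_perm = 999, seed = seed)
print(prm)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(sample_id = rownames(capres$site_scores),
                     date = rar$dates[idx], capres$site_scores[, 1:2],
                     cluster = cl$cluster, season = cl$season),
          "results/wec_ordination_scores.csv", row.names = FALSE)
write.csv(data.frame(variable = rownames(capres$biplot_scores),
                     capres$biplot_scores[, 1:2]),
          "results/wec_ordination_biplot.csv", row.names = FALSE)
writeLines(cl$newick, "results/wec_dendrogram.nwk")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  sc <- as.data.frame(capres$site_scores[, 1:2])
  sc$season <- cl$season
  bp <- as.data.frame(capres$biplot_scores[, 1:2])
  bp$variable <- rownames(bp)
  mult <- max(abs(sc[, 1:2])) * 0.9
  p <- ggplot(sc, aes(CAP1, CAP2, colour = season)) +
    geom_point(size = 1.6) +
    geom_segment(data = bp, inherit.aes = FALSE,
                 aes(x = 0, y = 0, xend = CAP1 * mult, yend = CAP2 * mult),
                 arrow = arrow(length = unit(2, "mm")), colour = "grey40") +
    geom_text(data = bp, inherit.aes = FALSE, size = 2.5, colour = "grey20",
              aes(CAP1 * mult * 1.08, CAP2 * mult * 1.08, label = variable)) +
    scale_colour_manual(values = c(warm = "#d1495b", cold = "#30638e")) +
    labs(title = sprintf(
      "db-RDA of SAR11 community (%.0f%% constrained, adj. %.0f%%; warm/cold Pr(>F) = %.3g)",
      100 * capres$constrained_proportion, 100 * capres$adjusted_R2, prm$p)) +
    theme_minimal()
  ggsave("results/wec_ordination.png", p, width = 8, height = 6, dpi = 150)
}
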