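#!/usr/bin/env Rscript
# Group comparison and correlation statistics on simulated per-genotype
# tables: whole-section plaque counts for two transgenic lines and their
# prion-protein-null counterparts, compared with tie-corrected
# Kruskal-Wallis plus Dunn's test over the study's explicit contrasts,
# and exact small-sample Spearman correlations.

suppressPackageStartupMessages(library(plaquetools))
dir.create("results", showWarnings = FALSE)

# medians on the scale of whole-section plaque counts in aged transgenics;
# controls essentially plaque-free
groups <- simulate_groups(
  medians = c(appps1 = 2815, appps1_prnp0 = 2815,
              j20 = 1315, j20_prnp0 = 1315,
              wt = 2, prnp0 = 2),
  spread = 0.35, n = c(8, 8, 5, 5, 8, 8), seed = 2024)

summ <- summarize_groups(groups)
print(summ, row.names = FALSE)
write.csv(summ, "results/group_summary.csv", row.names = FALSE)

contrasts <- list(c("wt", "appps1"), c("prnp0", "appps1_prnp0"),
                  c("wt", "j20"), c("prnp0", "j20_prnp0"),
                  c("appps1", "appps1_prnp0"), c("j20", "j20_prnp0"),
                  c("appps1", "j20"))
kd <- kruskal_dunn(groups, contrasts)
print(kd)
write.csv(kd$pairwise, "results/kw_dunn.csv", row.names = FALSE)

# exact permutation Spearman at cohort sizes of 4-5 animals
cor_tbl <- rbind(
  data.frame(cohort = "appps1", n = 5,
             rho = spearman_exact(1:5, c(1, 2, 3, 5, 4))$rho,
             p = spearman_exact(1:5, c(1, 2, 3, 5, 4))$p),
  data.frame(cohort = "j20", n = 4,
             rho = spearman_exact(1:4, c(4, 3, 1, 2))$rho,
             p = spearman_exact(1:4, c(4, 3, 1, 2))$p))
cor_tbl$p_2dp <- round(cor_tbl$p, 2)
print(cor_tbl, row.names = FALSE)
write.csv(cor_tbl, "results/spearman_exact.csv", row.names = FALSE)
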