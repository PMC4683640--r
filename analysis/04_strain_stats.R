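#!/usr/bin/env Rscript
# Stage 4 - strain-level statistics.
#
# Runs the survey's statistics layer on the simulated phenotype table:
# per-strain modified z-scores with outlier classification, broad-sense
# heritability under both variance-component estimators, pairwise-complete
# Pearson correlations (after adding a second, correlated trait), and the
# two-way ANOVA with a strain x age interaction.

suppressPackageStartupMessages(library(spermatoscope))
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

pheno <- read_phenotypes_csv("results/simulated/phenotypes.csv")

summ <- strain_summaries(pheno, "trait")
readr::write_csv(summ, "results/stats/strain_summaries.csv")
out <- summ[summ$z_class != "normal", ]
message(sprintf("modified z: %d/%d strains flagged as outliers (%s)",
                nrow(out), nrow(summ),
                paste(sprintf("%s %s z=%.2f", out$strain, out$z_class, out$z),
                      collapse = "; ")))

her <- rbind(heritability(pheno, "trait", "strain_mean_variance"),
             heritability(pheno, "trait", "anova_mom"))
readr::write_csv(her, "results/stats/heritability.csv")
message(sprintf("h2 (true 0.70): strain-mean estimator %.3f, ANOVA estimator %.3f",
                her$h2[1], her$h2[2]))

# second trait correlated with the first through the shared strain effects
set.seed(seed)
pheno$trait2 <- 0.8 * pheno$trait + rnorm(nrow(pheno), sd = 0.4)
pheno$trait2[sample(nrow(pheno), 20)] <- NA
corr <- pairwise_pearson(pheno, c("trait", "trait2"))
readr::write_csv(corr$long, "results/stats/correlations.csv")
message(sprintf("pairwise-complete Pearson r(trait, trait2) = %.3f on n = %d",
                corr$long$r[1], corr$long$n[1]))

anv <- rbind(two_way_anova(pheno, "trait"),
             one_way_anova(pheno, "trait", "strain"))
readr::write_csv(anv, "results/stats/anova.csv")
a <- two_way_anova(pheno, "trait")
message(sprintf("two-way ANOVA: strain F=%.1f (p=%.2g), age F=%.2f (p=%.2g), interaction F=%.2f (p=%.2g)",
                a$statistic[1], a$p[1], a$statistic[2], a$p[2],
                a$statistic[3], a$p[3]))
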