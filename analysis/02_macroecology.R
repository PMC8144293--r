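#!/usr/bin/env Rscript
# Macroecological characterization of each dataset: per-sample rarefaction
# curves, ASV accumulation with sample size, jackknife-1 pool extrapolation
# and its sample-size dependence, percent-of-pool detection, prevalence
# class distributions, occupancy-abundance and rank-abundance curves.
# Reads results/synth/ (run 01_simulate.R first); writes tidy TSVs under
# results/macroecology/.

suppressPackageStartupMessages(library(coresweep))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

root <- file.path("results", "synth")
datasets <- setdiff(list.dirs(root, recursive = FALSE, full.names = FALSE), "")
if (length(datasets) == 0) stop("no datasets under results/synth; run 01_simulate.R")
out_dir <- file.path("results", "macroecology")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rare_l <- acc_l <- pool_l <- pct_l <- cls_l <- oa_l <- ra_l <- list()
for (nm in datasets) {
  tb <- read_feature_table(file.path(root, nm, "table.tsv"))

  # detection vs depth for the deepest sample, on a log-ish depth grid
  deep <- which.max(rowSums(tb))
  grid <- unique(round(exp(seq(log(10), log(sum(tb[deep, ])), length.out = 25))))
  rc <- rarefaction_curve(tb[deep, ], grid)
  rare_l[[nm]] <- data.frame(dataset = nm, sample = rownames(tb)[deep], rc)

  acc <- sample_accumulation(tb, permutations = 199, seed = seed)
  acc_l[[nm]] <- data.frame(dataset = nm, acc, permutations = 199, seed = seed)

  pool <- pool_accumulation(tb, permutations = 99, seed = seed)
  pool_l[[nm]] <- data.frame(dataset = nm, pool, permutations = 99, seed = seed)

  pd <- percent_detected(tb, permutations = 99, seed = seed)
  pct_l[[nm]] <- data.frame(dataset = nm, pd$curve, k50 = pd$k50,
                            jack1 = pd$pool)
  message(sprintf("%-12s jackknife-1 pool %5.0f; %4.1f%% detected; 50%% of the pool needs %d samples",
                  nm, pd$pool, utils::tail(pd$curve$pct, 1), pd$k50))

  cls <- prevalence_class_distributions(tb, top_class = 8)
  cls_l[[nm]] <- data.frame(dataset = nm, class = names(cls$dataset),
                            dataset_prop = unname(cls$dataset),
                            per_sample_prop = unname(cls$per_sample))
  oa_l[[nm]] <- data.frame(dataset = nm, occupancy_abundance(tb))
  ra_l[[nm]] <- data.frame(dataset = nm, rank_abundance(tb))
}

write_tidy(do.call(rbind, rare_l), file.path(out_dir, "rarefaction.tsv"))
write_tidy(do.call(rbind, acc_l), file.path(out_dir, "accumulation.tsv"))
write_tidy(do.call(rbind, pool_l), file.path(out_dir, "pool_accumulation.tsv"))
write_tidy(do.call(rbind, pct_l), file.path(out_dir, "percent_detected.tsv"))
write_tidy(do.call(rbind, cls_l), file.path(out_dir, "prevalence_classes.tsv"))
write_tidy(do.call(rbind, oa_l), file.path(out_dir, "occupancy_abundance.tsv"))
write_tidy(do.call(rbind, ra_l), file.path(out_dir, "rank_abundance.tsv"))
message("wrote 7 tables under results/macroecology/")
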