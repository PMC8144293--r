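#' Configuration of a prevalence-threshold sweep
#'
#' Bundles every tunable of the sweep: the common rarefaction depth
#' (default 10,000 reads, the depth at which ASV detection saturates in
#' 16S gut data), the minimum depth a sample must reach to be retained,
#' the prevalence-threshold grid (default 0 to 0.9 in steps of 0.1), the
#' alpha and beta metric lists, the BWPD balance exponent, the weighted
#' UniFrac normalization flag, whether to rarefy at all (the unnormalized
#' variant of the sweep), and the RNG seed that makes the sweep
#' bit-reproducible.
#'
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param min_depth Samples below this total are dropped (defaults to the
#'   rarefaction depth).
#' @param thresholds Strictly increasing prevalence thresholds in \[0, 1).
#' @param alpha_metrics Subset of `observed_richness`, `shannon`,
#'   `faith_pd`, `bwpd`.
#' @param beta_metrics Subset of `jaccard`, `morisita`, `bray_curtis`,
#'   `unweighted_unifrac`, `weighted_unifrac`.
#' @param theta BWPD balance exponent in \[0, 1\].
#' @param wu_normalized Use normalized weighted UniFrac (default `TRUE`).
#' @param rarefy If `FALSE`, skip rarefaction (samples below `min_depth`
#'   are still dropped).
#' @param seed Integer seed for the rarefaction draw.
#' @return A `"sweep_config"` list.
#' @export
sweep_config <- function(rarefaction_depth = 10000L,
                         min_depth = rarefaction_depth,
                         thresholds = seq(0, 0.9, by = 0.1),
                         alpha_metrics = c("observed_richness", "shannon",
                                           "faith_pd", "bwpd"),
                         beta_metrics = c("jaccard", "morisita",
                                          "unweighted_unifrac",
                                          "weighted_unifrac"),
                         theta = 0.5, wu_normalized = TRUE,
                         rarefy = TRUE, seed = 1L) {
  if (rarefaction_depth < 1) stop("rarefaction depth must be >= 1")
  if (any(thresholds < 0) || any(thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing within [0, 1)")
  }
  # seq(0, 0.9, 0.1) carries float error at 0.3/0.6/0.7; round so grid
  # values compare equal to their literals downstream
  thresholds <- round(thresholds, 10)
  alpha_metrics <- match.arg(alpha_metrics, several.ok = TRUE)
  beta_metrics <- match.arg(beta_metrics, several.ok = TRUE)
  structure(list(rarefaction_depth = as.integer(rarefaction_depth),
                 min_depth = as.integer(min_depth),
                 thresholds = thresholds,
                 alpha_metrics = alpha_metrics,
                 beta_metrics = beta_metrics,
                 theta = theta, wu_normalized = wu_normalized,
                 rarefy = rarefy, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Rarefy every sample of a table to a common depth
#'
#' Samples whose total is below `depth` are dropped (with a message
#' listing them); each retained sample is subsampled without replacement
#' to exactly `depth` reads via [vegan::rrarefy()]; taxa left with zero
#' total are removed. Deterministic given `seed`.
#'
#' @param table Count matrix, samples as rows.
#' @param depth Target reads per sample.
#' @param seed Optional RNG seed.
#' @return Rarefied count matrix; all row sums equal `depth`.
#' @export
rarefy_table <- function(table, depth, seed = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  validate_counts(table)
  tot <- rowSums(table)
  drop <- tot < depth
  if (all(drop)) stop("no sample reaches the rarefaction depth of ", depth)
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[drop], collapse = ", "))
    table <- table[!drop, , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  out <- vegan::rrarefy(table, depth)
  out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Filter taxa by prevalence
#'
#' Retains taxa whose occupancy (fraction of samples with count > 0,
#' computed on the input table) is at least `threshold` — the boundary is
#' inclusive, matching common core-microbiome practice. Samples are never
#' dropped, even if the filter empties them; emptiness is surfaced
#' downstream as missing scores. Threshold 0 returns the input unchanged.
#'
#' @param table Count matrix, samples as rows.
#' @param threshold Prevalence threshold in \[0, 1\].
#' @return The filtered table.
#' @export
prevalence_filter <- function(table, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (threshold == 0) return(table)
  occ <- colMeans(table > 0)
  table[, occ >= threshold, drop = FALSE]
}

#' Run the prevalence-threshold sweep
#'
#' The core experiment: (optionally) rarefy, then for each prevalence
#' threshold filter the rarefied table — each threshold filters the
#' original rarefied table independently, never the output of an earlier
#' threshold — and score every configured alpha measure per sample and the
#' mean per-sample dissimilarity for every configured beta measure.
#' Filtering happens once per threshold, not per metric. Reads remaining
#' per sample after filtering are recorded for the read-depth bias check.
#' Samples emptied by a filter get `NA` scores (beta matrices are computed
#' over the remaining non-empty samples).
#'
#' When `metadata` is supplied the sweep runs within each dataset label
#' (prevalence, filtering and beta matrices are all per-dataset).
#'
#' @param table Count matrix, samples as rows.
#' @param tree Rooted `"phylo"` whose leaves cover the table's taxa
#'   (required if any phylogenetic metric is configured).
#' @param metadata Optional data frame with `sample_id`, `dataset_label`.
#' @param config A [sweep_config()].
#' @return A `"sweep_result"` data frame: `dataset`, `sample`,
#'   `threshold`, `metric`, `type` ("alpha"/"beta"), `score`,
#'   `reads_remaining`.
#' @export
run_sweep <- function(table, tree = NULL, metadata = NULL,
                      config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  validate_counts(table)
  needs_tree <- any(c(config$alpha_metrics, config$beta_metrics) %in%
                    c("faith_pd", "bwpd", "unweighted_unifrac",
                      "weighted_unifrac"))
  if (needs_tree) {
    if (is.null(tree)) stop("configured metrics require a tree")
    tree <- validate_phylogeny(tree)
    missing <- setdiff(colnames(table), tree$tip.label)
    if (length(missing) > 0L) {
      stop("table and tree are not aligned; taxa missing from tree: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }

  if (config$rarefy) {
    table <- rarefy_table(table, config$rarefaction_depth, seed = config$seed)
  } else {
    keep <- rowSums(table) >= config$min_depth
    if (!any(keep)) stop("no sample reaches min_depth = ", config$min_depth)
    if (!all(keep)) {
      message("dropping ", sum(!keep), " sample(s) below min_depth")
    }
    table <- table[keep, , drop = FALSE]
  }

  if (is.null(metadata)) {
    groups <- list(dataset = rownames(table))
    labels <- "dataset"
  } else {
    md <- metadata[match(rownames(table), metadata$sample_id), ]
    if (anyNA(md$dataset_label)) stop("metadata is missing some table samples")
    labels <- unique(md$dataset_label)
    groups <- lapply(labels, function(l) rownames(table)[md$dataset_label == l])
    names(groups) <- labels
  }

  res <- list()
  for (lab in labels) {
    sub <- table[groups[[lab]], , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    # one tree per dataset, shared by every threshold, so Faith's PD keeps
    # a fixed root path and is exactly non-increasing along the grid
    subtree <- NULL
    if (needs_tree) {
      subtree <- if (ncol(sub) >= 2L &&
                     length(setdiff(tree$tip.label, colnames(sub))) > 0L) {
        ape::keep.tip(tree, colnames(sub))
      } else tree
    }
    for (t in config$thresholds) {
      ft <- prevalence_filter(sub, t)
      reads <- rowSums(ft)
      res[[length(res) + 1L]] <-
        .score_block(ft, subtree, lab, t, reads, config)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

.score_block <- function(ft, subtree, lab, t, reads, config) {
  samples <- rownames(ft)
  empty <- reads == 0
  if (any(empty)) {
    message("threshold ", t, " (", lab, "): ", sum(empty),
            " sample(s) emptied by filtering")
  }
  blocks <- list()
  if (ncol(ft) > 0L && any(!empty)) {
    a <- alpha_diversity(ft, subtree, metrics = config$alpha_metrics,
                         theta = config$theta)
    a$type <- "alpha"
    blocks$alpha <- a
    for (bm in config$beta_metrics) {
      # Morisita needs >= 2 reads; samples below any measurability floor
      # get missing scores ("not even measurable"), like emptied samples
      usable <- if (bm == "morisita") reads >= 2 else !empty
      sc <- rep(NA_real_, length(samples))
      if (sum(usable) >= 2L) {
        D <- pairwise_matrix(ft[usable, , drop = FALSE], subtree, metric = bm,
                             normalized = config$wu_normalized)
        mu <- mean_dissimilarity_per_sample(D)
        sc[match(names(mu), samples)] <- mu
      }
      blocks[[bm]] <- data.frame(sample = samples, metric = bm, score = sc,
                                 type = "beta", stringsAsFactors = FALSE)
    }
  } else {
    # every sample emptied: all scores missing
    for (m in c(config$alpha_metrics, config$beta_metrics)) {
      blocks[[m]] <- data.frame(
        sample = samples, metric = m, score = NA_real_,
        type = if (m %in% config$alpha_metrics) "alpha" else "beta",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  out$dataset <- lab
  out$threshold <- t
  out$reads_remaining <- reads[match(out$sample, samples)]
  rownames(out) <- NULL
  out[, c("dataset", "sample", "threshold", "metric", "type", "score",
          "reads_remaining")]
}

#' Standardize sweep scores per dataset and metric
#'
#' Adds a z-score column: within each (dataset, metric) group, scores are
#' centered and scaled over all thresholds jointly, z = (score - mean) /
#' sd, with the n-1 sd. Grouping across thresholds (rather than within
#' each threshold) is what lets standardized means decline with threshold;
#' it accounts for natural between-species differences in diversity while
#' preserving the threshold effect. Missing scores propagate; a group
#' with zero sd gets all-missing z with a warning.
#'
#' @param result A `"sweep_result"` from [run_sweep()].
#' @return The result with a `z` column.
#' @export
standardize <- function(result) {
  key <- interaction(result$dataset, result$metric, drop = TRUE)
  z <- rep(NA_real_, nrow(result))
  for (g in levels(key)) {
    i <- which(key == g)
    x <- result$score[i]
    ok <- !is.na(x)
    if (sum(ok) < 2L) {
      warning("group ", g, " has fewer than two scores; z set missing")
      next
    }
    s <- stats::sd(x[ok])
    if (s == 0) {
      warning("group ", g, " has zero variance; z set missing")
      next
    }
    z[i] <- (x - mean(x[ok])) / s
  }
  result$z <- z
  result
}

#' Bartlett's test of equal variances
#'
#' \deqn{K^2 = \frac{(N-k)\ln s_p^2 - \sum_i (n_i-1)\ln s_i^2}{C}}
#' with the usual correction C and a chi-square upper tail on k-1 degrees
#' of freedom (delegated to [stats::bartlett.test()]). Groups must each
#' contain at least two values with positive variance, otherwise the
#' statistic is undefined.
#'
#' @param groups List of numeric vectors (one per group); NAs dropped.
#' @return List: `statistic` (K-squared), `df`, `p.value`, `method`.
#' @export
bartlett_test <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) < 2L) stop("Bartlett's test needs >= 2 groups of >= 2 values")
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("Bartlett's statistic is undefined when a group has zero variance")
  }
  ht <- stats::bartlett.test(groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = "bartlett")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (midranks for ties), with the
#' p-value from the t approximation on n-2 degrees of freedom (via
#' [stats::cor.test()] with `exact = FALSE`). Pairs with a missing value
#' in either vector are deleted first.
#'
#' @param x,y Equal-length numeric vectors; >= 3 complete pairs required.
#' @return List: `estimate` (rho), `p.value`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("Spearman correlation needs >= 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("Spearman correlation is undefined with zero rank variance")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(estimate = unname(ht$estimate), p.value = ht$p.value,
       n = length(x), method = "spearman")
}

#' Correlation of filtered with unfiltered diversity scores
#'
#' For every dataset x metric x threshold > 0: Spearman correlation, over
#' samples scored in both, between that threshold's per-sample scores and
#' the unfiltered (threshold 0) scores. High rho means filtering preserves
#' the ranking of individuals; a threshold that removed no taxa gives
#' rho = 1 exactly.
#'
#' @param result A `"sweep_result"`.
#' @return Data frame: `dataset`, `metric`, `threshold`, `rho`, `p`, `n`
#'   (`NA` rho where too few complete pairs or zero rank variance).
#' @export
core_vs_unfiltered <- function(result) {
  if (!any(result$threshold == 0)) stop("threshold-0 scores are required")
  base <- result[result$threshold == 0, ]
  rest <- result[result$threshold > 0, ]
  combos <- unique(rest[, c("dataset", "metric", "threshold")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    b <- base[base$dataset == cb$dataset & base$metric == cb$metric, ]
    f <- rest[rest$dataset == cb$dataset & rest$metric == cb$metric &
              rest$threshold == cb$threshold, ]
    x <- b$score[match(f$sample, b$sample)]
    st <- tryCatch(spearman_test(x, f$score), error = function(e) NULL)
    data.frame(dataset = cb$dataset, metric = cb$metric,
               threshold = cb$threshold,
               rho = if (is.null(st)) NA_real_ else st$estimate,
               p = if (is.null(st)) NA_real_ else st$p.value,
               n = if (is.null(st)) sum(!is.na(x) & !is.na(f$score)) else st$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read-depth bias after prevalence filtering
#'
#' Spearman correlation between per-sample reads remaining after filtering
#' and each diversity score, per dataset x metric x threshold. At
#' threshold 0 on a rarefied table the reads remaining are constant, so
#' the correlation is undefined and reported missing. No direction is
#' asserted anywhere: the sign of this bias is an empirical question.
#'
#' @param result A `"sweep_result"`.
#' @return Data frame: `dataset`, `metric`, `threshold`, `rho`, `p`, `n`.
#' @export
depth_bias <- function(result) {
  combos <- unique(result[, c("dataset", "metric", "threshold")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    f <- result[result$dataset == cb$dataset & result$metric == cb$metric &
                result$threshold == cb$threshold, ]
    st <- tryCatch(spearman_test(f$reads_remaining, f$score),
                   error = function(e) NULL)
    data.frame(dataset = cb$dataset, metric = cb$metric,
               threshold = cb$threshold,
               rho = if (is.null(st)) NA_real_ else st$estimate,
               p = if (is.null(st)) NA_real_ else st$p.value,
               n = if (is.null(st)) sum(!is.na(f$score)) else st$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance profile across prevalence thresholds
#'
#' Bartlett's test of equal variance with thresholds as groups, per
#' metric, on standardized scores. The default pools datasets (scores are
#' already standardized within dataset, so pooling compares the common
#' threshold effect); `per_dataset = TRUE` tests within each dataset.
#' A large K-squared means across-sample variation changes strongly along
#' the threshold grid.
#'
#' @param result A standardized `"sweep_result"` (see [standardize()]).
#' @param per_dataset Test within each dataset instead of pooling.
#' @return Data frame: (`dataset`,) `metric`, `statistic`, `df`, `p`.
#' @export
variance_profile <- function(result, per_dataset = FALSE) {
  if (is.null(result$z)) stop("run standardize() first")
  split_by <- if (per_dataset) {
    split(result, result[, c("dataset", "metric")], drop = TRUE)
  } else {
    split(result, result$metric)
  }
  rows <- lapply(split_by, function(d) {
    groups <- split(d$z, d$threshold)
    groups <- lapply(groups, function(g) g[!is.na(g)])
    # degenerate threshold groups (too few scores, or all samples collapsed
    # to the same value) carry no variance information; drop them like the
    # paper drops thresholds where scores were no longer measurable
    groups <- groups[vapply(groups, length, integer(1)) >= 2L]
    groups <- groups[vapply(groups, stats::var, numeric(1)) > 0]
    bt <- tryCatch(bartlett_test(groups), error = function(e) NULL)
    data.frame(dataset = if (per_dataset) d$dataset[1L] else "pooled",
               metric = d$metric[1L],
               statistic = if (is.null(bt)) NA_real_ else bt$statistic,
               df = if (is.null(bt)) NA_real_ else bt$df,
               p = if (is.null(bt)) NA_real_ else bt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
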