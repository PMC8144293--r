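#' Incidence summary of a feature table
#'
#' Occupancy bookkeeping shared by the accumulation and extrapolation
#' functions: per-taxon incidence counts m_j (number of samples in which
#' taxon j is detected), the incidence frequency spectrum f_k (number of
#' taxa occurring in exactly k samples), and per-taxon occupancy m_j / n.
#'
#' @param table Count matrix, samples as rows.
#' @return List with `n` (samples), `S_obs` (observed taxa), `incidence`
#'   (named m_j for observed taxa), `f` (f_1..f_n), `occupancy` (m_j / n).
#' @export
incidence_summary <- function(table) {
  n <- nrow(table)
  m <- colSums(table > 0)
  m <- m[m > 0]
  list(n = n,
       S_obs = length(m),
       incidence = m,
       f = tabulate(m, nbins = n),
       occupancy = m / n)
}

#' Rarefaction curve: expected ASV richness vs sequencing depth
#'
#' Exact mode evaluates the hypergeometric expectation
#' \deqn{E[S_m] = \sum_j \left[1 - \binom{N - x_j}{m} / \binom{N}{m}\right]}
#' with binomial coefficients in log space (`lchoose`), which is stable at
#' depths of 1e5 and beyond. Subsample mode averages the richness of
#' seeded without-replacement draws and also reports their standard
#' deviation.
#'
#' @param counts Count vector for one sample.
#' @param depths Integer depths, each <= the sample total.
#' @param mode `"exact"` or `"subsample"`.
#' @param iterations Number of draws per depth in subsample mode.
#' @param seed Optional RNG seed for subsample mode.
#' @return Data frame: `depth`, `richness` (expected/mean), `sd` (NA in
#'   exact mode), `mode`.
#' @export
rarefaction_curve <- function(counts, depths, mode = c("exact", "subsample"),
                              iterations = 100L, seed = NULL) {
  mode <- match.arg(mode)
  N <- sum(counts)
  if (any(depths < 1) || any(depths != round(depths))) {
    stop("depths must be positive integers")
  }
  if (any(depths > N)) stop("rarefaction depth exceeds the sample total (", N, ")")
  x <- counts[counts > 0]
  if (mode == "exact") {
    rich <- vapply(depths, function(m) {
      sum(1 - exp(lchoose(N - x, m) - lchoose(N, m)))
    }, numeric(1))
    return(data.frame(depth = depths, richness = rich, sd = NA_real_,
                      mode = "exact", stringsAsFactors = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- rep.int(seq_along(x), x)
  res <- vapply(depths, function(m) {
    r <- vapply(seq_len(iterations), function(i) {
      length(unique(sample(pool, m)))
    }, numeric(1))
    c(mean(r), stats::sd(r))
  }, numeric(2))
  data.frame(depth = depths, richness = res[1L, ], sd = res[2L, ],
             mode = "subsample", stringsAsFactors = FALSE)
}

# positions of each sample under a permuted ordering -> per-taxon first
# (and optionally second) detection position
.taxon_index_list <- function(table) {
  B <- table > 0
  lapply(seq_len(ncol(B)), function(j) which(B[, j]))
}

#' ASV accumulation curve with sample size
#'
#' Mean and standard deviation, over random sample orderings, of the
#' richness of the union of the first k samples — plus the exact
#' expectation \eqn{E[S_k] = \sum_j [1 - \binom{n - m_j}{k}/\binom{n}{k}]}
#' over all equally likely k-subsets, which the permutation mean estimates.
#'
#' @param table Count matrix with >= 2 samples.
#' @param permutations Number of random orderings (default 999).
#' @param seed Optional RNG seed.
#' @return Data frame: `k`, `mean`, `sd`, `exact`; attributes
#'   `permutations` and `seed`. The curve at k = n equals `S_obs` exactly
#'   with sd 0.
#' @export
sample_accumulation <- function(table, permutations = 999L, seed = NULL) {
  n <- nrow(table)
  if (n < 2L) stop("accumulation needs at least two samples")
  inc <- incidence_summary(table)
  m <- inc$incidence
  ks <- seq_len(n)
  exact <- vapply(ks, function(k) {
    sum(1 - exp(lchoose(n - m, k) - lchoose(n, k)))
  }, numeric(1))

  idx <- .taxon_index_list(table[, names(m), drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  s1 <- s2 <- numeric(n)
  pos <- integer(n)
  for (p in seq_len(permutations)) {
    ord <- sample.int(n)
    pos[ord] <- ks
    first <- vapply(idx, function(ii) min(pos[ii]), numeric(1))
    rich <- cumsum(tabulate(first, nbins = n))
    s1 <- s1 + rich
    s2 <- s2 + rich^2
  }
  mn <- s1 / permutations
  vr <- pmax(0, (s2 - permutations * mn^2) / max(1, permutations - 1L))
  out <- data.frame(k = ks, mean = mn, sd = sqrt(vr), exact = exact)
  attr(out, "permutations") <- permutations
  attr(out, "seed") <- seed
  out
}

#' First-order jackknife richness extrapolation
#'
#' \deqn{S_{jack1} = S_{obs} + f_1 (n - 1) / n}
#' where f_1 is the number of taxa detected in exactly one sample. Always
#' >= S_obs, with equality iff there are no single-sample taxa.
#'
#' @param x A feature table (count matrix) or an [incidence_summary()].
#' @return The jackknife-1 estimate of the total taxon pool.
#' @examples
#' # S_obs = 5, f1 = 2, n = 3 -> 5 + 2 * 2/3
#' @export
jackknife1 <- function(x) {
  inc <- if (is.matrix(x)) incidence_summary(x) else x
  if (inc$n < 2L) stop("jackknife-1 needs at least two samples")
  inc$S_obs + inc$f[1L] * (inc$n - 1) / inc$n
}

#' Jackknife-1 pool estimates as a function of sample size
#'
#' For each subset size k (3..n), the mean and sd over random sample
#' orderings of the jackknife-1 estimate computed on the first k samples.
#' A rising curve means the pool estimate is driven by sample size —
#' each new sample contributes new single-sample taxa. The final point is
#' the exact full-table jackknife-1 with dispersion 0.
#'
#' @param table Count matrix with >= 3 samples.
#' @param permutations Number of random orderings (default 199).
#' @param seed Optional RNG seed.
#' @return Data frame: `k`, `mean`, `sd`; attributes as in
#'   [sample_accumulation()].
#' @export
pool_accumulation <- function(table, permutations = 199L, seed = NULL) {
  n <- nrow(table)
  if (n < 3L) stop("pool accumulation needs at least three samples")
  inc <- incidence_summary(table)
  idx <- .taxon_index_list(table[, names(inc$incidence), drop = FALSE])
  ks <- 3:n
  if (!is.null(seed)) set.seed(seed)
  s1 <- s2 <- numeric(length(ks))
  pos <- integer(n)
  for (p in seq_len(permutations)) {
    ord <- sample.int(n)
    pos[ord] <- seq_len(n)
    two <- vapply(idx, function(ii) {
      pp <- pos[ii]
      if (length(pp) == 1L) c(pp, n + 1L) else {
        sp <- sort.int(pp, partial = 1:2)
        sp[1:2]
      }
    }, numeric(2))
    S_k <- cumsum(tabulate(two[1L, ], nbins = n))
    S2_k <- cumsum(tabulate(two[2L, ][two[2L, ] <= n], nbins = n))
    f1_k <- S_k - S2_k
    jack <- (S_k + f1_k * (seq_len(n) - 1) / seq_len(n))[ks]
    s1 <- s1 + jack
    s2 <- s2 + jack^2
  }
  mn <- s1 / permutations
  vr <- pmax(0, (s2 - permutations * mn^2) / max(1, permutations - 1L))
  out <- data.frame(k = ks, mean = mn, sd = sqrt(vr))
  attr(out, "permutations") <- permutations
  attr(out, "seed") <- seed
  out
}

#' Percent of the predicted ASV pool detected vs sample size
#'
#' 100 * E[S_k] / S_jack1, with E[S_k] the exact accumulation expectation
#' and S_jack1 the full-table jackknife-1 pool estimate, plus the smallest
#' k at which at least 50% of the predicted pool is detected.
#'
#' @param table Count matrix with >= 3 samples.
#' @param permutations Orderings for the companion permutation mean.
#' @param seed Optional RNG seed.
#' @return List with `curve` (data frame: `k`, `pct` from the exact
#'   expectation, `pct_mean` from permutations) and `k50`.
#' @export
percent_detected <- function(table, permutations = 199L, seed = NULL) {
  if (nrow(table) < 3L) stop("percent detected needs at least three samples")
  acc <- sample_accumulation(table, permutations = permutations, seed = seed)
  pool <- jackknife1(table)
  curve <- data.frame(k = acc$k,
                      pct = 100 * acc$exact / pool,
                      pct_mean = 100 * acc$mean / pool)
  k50 <- curve$k[which(curve$pct >= 50)[1L]]
  list(curve = curve, k50 = k50, pool = pool)
}

#' Occupancy-abundance relationship
#'
#' Per-taxon occupancy (fraction of samples where detected) against mean
#' relative abundance. By default the mean is taken across all samples,
#' zeros included — the convention behind the classic triangular
#' occupancy-abundance plot; `mean_over = "occupied"` averages only over
#' samples where the taxon is present.
#'
#' @param table Count matrix with >= 1 non-empty sample.
#' @param mean_over `"all"` (default) or `"occupied"`.
#' @return Data frame: `taxon`, `occupancy`, `mean_rel_abund`.
#' @export
occupancy_abundance <- function(table, mean_over = c("all", "occupied")) {
  mean_over <- match.arg(mean_over)
  empty <- rowSums(table) == 0
  if (all(empty)) stop("occupancy-abundance needs at least one non-empty sample")
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty sample(s)")
    table <- table[!empty, , drop = FALSE]
  }
  rel <- table / rowSums(table)
  occ <- colMeans(table > 0)
  mra <- if (mean_over == "all") {
    colMeans(rel)
  } else {
    colSums(rel) / pmax(1, colSums(table > 0))
  }
  keep <- occ > 0
  data.frame(taxon = colnames(table)[keep], occupancy = occ[keep],
             mean_rel_abund = mra[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Rank-abundance curve
#'
#' Mean relative abundances (across all samples, zeros included) sorted in
#' decreasing order. The curve is non-increasing and sums to 1.
#'
#' @param table Count matrix with >= 1 non-empty sample.
#' @return Data frame: `rank`, `taxon`, `mean_rel_abund`.
#' @export
rank_abundance <- function(table) {
  oa <- occupancy_abundance(table, mean_over = "all")
  ord <- order(oa$mean_rel_abund, decreasing = TRUE)
  data.frame(rank = seq_along(ord), taxon = oa$taxon[ord],
             mean_rel_abund = oa$mean_rel_abund[ord],
             stringsAsFactors = FALSE)
}

#' Prevalence-class distributions
#'
#' Bins observed taxa by the number of samples they occur in (1, 2, ...,
#' capped at `top_class`+) and reports two proper probability vectors:
#' the dataset-level proportion of taxa in each class, and the per-sample
#' view — for each sample, the fraction of that sample's taxa falling in
#' each class, averaged over samples. The per-sample class-1 entry is the
#' mean proportion of a sample's ASVs found in no other sample.
#'
#' @param table Count matrix with at least `top_class` samples.
#' @param top_class Occupancy cap (default 8; the top class is
#'   "`top_class` or more").
#' @return List with `dataset` and `per_sample`, each a named numeric
#'   vector over classes `1 .. (top_class-1), top_class+` summing to 1.
#' @export
prevalence_class_distributions <- function(table, top_class = 8L) {
  n <- nrow(table)
  if (n < top_class) {
    stop("need at least top_class = ", top_class, " samples, got ", n)
  }
  m <- colSums(table > 0)
  obs <- m > 0
  cls <- pmin(m, top_class)
  labels <- c(as.character(seq_len(top_class - 1L)), paste0(top_class, "+"))
  dataset <- tabulate(cls[obs], nbins = top_class) / sum(obs)
  names(dataset) <- labels

  pres <- table > 0
  nonempty <- rowSums(pres) > 0
  per <- t(apply(pres[nonempty, , drop = FALSE], 1L, function(present) {
    tabulate(cls[present], nbins = top_class) / sum(present)
  }))
  per_sample <- colMeans(per)
  names(per_sample) <- labels
  list(dataset = dataset, per_sample = per_sample)
}
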