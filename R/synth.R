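#' Parameters of the synthetic ASV-table generator
#'
#' The generative model: a lognormal metacommunity of relative abundances
#' p_j (mu, sigma on the log scale, renormalized); per-cell counts
#' x_ij ~ NegativeBinomial(mean = depth_i * p_j, dispersion k), independent
#' across cells, so a taxon's occupancy has the closed form
#' occ_j = 1 - (k / (k + depth * p_j))^k — abundant taxa are near-ubiquitous,
#' rare taxa sparse, producing the classic occupancy-abundance triangle.
#' On top of that, an "individualized" fraction u of each sample's taxa is
#' injected as sample-private taxa at 1-2 reads drawn from a reserved taxon
#' pool, modeling hosts whose microbiomes carry unique strains (a
#' structural property, not extra variance).
#'
#' @param label Dataset label written into the metadata.
#' @param n_taxa Number of metacommunity taxa (>= 2).
#' @param n_samples Number of samples.
#' @param mu,sigma Log-scale location and spread of the lognormal
#'   metacommunity (sigma = 0 degenerates to equal abundances).
#' @param k Negative-binomial dispersion (shape); smaller k means lower
#'   occupancy at fixed mean abundance. Must be > 0.
#' @param depth Target reads per sample: a single value or a (min, max)
#'   range sampled uniformly per sample. Realized totals vary around the
#'   target; exact common depths are restored by rarefaction downstream.
#' @param u Expected proportion of each sample's observed taxa that are
#'   unique to that sample, in \[0, 1).
#' @param n_reserved Size of the reserved sample-private taxon pool; `NULL`
#'   auto-sizes it from the expected per-sample richness (with 60%
#'   headroom). Exhaustion at generation time is an error.
#' @param birth_rate Yule birth rate of the simulated phylogeny.
#' @param seed Integer seed; the full dataset is deterministic given the
#'   parameter set.
#' @return A `"synth_params"` list.
#' @export
synth_params <- function(label = "synthetic", n_taxa = 400L, n_samples = 50L,
                         mu = 0, sigma = 1.35, k = 0.2, depth = 20000L,
                         u = 0.08, n_reserved = NULL, birth_rate = 1,
                         seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (sigma < 0) stop("sigma must be >= 0")
  if (k <= 0) stop("dispersion k must be > 0")
  if (u < 0 || u >= 1) stop("u must be in [0, 1)")
  if (any(depth < 1)) stop("depth must be >= 1")
  if (!length(depth) %in% c(1L, 2L)) stop("depth must be a value or a (min, max) range")
  structure(list(label = label, n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples), mu = mu, sigma = sigma,
                 k = k, depth = depth, u = u,
                 n_reserved = if (is.null(n_reserved)) NULL else as.integer(n_reserved),
                 birth_rate = birth_rate, seed = as.integer(seed)),
            class = "synth_params")
}

#' Draw metacommunity relative abundances
#'
#' Lognormal(mu, sigma) abundances renormalized to sum to 1. The draw is
#' stratified: taxon j receives the quantile at (j - U_j)/n_taxa with U_j
#' uniform on (0.15, 0.85), i.e. one jittered draw per rank stratum. This
#' keeps the rank-abundance shape (and in particular the top taxon's
#' relative abundance) stable across seeds while remaining random and
#' lognormal-shaped; with sigma = 0 every taxon gets exactly 1/n_taxa.
#'
#' @param params A [synth_params()].
#' @param reseed Set the seed from `params$seed` (default `TRUE`); internal
#'   callers that manage the RNG stream pass `FALSE`.
#' @return Named vector of relative abundances summing to 1, increasing in
#'   taxon index.
#' @export
generate_metacommunity <- function(params, reseed = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  if (reseed) set.seed(params$seed)
  n <- params$n_taxa
  q <- (seq_len(n) - stats::runif(n, 0.15, 0.85)) / n
  p <- stats::qlnorm(q, meanlog = params$mu, sdlog = params$sigma)
  p <- p / sum(p)
  names(p) <- sprintf("asv%05d", seq_len(n))
  p
}

#' Simulate a Yule phylogeny over a taxon namespace
#'
#' Pure-birth topology with the corresponding exponential waiting-time
#' branch lengths (via [ape::rphylo()] with zero death rate), rooted, leaf
#' labels taken from `labels` (or `asv00001...`).
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Optional RNG seed.
#' @param birth_rate Birth rate of the Yule process.
#' @param labels Optional leaf labels (length `n_taxa`).
#' @return A rooted `"phylo"` with branch lengths and `root.edge = 0`.
#' @export
generate_tree <- function(n_taxa, seed = NULL, birth_rate = 1, labels = NULL) {
  if (n_taxa < 2) stop("a tree needs at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tr$tip.label <- if (is.null(labels)) sprintf("asv%05d", seq_len(n_taxa)) else labels
  tr$root.edge <- 0
  validate_phylogeny(tr)
}

#' Closed-form occupancy of the negative-binomial generator
#'
#' Probability that a taxon with mean per-sample count mu is detected in a
#' sample: 1 - (k / (k + mu))^k; the Poisson limit 1 - exp(-mu) as k grows.
#'
#' @param mu Expected count (depth * relative abundance).
#' @param k Negative-binomial dispersion.
#' @return Detection probability.
#' @export
nb_occupancy <- function(mu, k) {
  1 - (k / (k + mu))^k
}

#' Generate a synthetic ASV dataset
#'
#' Draws the metacommunity, samples counts cell-wise from the negative
#' binomial, injects sample-private taxa from the reserved pool, drops
#' zero-sum taxa, and builds a Yule tree over the realized taxa. The
#' number injected into sample i is ceiling(u/(1-u) * S_i) with S_i the
#' sample's pre-injection richness, so that the injected taxa make up an
#' expected fraction u of the sample's final taxon list.
#'
#' @param params A [synth_params()].
#' @return A `"synth_dataset"` list: `table` (counts, samples x taxa),
#'   `tree` (leaves = table taxa), `metadata` (sample_id, dataset_label),
#'   `truth` (per-taxon metacommunity abundance and injected flag), and
#'   `params`.
#' @export
generate_table <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  p <- generate_metacommunity(params, reseed = FALSE)
  n <- params$n_samples
  depth_i <- if (length(params$depth) == 2L) {
    round(stats::runif(n, params$depth[1L], params$depth[2L]))
  } else rep(params$depth, n)

  mu <- outer(depth_i, p)
  counts <- matrix(stats::rnbinom(length(mu), size = params$k, mu = mu),
                   nrow = n)
  sample_ids <- sprintf("%s_s%03d", params$label, seq_len(n))
  dimnames(counts) <- list(sample_ids, names(p))

  injected_cols <- NULL
  if (params$u > 0) {
    S_i <- rowSums(counts > 0)
    m_i <- ceiling(params$u / (1 - params$u) * S_i)
    need <- sum(m_i)
    n_res <- params$n_reserved
    if (is.null(n_res)) n_res <- ceiling(1.6 * params$u / (1 - params$u) * mean(S_i) * n)
    if (need > n_res) {
      stop("reserved sample-private taxon pool exhausted (need ", need,
           ", have ", n_res, "); increase n_taxa or n_reserved")
    }
    inj <- matrix(0, n, n_res,
                  dimnames = list(sample_ids,
                                  sprintf("asv%05d", params$n_taxa + seq_len(n_res))))
    nxt <- 1L
    for (i in seq_len(n)) {
      if (m_i[i] == 0L) next
      cols <- nxt:(nxt + m_i[i] - 1L)
      inj[i, cols] <- sample(1:2, m_i[i], replace = TRUE)
      nxt <- nxt + m_i[i]
    }
    injected_cols <- inj[, seq_len(nxt - 1L), drop = FALSE]
  }

  table <- cbind(counts, injected_cols)
  table <- table[, colSums(table) > 0, drop = FALSE]
  if (any(rowSums(table) == 0)) {
    # astronomically unlikely at realistic depths, but the invariant is
    # that every sample has reads
    stop("generated an empty sample; increase depth or k")
  }

  taxa <- colnames(table)
  tree <- generate_tree(length(taxa), seed = params$seed + 1L,
                        birth_rate = params$birth_rate, labels = taxa)
  truth <- data.frame(taxon = taxa,
                      meta_abundance = unname(p[taxa]),
                      injected = !(taxa %in% names(p)),
                      stringsAsFactors = FALSE)
  truth$meta_abundance[truth$injected] <- 0
  metadata <- data.frame(sample_id = rownames(table),
                         dataset_label = params$label,
                         stringsAsFactors = FALSE)
  structure(list(table = table, tree = tree, metadata = metadata,
                 truth = truth, params = params),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes `table.tsv` (samples as rows), `tree.nwk`, `metadata.tsv` and
#' `truth.tsv` under `dir`.
#'
#' @param dataset A `"synth_dataset"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- data.frame(sample_id = rownames(dataset$table), dataset$table,
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  write_tidy(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tidy(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
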