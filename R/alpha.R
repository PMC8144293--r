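#' Observed ASV richness of one sample
#'
#' @param counts Numeric vector of counts for one sample.
#' @return Number of taxa with count > 0.
#' @export
observed_richness <- function(counts) {
  sum(counts > 0)
}

#' Shannon diversity of one sample (natural log)
#'
#' H = -sum_j p_j ln p_j over taxa with positive relative abundance p_j,
#' with the convention 0 ln 0 = 0. Natural logarithms throughout, for
#' cross-study comparability.
#'
#' @param counts Numeric vector of counts for one sample; must contain at
#'   least one positive count.
#' @return Shannon entropy in nats.
#' @examples shannon(c(1, 1)) # log(2)
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("Shannon diversity is undefined for an empty sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the tree connecting all taxa present in a
#' sample, up to and including the root: every edge whose descendant mass
#' is positive contributes its full length, plus the root edge (which
#' defaults to length 0). This is the rooted-tree convention; unrooted
#' variants that exclude the root path will differ.
#'
#' @param counts Named count vector for one sample (names are tree leaves).
#' @param tree Rooted `"phylo"` with branch lengths.
#' @return Faith's PD.
#' @export
faith_pd <- function(counts, tree) {
  if (sum(counts) <= 0) stop("Faith's PD is undefined for an empty sample")
  em <- edge_masses(counts, tree)
  sum(em$length[em$mass > 0]) + attr(em, "root_edge")
}

#' Balance-weighted phylogenetic diversity (BWPD)
#'
#' One-parameter abundance-weighted extension of Faith's PD:
#' \deqn{BWPD_\theta = \sum_e \ell_e (2 \min(p_e, 1 - p_e))^\theta}
#' where p_e is the descendant relative-abundance mass of edge e. Edges
#' with all or none of the sample's abundance below them (p_e in {0, 1})
#' never contribute, by the convention 0^0 = 0; consequently a sample with
#' a single taxon has BWPD = 0 for every theta. theta = 0 counts the full
#' length of every "mixed" edge; theta = 1 is fully abundance-weighted;
#' the default theta = 0.5 balances the two regimes.
#'
#' @param counts Named count vector for one sample.
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param theta Balance exponent in \[0, 1\]; default 0.5.
#' @return BWPD_theta.
#' @export
bwpd <- function(counts, tree, theta = 0.5) {
  if (length(theta) != 1L || !is.finite(theta) || theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]")
  }
  if (sum(counts) <= 0) stop("BWPD is undefined for an empty sample")
  em <- edge_masses(counts, tree)
  w <- .bwpd_weight(em$mass)
  sum(em$length[w > 0] * w[w > 0]^theta)
}

# balance weight 2 min(p, 1-p); accumulated float error can leave an edge
# that carries the whole sample at p = 1 - 1e-16, and w^theta would amplify
# that noise, so weights within 1e-12 of a pure edge are snapped to zero
.bwpd_weight <- function(mass) {
  w <- pmax(2 * pmin(mass, 1 - mass), 0)
  w[w < 1e-12] <- 0
  w
}

#' Alpha diversity of every sample in a table
#'
#' Batch version of the scalar alpha measures, sharing one edge-mass
#' computation across samples. Samples with zero total count get `NA`
#' scores (the scalar functions raise errors instead; in a sweep a missing
#' score must propagate rather than halt).
#'
#' @param table Count matrix, samples as rows.
#' @param tree Rooted `"phylo"`; required for `faith_pd` and `bwpd`.
#' @param metrics Character vector from `"observed_richness"`,
#'   `"shannon"`, `"faith_pd"`, `"bwpd"`.
#' @param theta BWPD balance exponent.
#' @return Long data frame: `sample`, `metric`, `score`.
#' @export
alpha_diversity <- function(table, tree = NULL,
                            metrics = c("observed_richness", "shannon",
                                        "faith_pd", "bwpd"),
                            theta = 0.5) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  needs_tree <- any(metrics %in% c("faith_pd", "bwpd"))
  if (needs_tree && is.null(tree)) stop("phylogenetic alpha metrics require a tree")
  empty <- rowSums(table) == 0
  out <- list()
  if (needs_tree) {
    tree <- validate_phylogeny(tree)
    km <- edge_mass_kernel(.rel_abund(table), tree)
  }
  for (m in metrics) {
    score <- switch(m,
      observed_richness = rowSums(table > 0),
      shannon = apply(table, 1L, function(x) {
        if (sum(x) <= 0) return(NA_real_)
        p <- x[x > 0] / sum(x)
        -sum(p * log(p))
      }),
      faith_pd = as.vector((km$mass > 0) %*% km$length) + km$root_edge,
      bwpd = {
        w <- .bwpd_weight(km$mass)
        wt <- w^theta
        wt[w == 0] <- 0 # 0^0 == 0 convention: p_e in {0,1} never contributes
        as.vector(wt %*% km$length)
      })
    score[empty] <- NA_real_
    out[[m]] <- data.frame(sample = rownames(table), metric = m,
                           score = as.numeric(score),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
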