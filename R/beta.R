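#' Jaccard dissimilarity between two samples
#'
#' 1 - |A intersect B| / |A union B| on presence sets, in \[0, 1\].
#'
#' @param x,y Count vectors over the same taxa.
#' @return Jaccard dissimilarity.
#' @export
jaccard <- function(x, y) {
  .check_pair(x, y)
  m <- .pair_table(x, y)
  a <- m[1L, ] > 0
  b <- m[2L, ] > 0
  1 - sum(a & b) / sum(a | b)
}

#' Morisita dissimilarity between two samples (integer counts)
#'
#' Morisita's similarity
#' \deqn{C = \frac{2 \sum_j x_j y_j}{(\lambda_x + \lambda_y) X Y}, \quad
#'       \lambda_x = \frac{\sum_j x_j (x_j - 1)}{X (X - 1)}}
#' with X, Y the sample totals. The dissimilarity 1 - C can be slightly
#' negative for identical low-count samples (C can exceed 1), so by default
#' it is clamped at 0 to respect the \[0, 1\] beta-dissimilarity range;
#' `clamp = FALSE` returns the unclamped value for cross-checks against
#' other implementations. The formula's x(x-1) term requires integer
#' counts and totals of at least 2 in each sample.
#'
#' @param x,y Integer count vectors over the same taxa.
#' @param clamp Clamp the dissimilarity at 0 (default `TRUE`).
#' @return Morisita dissimilarity.
#' @export
morisita <- function(x, y, clamp = TRUE) {
  if (any(x != round(x)) || any(y != round(y))) {
    stop("Morisita requires integer counts")
  }
  X <- sum(x)
  Y <- sum(y)
  if (X < 2 || Y < 2) stop("Morisita is undefined for sample totals < 2")
  lx <- sum(x * (x - 1)) / (X * (X - 1))
  ly <- sum(y * (y - 1)) / (Y * (Y - 1))
  if (lx + ly == 0) {
    warning("Morisita undefined: both samples have zero dispersion (all counts <= 1)")
    return(NA_real_)
  }
  m <- .pair_table(x, y)
  C <- 2 * sum(m[1L, ] * m[2L, ]) / ((lx + ly) * X * Y)
  d <- 1 - C
  if (clamp) max(0, d) else d
}

#' Bray-Curtis dissimilarity between two samples
#'
#' sum |x_j - y_j| / sum (x_j + y_j). Provided for the redundancy check
#' that Bray-Curtis is almost perfectly rank-correlated with Jaccard on
#' these data; it is not part of the default sweep metric set.
#'
#' @param x,y Count vectors over the same taxa.
#' @return Bray-Curtis dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  .check_pair(x, y)
  m <- .pair_table(x, y)
  sum(abs(m[1L, ] - m[2L, ])) / sum(m)
}

#' Unweighted UniFrac dissimilarity
#'
#' Fraction of branch length unique to one of the two communities:
#' (sum of l_e over edges whose descendant mass is positive in exactly one
#' sample) / (sum of l_e over edges positive in at least one). The root
#' edge (mass 1 in both non-empty samples) is shared by construction.
#'
#' @param x,y Named count vectors over the same taxa (tree leaves).
#' @param tree Rooted `"phylo"` with branch lengths.
#' @return Unweighted UniFrac in \[0, 1\].
#' @export
unweighted_unifrac <- function(x, y, tree) {
  .check_pair(x, y)
  tree <- validate_phylogeny(tree)
  km <- edge_mass_kernel(.rel_abund(.pair_table(x, y)), tree)
  inx <- km$mass[1L, ] > 0
  iny <- km$mass[2L, ] > 0
  unique_len <- sum(km$length[xor(inx, iny)])
  union_len <- sum(km$length[inx | iny]) + km$root_edge
  unique_len / union_len
}

#' Weighted UniFrac dissimilarity
#'
#' Raw form: sum_e l_e |p_e^x - p_e^y| over edge descendant masses of the
#' two samples. The normalized form (default) divides by
#' sum_e l_e (p_e^x + p_e^y), which bounds the score in \[0, 1\] so beta
#' scores remain comparable across trees.
#'
#' @param x,y Named count vectors over the same taxa (tree leaves).
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param normalized Return the normalized form (default `TRUE`).
#' @return Weighted UniFrac dissimilarity.
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  .check_pair(x, y)
  tree <- validate_phylogeny(tree)
  km <- edge_mass_kernel(.rel_abund(.pair_table(x, y)), tree)
  raw <- sum(km$length * abs(km$mass[1L, ] - km$mass[2L, ]))
  if (!normalized) return(raw)
  denom <- sum(km$length * (km$mass[1L, ] + km$mass[2L, ])) + 2 * km$root_edge
  raw / denom
}

.check_pair <- function(x, y) {
  if (sum(x) <= 0 && sum(y) <= 0) {
    stop("dissimilarity is undefined when both samples are empty")
  }
  invisible(NULL)
}

# align two count vectors into a 2-row matrix; named vectors are joined
# over the union of their names (absences are zeros), unnamed vectors must
# have equal length
.pair_table <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    taxa <- union(names(x), names(y))
    m <- matrix(0, 2L, length(taxa), dimnames = list(c("x", "y"), taxa))
    m["x", names(x)] <- x
    m["y", names(y)] <- y
    m
  } else {
    if (length(x) != length(y)) stop("samples must cover the same taxa")
    rbind(x = x, y = y)
  }
}

#' Pairwise beta-dissimilarity matrix
#'
#' Computes the full symmetric zero-diagonal dissimilarity matrix over all
#' sample pairs of a table, using vectorized forms of the scalar measures
#' (a shared edge-mass matrix for the UniFracs; cross-product identities
#' for Jaccard and Morisita). Samples with zero total count are excluded
#' with a warning, since every measure is undefined or degenerate there.
#'
#' @param table Count matrix, samples as rows.
#' @param tree Rooted `"phylo"`; required for the UniFrac measures.
#' @param metric One of `"jaccard"`, `"morisita"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param normalized Normalized weighted UniFrac (default `TRUE`).
#' @param clamp Clamp Morisita at 0 (default `TRUE`).
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_matrix <- function(table, tree = NULL,
                            metric = c("jaccard", "morisita", "bray_curtis",
                                       "unweighted_unifrac", "weighted_unifrac"),
                            normalized = TRUE, clamp = TRUE) {
  metric <- match.arg(metric)
  empty <- rowSums(table) == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty sample(s) from the ", metric,
            " matrix: ", paste(rownames(table)[empty], collapse = ", "))
    table <- table[!empty, , drop = FALSE]
  }
  n <- nrow(table)
  if (n < 2L) stop("need at least two non-empty samples")
  ids <- rownames(table)

  D <- switch(metric,
    jaccard = {
      B <- (table > 0) * 1
      inter <- tcrossprod(B)
      pres <- rowSums(B)
      union <- outer(pres, pres, "+") - inter
      1 - inter / union
    },
    morisita = {
      if (any(table != round(table))) stop("Morisita requires integer counts")
      X <- rowSums(table)
      if (any(X < 2)) stop("Morisita is undefined for sample totals < 2")
      lam <- rowSums(table * (table - 1)) / (X * (X - 1))
      cross <- tcrossprod(table)
      C <- 2 * cross / (outer(lam, lam, "+") * outer(X, X))
      d <- 1 - C
      if (clamp) d <- pmax(d, 0)
      d
    },
    bray_curtis = {
      tot <- rowSums(table)
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        xi <- table[i, ]
        for (j in (i + 1L):n) {
          d[i, j] <- d[j, i] <- sum(abs(xi - table[j, ])) / (tot[i] + tot[j])
        }
      }
      d
    },
    unweighted_unifrac = {
      km <- .require_tree_kernel(table, tree)
      B <- (km$mass > 0) * 1
      shared <- tcrossprod(B * rep(sqrt(km$length), each = n)) + km$root_edge
      len <- as.vector(B %*% km$length) + km$root_edge
      union <- outer(len, len, "+") - shared
      (outer(len, len, "+") - 2 * shared) / union
    },
    weighted_unifrac = {
      km <- .require_tree_kernel(table, tree)
      E <- km$mass
      l <- km$length
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) {
        ei <- E[i, ]
        for (j in (i + 1L):n) {
          d[i, j] <- d[j, i] <- sum(l * abs(ei - E[j, ]))
        }
      }
      if (normalized) {
        depth <- as.vector(E %*% l) + km$root_edge
        d <- d / outer(depth, depth, "+")
      }
      d
    })
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

.require_tree_kernel <- function(table, tree) {
  if (is.null(tree)) stop("UniFrac measures require a tree")
  km <- edge_mass_kernel(.rel_abund(table), validate_phylogeny(tree))
  # edges with zero mass in every sample contribute nothing to any UniFrac
  # term; dropping them keeps the pair loops proportional to occupied edges
  live <- colSums(km$mass) > 0
  km$mass <- km$mass[, live, drop = FALSE]
  km$length <- km$length[live]
  km
}

#' Mean dissimilarity of each sample to all others
#'
#' For sample i, the mean of d(i, j) over all j != i; the per-individual
#' beta score carried through the prevalence sweep.
#'
#' @param mat Symmetric dissimilarity matrix with >= 2 samples.
#' @return Named numeric vector of per-sample means.
#' @export
mean_dissimilarity_per_sample <- function(mat) {
  n <- nrow(mat)
  if (is.null(n) || n < 2L) stop("mean dissimilarity needs at least two samples")
  rowSums(mat) / (n - 1L)
}

#' Write a dissimilarity matrix as square TSV
#' @param mat Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a dissimilarity matrix to long format (i, j, value)
#' @param mat Symmetric matrix with dimnames.
#' @param metric Metric name recorded in the output.
#' @return Data frame of the upper triangle: `i`, `j`, `metric`, `value`.
#' @export
matrix_to_long <- function(mat, metric = "dissimilarity") {
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  data.frame(i = rownames(mat)[ut[, 1L]], j = colnames(mat)[ut[, 2L]],
             metric = metric, value = mat[ut], stringsAsFactors = FALSE)
}
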