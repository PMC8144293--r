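# naive reference implementations, written as direct transcriptions of the
# defining formulas (explicit loops over edges and presence sets), kept
# deliberately independent of the package's edge-mass kernel

# descendant leaf set of every edge, by recursion over the edge list
edge_leaf_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below), use.names = FALSE)
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below(tree$edge[e, 2L]))
}

oracle_edge_mass <- function(p, tree) {
  sets <- edge_leaf_sets(tree)
  vapply(sets, function(s) sum(p[names(p) %in% s]), numeric(1))
}

oracle_shannon <- function(x) {
  p <- x / sum(x)
  h <- 0
  for (pj in p) if (pj > 0) h <- h - pj * log(pj)
  h
}

oracle_faith <- function(x, tree) {
  mass <- oracle_edge_mass(x / sum(x), tree)
  sum(tree$edge.length[mass > 0]) +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
}

oracle_bwpd <- function(x, tree, theta = 0.5) {
  mass <- oracle_edge_mass(x / sum(x), tree)
  tot <- 0
  for (e in seq_along(mass)) {
    w <- 2 * min(mass[e], 1 - mass[e])
    # same pure-edge snap as the implementation: float error can leave the
    # full-mass edge at p = 1 - 1e-16
    if (w > 1e-12) tot <- tot + tree$edge.length[e] * w^theta
  }
  tot
}

oracle_jaccard <- function(x, y) {
  A <- names(x)[x > 0]
  B <- names(y)[y > 0]
  1 - length(intersect(A, B)) / length(union(A, B))
}

oracle_morisita <- function(x, y, clamp = TRUE) {
  X <- sum(x); Y <- sum(y)
  lx <- sum(x * (x - 1)) / (X * (X - 1))
  ly <- sum(y * (y - 1)) / (Y * (Y - 1))
  C <- 2 * sum(x * y) / ((lx + ly) * X * Y)
  if (clamp) max(0, 1 - C) else 1 - C
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_unweighted_unifrac <- function(x, y, tree) {
  mx <- oracle_edge_mass(x / sum(x), tree)
  my <- oracle_edge_mass(y / sum(y), tree)
  num <- den <- 0
  for (e in seq_along(mx)) {
    inx <- mx[e] > 0; iny <- my[e] > 0
    if (xor(inx, iny)) num <- num + tree$edge.length[e]
    if (inx || iny) den <- den + tree$edge.length[e]
  }
  den <- den + (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  num / den
}

oracle_weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  mx <- oracle_edge_mass(x / sum(x), tree)
  my <- oracle_edge_mass(y / sum(y), tree)
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  num <- sum(tree$edge.length * abs(mx - my))
  if (!normalized) return(num)
  num / (sum(tree$edge.length * (mx + my)) + 2 * re)
}

# independent transcriptions of the test statistics
oracle_bartlett <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  si2 <- vapply(groups, stats::var, numeric(1))
  N <- sum(ni)
  sp2 <- sum((ni - 1) * si2) / (N - k)
  K2 <- ((N - k) * log(sp2) - sum((ni - 1) * log(si2)))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  K2 <- K2 / C
  list(statistic = K2, df = k - 1,
       p.value = stats::pchisq(K2, k - 1, lower.tail = FALSE))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(estimate = rho, p.value = 2 * stats::pt(-abs(tstat), n - 2))
}
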