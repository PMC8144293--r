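#' Edge descendant-mass kernel
#'
#' Every phylogenetic measure in the package (Faith's PD, BWPD, both
#' UniFracs) reduces to per-edge descendant masses: for each edge e of a
#' rooted tree, p_e is the total relative abundance of the taxa in the
#' subtree below e. One post-order accumulation over the edge list computes
#' all masses in time linear in tree size, vectorized across samples.
#'
#' @param P Matrix of per-sample relative abundances (samples as rows,
#'   columns named by taxa; taxa must be tree leaves). Leaves absent from
#'   `P` carry zero mass.
#' @param tree A validated rooted `"phylo"` with branch lengths.
#' @return A list with `mass` (samples x edges matrix; column j is the edge
#'   in row j of the postorder edge matrix), `length` (edge lengths in the
#'   same order), `root_edge` (root edge length; its mass is the row sum of
#'   `P`, i.e. 1 for complete non-empty samples), and `edge` (the postorder
#'   edge matrix).
#' @keywords internal
edge_mass_kernel <- function(P, tree) {
  taxa <- colnames(P)
  bad <- setdiff(taxa, tree$tip.label)
  if (length(bad) > 0L) {
    stop("taxa not found among tree leaves: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  tre <- stats::reorder(tree, "postorder")
  ntip <- length(tre$tip.label)
  nnode <- ntip + tre$Nnode
  n <- nrow(P)
  M <- matrix(0, n, nnode)
  M[, match(taxa, tre$tip.label)] <- P
  e <- tre$edge
  for (r in seq_len(nrow(e))) {
    M[, e[r, 1L]] <- M[, e[r, 1L]] + M[, e[r, 2L]]
  }
  list(mass = M[, e[, 2L], drop = FALSE],
       length = tre$edge.length,
       root_edge = if (is.null(tre$root.edge)) 0 else tre$root.edge,
       edge = e)
}

#' Per-edge descendant masses for one sample
#'
#' @param sample Named vector of counts or relative abundances for one
#'   sample; names must be tree leaves. Counts are normalized to relative
#'   abundances internally.
#' @param tree A rooted `"phylo"` with branch lengths.
#' @return Data frame with one row per edge: `parent`, `child` (node ids),
#'   `length`, and descendant `mass`; plus attributes `root_edge` and
#'   `root_mass`.
#' @examples
#' tree <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
#' edge_masses(c(A = 1, B = 1), tree)
#' @export
edge_masses <- function(sample, tree) {
  tree <- validate_phylogeny(tree)
  if (is.null(names(sample))) stop("sample must be a named vector of abundances")
  tot <- sum(sample)
  p <- if (tot > 0) sample / tot else sample
  km <- edge_mass_kernel(matrix(p, 1L, dimnames = list("s", names(p))), tree)
  out <- data.frame(parent = km$edge[, 1L], child = km$edge[, 2L],
                    length = km$length, mass = km$mass[1L, ])
  attr(out, "root_edge") <- km$root_edge
  attr(out, "root_mass") <- sum(p)
  out
}

# relative abundances per row; zero-sum rows stay zero
.rel_abund <- function(x) {
  tot <- rowSums(x)
  tot[tot == 0] <- 1
  x / tot
}
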