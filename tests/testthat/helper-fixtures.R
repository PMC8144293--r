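# shared fixtures, built in code

# the 4-leaf example tree used throughout the hand-worked metric examples
tree4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1):0;")

star_tree <- function(taxa) {
  read_newick(text = paste0("(", paste0(taxa, ":1", collapse = ","), "):0;"))
}

random_table <- function(n_samples, n_taxa, lambda = 2, seed = NULL,
                         prefix = "t") {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("%s%02d", prefix, seq_len(n_taxa))))
    if (all(rowSums(m) >= 2) && all(colSums(m) > 0)) return(m)
  }
}

random_tree_for <- function(table, seed = NULL) {
  generate_tree(ncol(table), seed = seed, labels = colnames(table))
}

# one small synthetic dataset reused across pipeline tests
small_synth <- function(seed = 101, u = 0.2, n_samples = 20) {
  generate_table(synth_params(label = "small", n_taxa = 150,
                              n_samples = n_samples, sigma = 1.2, k = 0.3,
                              depth = 3000, u = u, seed = seed))
}
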