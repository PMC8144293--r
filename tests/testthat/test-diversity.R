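test_that("edge masses satisfy conservation and the hand-worked cases", {
  tr <- tree4()
  em <- edge_masses(c(A = 1), tr)
  on_path <- em$mass[em$mass > 0]
  expect_equal(sort(on_path), c(1, 1)) # leaf edge + its parent edge
  expect_equal(sum(em$mass > 0), 2)

  em2 <- edge_masses(c(A = 1, B = 1), tr)
  expect_equal(sort(em2$mass[em2$mass > 0]), c(0.5, 0.5, 1))

  em3 <- edge_masses(c(A = 1, B = 1, C = 1, D = 1), tr)
  expect_equal(sort(unique(em3$mass)), c(0.25, 0.5))

  # conservation: masses entering the root sum to 1 for any random sample
  set.seed(5)
  for (i in 1:20) {
    tree <- generate_tree(sample(3:16, 1), seed = i)
    p <- stats::runif(length(tree$tip.label))
    p <- p / sum(p)
    names(p) <- tree$tip.label
    em <- edge_masses(p, tree)
    root <- setdiff(em$parent, em$child)
    expect_equal(sum(em$mass[em$parent == root]), 1, tolerance = 1e-12)
  }
})

test_that("alpha measures match their closed-form examples", {
  tr <- tree4()
  expect_equal(observed_richness(c(3, 0, 1, 2)), 3)
  expect_equal(observed_richness(c(0, 0)), 0)

  expect_equal(shannon(c(1, 1)), log(2))
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon(c(0, 0)), "empty")

  expect_equal(faith_pd(c(A = 1, B = 1), tr), 3)
  expect_equal(faith_pd(c(A = 7), tr), 2)
  expect_equal(faith_pd(c(A = 1, B = 1, C = 1, D = 1), tr), 6)
  expect_error(faith_pd(c(A = 0), tr), "empty")

  for (theta in c(0, 0.25, 0.5, 1)) {
    expect_equal(bwpd(c(A = 1, B = 1), tr, theta), 2)
    expect_equal(bwpd(c(C = 9), tr, theta), 0) # single taxon, all theta
  }
  expect_equal(bwpd(c(A = 1, B = 1, C = 1, D = 1), tr, theta = 1),
               4 * (2 * 0.25) + 2 * (2 * 0.5))
  expect_error(bwpd(c(A = 1), tr, theta = 1.2), "theta")
})

test_that("beta measures match their hand-worked examples", {
  tr <- tree4()
  x <- c(a = 1, b = 1, c = 1, d = 0)
  y <- c(a = 0, b = 1, c = 1, d = 1)
  expect_equal(jaccard(x, y), 0.5)
  expect_equal(jaccard(x, x), 0)
  expect_equal(jaccard(c(a = 1, b = 0), c(a = 0, b = 1)), 1)

  expect_equal(morisita(c(5, 0), c(0, 5)), 1)
  expect_equal(morisita(c(10, 10), c(10, 10)), 0)
  expect_equal(morisita(c(10, 10), c(10, 10), clamp = FALSE), 1 - 380 / 360)
  expect_error(morisita(c(1.5, 1), c(1, 1)), "integer")
  expect_error(morisita(c(1, 0), c(3, 3)), "totals")

  expect_equal(bray_curtis(c(2, 2), c(2, 0)), 1 / 3)
  expect_equal(bray_curtis(x, x), 0)
  expect_equal(bray_curtis(c(2, 0), c(0, 7)), 1)

  expect_equal(unweighted_unifrac(c(A = 1), c(B = 1), tr), 2 / 3)
  expect_equal(unweighted_unifrac(c(A = 1, B = 1), c(C = 1, D = 1), tr), 1)
  expect_equal(unweighted_unifrac(c(A = 2, C = 1), c(A = 2, C = 1), tr), 0)

  expect_equal(weighted_unifrac(c(A = 1), c(B = 1), tr, normalized = FALSE), 2)
  expect_equal(weighted_unifrac(c(A = 1), c(B = 1), tr), 0.5)
  expect_equal(weighted_unifrac(c(A = 3, D = 1), c(A = 3, D = 1), tr), 0)

  expect_error(jaccard(c(a = 0), c(a = 0)), "empty")
})

test_that("star tree collapses phylogeny-weighting: PD = richness, UU = Jaccard", {
  set.seed(8)
  taxa <- sprintf("t%02d", 1:12)
  star <- star_tree(taxa)
  for (i in 1:10) {
    x <- stats::rpois(12, 1)
    y <- stats::rpois(12, 1)
    names(x) <- names(y) <- taxa
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(faith_pd(x, star), observed_richness(x))
    expect_equal(unweighted_unifrac(x, y, star), jaccard(x, y))
  }
})

test_that("all measures agree with naive reimplementations on random instances", {
  set.seed(42)
  for (i in 1:25) {
    nt <- sample(3:16, 1)
    ns <- sample(2:8, 1)
    tb <- random_table(ns, nt, lambda = stats::runif(1, 0.5, 3))
    tree <- random_tree_for(tb, seed = 1000 + i)
    x <- tb[1, ]
    y <- tb[2, ]
    expect_equal(shannon(x), oracle_shannon(x), tolerance = 1e-9)
    expect_equal(faith_pd(x, tree), oracle_faith(x, tree), tolerance = 1e-9)
    th <- stats::runif(1)
    expect_equal(bwpd(x, tree, th), oracle_bwpd(x, tree, th), tolerance = 1e-9)
    expect_equal(jaccard(x, y), oracle_jaccard(x, y), tolerance = 1e-9)
    if (sum(x * (x - 1)) + sum(y * (y - 1)) > 0) { # else Morisita undefined
      expect_equal(morisita(x, y), oracle_morisita(x, y), tolerance = 1e-9)
    }
    expect_equal(bray_curtis(x, y), oracle_bray(x, y), tolerance = 1e-9)
    expect_equal(unweighted_unifrac(x, y, tree),
                 oracle_unweighted_unifrac(x, y, tree), tolerance = 1e-9)
    expect_equal(weighted_unifrac(x, y, tree),
                 oracle_weighted_unifrac(x, y, tree), tolerance = 1e-9)
    expect_equal(weighted_unifrac(x, y, tree, normalized = FALSE),
                 oracle_weighted_unifrac(x, y, tree, normalized = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("measures agree with the ecology packages' implementations", {
  skip_if_not_installed("vegan")
  skip_if_not_installed("picante")
  set.seed(9)
  tb <- random_table(6, 14, lambda = 1.5)
  tree <- random_tree_for(tb, seed = 77)

  vd <- as.matrix(vegan::vegdist(tb, method = "bray"))
  expect_equal(pairwise_matrix(tb, metric = "bray_curtis"), vd,
               tolerance = 1e-9, ignore_attr = TRUE)

  vj <- as.matrix(vegan::vegdist(tb, method = "jaccard", binary = TRUE))
  expect_equal(pairwise_matrix(tb, metric = "jaccard"), vj,
               tolerance = 1e-9, ignore_attr = TRUE)

  # vegan also floors Morisita dissimilarity at zero, so the clamped form
  # is the comparable one
  vm <- as.matrix(vegan::vegdist(tb, method = "morisita"))
  expect_equal(pairwise_matrix(tb, metric = "morisita"), vm,
               tolerance = 1e-9, ignore_attr = TRUE)

  pd <- picante::pd(tb, tree, include.root = TRUE)
  mine <- alpha_diversity(tb, tree, metrics = "faith_pd")
  expect_equal(mine$score, pd$PD, tolerance = 1e-9)
})

test_that("UniFrac matches phyloseq on a small community", {
  skip_if_not_installed("phyloseq")
  set.seed(12)
  tb <- random_table(5, 10, lambda = 1.5)
  tree <- random_tree_for(tb, seed = 55)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tb, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tree))
  uu <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  wu <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ids <- rownames(tb)
  expect_equal(pairwise_matrix(tb, tree, "unweighted_unifrac")[ids, ids],
               uu[ids, ids], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(pairwise_matrix(tb, tree, "weighted_unifrac")[ids, ids],
               wu[ids, ids], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("pairwise matrices are symmetric, bounded, and match the scalar ops", {
  set.seed(21)
  tb <- random_table(5, 12, lambda = 1.2)
  tree <- random_tree_for(tb, seed = 31)
  scalar <- list(
    jaccard = function(i, j) jaccard(tb[i, ], tb[j, ]),
    morisita = function(i, j) morisita(tb[i, ], tb[j, ]),
    bray_curtis = function(i, j) bray_curtis(tb[i, ], tb[j, ]),
    unweighted_unifrac = function(i, j) unweighted_unifrac(tb[i, ], tb[j, ], tree),
    weighted_unifrac = function(i, j) weighted_unifrac(tb[i, ], tb[j, ], tree))
  for (m in names(scalar)) {
    D <- pairwise_matrix(tb, tree, metric = m)
    expect_true(isSymmetric(D))
    expect_equal(unname(diag(D)), rep(0, nrow(tb)))
    expect_true(all(D >= 0 & D <= 1 + 1e-12))
    for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
      expect_equal(D[pair[1], pair[2]], scalar[[m]](pair[1], pair[2]),
                   tolerance = 1e-12)
    }
  }
  # identical samples give an all-zero matrix
  same <- tb[c(1, 1, 1), , drop = FALSE]
  rownames(same) <- c("a", "b", "c")
  expect_equal(max(pairwise_matrix(same, metric = "jaccard")), 0)
  # empty samples are excluded with a warning
  tb2 <- rbind(tb, empty = 0)
  expect_warning(D2 <- pairwise_matrix(tb2, metric = "jaccard"), "empty")
  expect_false("empty" %in% rownames(D2))
})

test_that("mean per-sample dissimilarity averages over the off-diagonal", {
  m <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.4, 0.6, 0.4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(mean_dissimilarity_per_sample(m)), c(0.4, 0.3, 0.5))
  two <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(mean_dissimilarity_per_sample(two)), c(0.4, 0.4))
  expect_error(mean_dissimilarity_per_sample(matrix(0, 1, 1)), "two samples")
})

test_that("Bray-Curtis tracks Jaccard in the sparse presence-dominated regime", {
  # the redundancy between the two arises when most non-zero counts are
  # minimal, so that abundance differences reduce to presence differences;
  # with purely independent samples (no host-level compositional signal)
  # the association stays well below what correlated real communities show
  ds <- generate_table(synth_params(label = "sparse", n_taxa = 1500,
                                    n_samples = 30, sigma = 0.5, k = 1,
                                    depth = 800, u = 0.1, seed = 301))
  tb <- ds$table
  bc <- pairwise_matrix(tb, metric = "bray_curtis")
  jc <- pairwise_matrix(tb, metric = "jaccard")
  rho <- stats::cor(bc[upper.tri(bc)], jc[upper.tri(jc)], method = "spearman")
  expect_gt(rho, 0.6)
})
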