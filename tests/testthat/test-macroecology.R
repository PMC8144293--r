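test_that("incidence summary books occupancy correctly", {
  tb <- rbind(s1 = c(t1 = 1, t2 = 0, t3 = 2, t4 = 0),
              s2 = c(3, 0, 1, 0),
              s3 = c(0, 0, 4, 0))
  colnames(tb) <- paste0("t", 1:4)
  inc <- incidence_summary(tb)
  expect_equal(inc$S_obs, 2)
  expect_equal(unname(inc$incidence), c(2, 3))
  expect_equal(inc$f, c(0, 1, 1))
  expect_equal(sum(inc$f), inc$S_obs)
  expect_equal(unname(inc$occupancy), c(2 / 3, 1))
})

test_that("exact rarefaction matches endpoints, vegan, and Monte Carlo", {
  x <- c(50, 30, 5, 1, 14)
  N <- sum(x)
  rc <- rarefaction_curve(x, c(1, 10, 50, N))
  expect_equal(rc$richness[1], 1)
  expect_equal(rc$richness[4], 5)
  expect_true(all(diff(rc$richness) > 0))
  skip_if_not_installed("vegan")
  expect_equal(rc$richness,
               as.numeric(vegan::rarefy(matrix(x, 1), sample = c(1, 10, 50, N))),
               tolerance = 1e-10)

  # closed form vs seeded subsampling (3 SE of the Monte-Carlo mean)
  mc <- rarefaction_curve(c(50, 50), 10, mode = "subsample",
                          iterations = 10000, seed = 1)
  ex <- rarefaction_curve(c(50, 50), 10)$richness
  expect_lt(abs(mc$richness - ex), 3 * mc$sd / sqrt(10000))

  expect_equal(rarefaction_curve(c(50, 50), 100, mode = "subsample",
                                 iterations = 5, seed = 1)$richness, 2)
  expect_error(rarefaction_curve(x, N + 1), "exceeds")
})

test_that("sample accumulation: exact expectation, permutations, endpoints", {
  # low occupancy so no subset size saturates and the 3 SE band is meaningful
  set.seed(3)
  tb <- matrix(stats::rpois(10 * 60, 0.25), 10, 60,
               dimnames = list(sprintf("s%02d", 1:10), sprintf("t%02d", 1:60)))
  tb <- tb[, colSums(tb) > 0]
  sa <- sample_accumulation(tb, permutations = 999, seed = 1)
  S <- sum(colSums(tb) > 0)
  n <- nrow(tb)
  expect_equal(sa$mean[n], S)
  expect_equal(sa$sd[n], 0)
  expect_equal(sa$exact[n], S, tolerance = 1e-12)
  expect_true(all(diff(sa$exact) > -1e-12))
  expect_true(all(diff(sa$mean) > -1e-12))

  inside <- abs(sa$mean - sa$exact)[-n] <= 3 * (sa$sd / sqrt(999))[-n]
  expect_true(all(inside))

  skip_if_not_installed("vegan")
  ve <- vegan::specaccum(tb, method = "exact")
  expect_equal(sa$exact, as.numeric(ve$richness), tolerance = 1e-9)

  # every taxon in every sample -> flat curve
  flat <- matrix(1, 4, 7, dimnames = list(paste0("s", 1:4), paste0("t", 1:7)))
  sf <- sample_accumulation(flat, permutations = 9, seed = 1)
  expect_equal(sf$mean, rep(7, 4))
  expect_equal(sf$exact, rep(7, 4))
})

test_that("jackknife-1 follows its formula and vegan's specpool", {
  expect_equal(jackknife1(list(n = 3, S_obs = 5, f = c(2, 0, 0))), 5 + 2 * 2 / 3)
  expect_equal(jackknife1(list(n = 4, S_obs = 9, f = c(0, 3, 1, 5))), 9)
  # n -> large with fixed f1 approaches S_obs + f1
  expect_equal(jackknife1(list(n = 1e6, S_obs = 10, f = c(4, rep(0, 5)))),
               14, tolerance = 1e-5)
  expect_error(jackknife1(list(n = 1, S_obs = 2, f = 2)), "two samples")

  set.seed(4)
  tb <- random_table(8, 30, lambda = 0.4)
  skip_if_not_installed("vegan")
  expect_equal(jackknife1(tb), vegan::specpool(tb)$jack1, tolerance = 1e-9)
  expect_gte(jackknife1(tb), incidence_summary(tb)$S_obs)
})

test_that("pool accumulation tracks jackknife-1 across subset sizes", {
  # no singletons at any subset size: every taxon in every sample
  flat <- matrix(2, 5, 6, dimnames = list(paste0("s", 1:5), paste0("t", 1:6)))
  pf <- pool_accumulation(flat, permutations = 19, seed = 1)
  expect_equal(pf$mean, rep(6, 3))
  expect_equal(pf$sd, rep(0, 3))

  ds <- small_synth(seed = 77, u = 0.35)
  pa <- pool_accumulation(ds$table, permutations = 49, seed = 2)
  n <- nrow(ds$table)
  expect_equal(pa$k, 3:n)
  expect_equal(pa$mean[length(pa$mean)], jackknife1(ds$table))
  expect_equal(pa$sd[length(pa$sd)], 0)
  # heavy singleton injection -> pool estimate strictly driven by sample size
  expect_true(all(diff(pa$mean) > 0))
})

test_that("percent detected is monotone, bounded, and hits 100 without singletons", {
  ds <- small_synth(seed = 78, u = 0.3)
  pd <- percent_detected(ds$table, permutations = 29, seed = 3)
  expect_true(all(pd$curve$pct > 0 & pd$curve$pct <= 100))
  expect_true(all(diff(pd$curve$pct) > -1e-9))
  final <- utils::tail(pd$curve$pct, 1)
  expect_equal(final,
               100 * incidence_summary(ds$table)$S_obs / jackknife1(ds$table))
  expect_equal(pd$curve$k[pd$curve$pct >= 50][1], pd$k50)

  flat <- matrix(1, 5, 4, dimnames = list(paste0("s", 1:5), paste0("t", 1:4)))
  pf <- percent_detected(flat, permutations = 9, seed = 1)
  expect_equal(utils::tail(pf$curve$pct, 1), 100)
})

test_that("occupancy-abundance and rank-abundance behave as defined", {
  tb <- rbind(s1 = c(a = 8, b = 2, c = 0),
              s2 = c(a = 4, b = 1, c = 0),
              s3 = c(a = 16, b = 4, c = 12))
  oa <- occupancy_abundance(tb)
  expect_equal(oa$occupancy[oa$taxon == "a"], 1)
  expect_equal(oa$occupancy[oa$taxon == "c"], 1 / 3)
  expect_equal(oa$mean_rel_abund[oa$taxon == "a"], mean(c(0.8, 0.8, 0.5)))
  # occupancy invariant to rescaling a sample by a positive integer factor
  tb2 <- tb
  tb2[2, ] <- tb2[2, ] * 7
  expect_equal(occupancy_abundance(tb2)$occupancy, oa$occupancy)

  ra <- rank_abundance(tb)
  expect_true(all(diff(ra$mean_rel_abund) <= 1e-12))
  expect_equal(sum(ra$mean_rel_abund), 1, tolerance = 1e-12)
  eq <- matrix(5, 3, 4, dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  expect_equal(rank_abundance(eq)$mean_rel_abund, rep(0.25, 4))
})

test_that("prevalence-class distributions are proper and match hand counts", {
  # occupancies {1, 1, 2, 3} over 3 samples -> proportions (0.5, 0.25, 0.25)
  tb <- rbind(s1 = c(t1 = 1, t2 = 0, t3 = 1, t4 = 1),
              s2 = c(0, 1, 1, 1),
              s3 = c(0, 0, 0, 1))
  colnames(tb) <- paste0("t", 1:4)
  cls <- prevalence_class_distributions(tb, top_class = 3)
  expect_equal(unname(cls$dataset), c(0.5, 0.25, 0.25))
  expect_equal(sum(cls$per_sample), 1, tolerance = 1e-12)

  ds <- small_synth(seed = 80)
  full <- prevalence_class_distributions(ds$table, top_class = 8)
  expect_equal(sum(full$dataset), 1, tolerance = 1e-12)
  expect_equal(sum(full$per_sample), 1, tolerance = 1e-12)
  expect_error(prevalence_class_distributions(tb, top_class = 8), "at least")

  # all taxa in exactly one sample
  one <- diag(3)
  dimnames(one) <- list(paste0("s", 1:3), paste0("t", 1:3))
  expect_equal(unname(prevalence_class_distributions(one, 3)$dataset), c(1, 0, 0))
  # all taxa ubiquitous with n >= top_class
  ubi <- matrix(1, 8, 5, dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  cu <- prevalence_class_distributions(ubi, 8)
  expect_equal(unname(cu$dataset[["8+"]]), 1)
})
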