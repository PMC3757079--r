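test_that("superposition of a conformation onto itself is exact", {
  cf <- ideal_helix_conf()
  fit <- kabsch_superpose(cf, cf)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
})

test_that("superposition recovers a rigid copy to machine precision", {
  set.seed(7)
  cf <- refined_motif_conf("beta-hairpin")
  cf2 <- transform_rigid(cf, random_rotation(), rnorm(3, sd = 30))
  expect_lt(kabsch_superpose(cf2, cf)$rmsd, 1e-6)
  expect_lt(rmsd_matrix(ensemble(list(cf, cf2)))[1, 2], 1e-6)
})

test_that("kabsch RMSD matches a brute-force rotation-grid search", {
  set.seed(101)
  for (rep in 1:4) {
    X <- matrix(rnorm(12, sd = 2), 4, 3)
    Y <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(kabsch_fit_rmsd(X, Y), grid_rmsd(X, Y), tolerance = 1e-3)
  }
})

test_that("degenerate selections are rejected", {
  cf <- ideal_helix_conf()
  expect_error(kabsch_superpose(cf, cf, residues = 1:2), "3 atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(idpens:::kabsch_fit(line, line), "collinear")
})

test_that("RMSD matrices are symmetric with zero diagonal", {
  e <- cached_ensemble("rat", 12, 3, 3)
  m <- rmsd_matrix(e)
  expect_equal(diag(m), rep(0, 12))
  expect_equal(m, t(m), tolerance = 1e-9)
  expect_true(all(m >= 0))
})

test_that("jittered copies of an ideal helix stay within the 3 A cutoff", {
  seq <- poly_ala()
  set.seed(8)
  confs <- lapply(1:20, function(i)
    build_chain(seq, rnorm(37, -57, 2), rnorm(37, -47, 2)))
  m <- rmsd_matrix(ensemble(confs, seq))
  expect_lt(max(m), 3.0)
})

test_that("greedy clustering handles the degenerate extremes", {
  m <- matrix(1, 10, 10); diag(m) <- 0
  r <- daura_cluster(m, cutoff = 3)
  expect_length(r$families, 1)
  expect_equal(r$families[[1]]$members, 1:10)

  m2 <- matrix(10, 10, 10); diag(m2) <- 0
  r2 <- daura_cluster(m2, cutoff = 3)
  expect_length(r2$families, 10)
  expect_true(all(vapply(r2$families, `[[`, 0L, "size") == 1L))
})

test_that("clustering agrees with an independent naive implementation", {
  for (s in 1:20) {
    set.seed(s)
    pts <- matrix(rnorm(40 * 2, sd = 2.2), 40, 2)
    m <- as.matrix(dist(pts))
    r <- daura_cluster(m, cutoff = 3)
    expect_identical(family_assignment(r), naive_daura(m, 3))
  }
})

test_that("clustering is a deterministic partition with greedy dominance", {
  set.seed(77)
  pts <- matrix(rnorm(50 * 2, sd = 2.5), 50, 2)
  m <- as.matrix(dist(pts))
  r <- daura_cluster(m, cutoff = 3)
  assig <- family_assignment(r)
  expect_true(all(assig >= 1))                      # every structure assigned
  expect_equal(sum(vapply(r$families, `[[`, 0L, "size")), 50)
  sizes <- vapply(r$families, `[[`, 0L, "size")
  expect_true(all(diff(sizes) <= 0))                # non-increasing sizes
  r2 <- daura_cluster(m, cutoff = 3)
  expect_identical(family_assignment(r2), assig)    # determinism
  # members lie within the cutoff of their centroid
  for (f in r$families)
    expect_true(all(m[f$centroid, f$members] <= 3))
})

test_that("top_families applies the population threshold and cap", {
  fams <- list(
    list(members = 1:50, centroid = 1L, size = 50L),
    list(members = 51:80, centroid = 51L, size = 30L),
    list(members = 81:95, centroid = 81L, size = 15L),
    list(members = 96:99, centroid = 96L, size = 4L),
    list(members = 100L, centroid = 100L, size = 1L))
  r <- structure(list(families = fams, cutoff = 3, n = 100L),
                 class = "ClusterResult")
  expect_length(top_families(r)$families, 5)                  # all >= 1%
  expect_length(top_families(r, min_fraction = 0.05)$families, 3)
  expect_length(top_families(r, max_k = 2)$families, 2)
  expect_equal(top_families(r, max_k = 2)$families[[1]]$size, 50L)

  one <- structure(list(families = fams[1], cutoff = 3, n = 50L),
                   class = "ClusterResult")
  expect_length(top_families(one)$families, 1)
})
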