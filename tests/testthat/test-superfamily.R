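ss_from_ranges <- function(helix = NULL, sheet = NULL, L = 37) {
  ss <- rep("C", L)
  ss[helix] <- "H"
  ss[sheet] <- "E"
  ss
}

test_that("merge rule reproduces the three canonical folds", {
  # helix 8-17, no sheet -> helix-coil
  expect_equal(classify_superfamily(ss_from_ranges(helix = 8:17)),
               "helix-coil")
  # helix 8-17 plus strands 25-27 and 33-36 (6 C-part sheet residues)
  expect_equal(classify_superfamily(
    ss_from_ranges(helix = 8:17, sheet = c(25:27, 33:36))),
    "helix-hairpin")
  # strands 9-17 and 23-33, no helix -> beta-hairpin
  expect_equal(classify_superfamily(
    ss_from_ranges(sheet = c(9:17, 23:33))), "beta-hairpin")
})

test_that("the C-part boundary is strictly more than four sheet residues", {
  base <- ss_from_ranges(helix = 8:17)
  four <- base; four[c(25, 26, 33, 34)] <- "E"
  five <- base; five[c(25, 26, 27, 33, 34)] <- "E"
  expect_equal(classify_superfamily(four), "helix-coil")
  expect_equal(classify_superfamily(five), "helix-hairpin")
})

test_that("an N-part tie between helix and sheet is not helix-rich", {
  tie <- ss_from_ranges(helix = 8:10, sheet = 12:14)
  expect_equal(classify_superfamily(tie), "beta-hairpin")
  win <- ss_from_ranges(helix = 8:11, sheet = 12:14)
  expect_equal(classify_superfamily(win), "helix-coil")
})

test_that("every code string maps to exactly one label", {
  set.seed(5)
  for (i in 1:50) {
    ss <- sample(c("H", "G", "E", "B", "T", "C"), 37, replace = TRUE)
    lab <- classify_superfamily(ss)
    expect_true(lab %in% c("helix-coil", "helix-hairpin", "beta-hairpin"))
  }
  expect_error(classify_superfamily(rep("C", 20)), "length 37")
})

test_that("adding C-part sheet residues never demotes helix-hairpin", {
  set.seed(9)
  for (i in 1:20) {
    ss <- ss_from_ranges(helix = 8:17)
    ss[sample(18:37, 5)] <- "E"
    lab <- classify_superfamily(ss)
    more <- ss
    more[sample(which(more[18:37] == "C") + 17, 3)] <- "E"
    if (lab == "helix-hairpin")
      expect_equal(classify_superfamily(more), "helix-hairpin")
  }
})

test_that("family members inherit their centroid's label", {
  e <- cached_ensemble("human", 60, 3, 21)
  prof <- ss_profile(e)
  m <- rmsd_matrix(e)
  cl <- daura_cluster(m, 3.0)
  labs <- classify_families(cl, prof$ss)
  assig <- family_assignment(cl)
  for (f in cl$families)
    expect_length(unique(labs[f$members]), 1)
  # frame granularity on a sigma=0 mixture recovers the exact ground truth
  mix <- mixture_spec(list(make_motif("helix-coil"),
                           make_motif("beta-hairpin"),
                           make_motif("helix-hairpin")),
                      c(0.4, 0.4, 0.2), n = 30, seed = 2)
  e0 <- sample_ensemble(mix, iapp_sequence("human"))
  prof0 <- ss_profile(e0)
  cl0 <- daura_cluster(rmsd_matrix(e0), 3.0)
  labs0 <- classify_families(cl0, prof0$ss, granularity = "frame")
  expect_identical(labs0, e0$truth)
  # centroid granularity agrees with ground truth at sigma = 3
  expect_gte(mean(classify_families(cl, prof$ss) == e$truth), 0.95)
})

test_that("classify_families validates index agreement", {
  e <- cached_ensemble("rat", 12, 3, 3)
  cl <- daura_cluster(rmsd_matrix(e), 3.0)
  expect_error(classify_families(cl, matrix("C", 5, 37)), "12")
})

test_that("abundances are block means with sample standard deviations", {
  # blocks engineered to have label-A fractions 0.8, 0.9, 1.0
  labels <- c(rep(c("helix-coil", "beta-hairpin"), c(8, 2)),
              rep(c("helix-coil", "beta-hairpin"), c(9, 1)),
              rep("helix-coil", 10))
  blocks <- make_blocks(30, 3)
  rep_ <- superfamily_abundance(labels, blocks, last_k = 3)
  hc <- rep_[rep_$label == "helix-coil", ]
  expect_equal(hc$abundance, 0.9)
  expect_equal(hc$std, 0.1)
  expect_equal(sum(rep_$abundance), 1, tolerance = 1e-9)

  single <- superfamily_abundance(rep("helix-coil", 12), make_blocks(12, 6))
  expect_equal(single$abundance, 1)
  expect_equal(single$std, 0)
  expect_error(superfamily_abundance(labels, make_blocks(30, 2), last_k = 3),
               "last_k")
})
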