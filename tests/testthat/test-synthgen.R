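test_that("build_chain reproduces its input dihedrals", {
  seq <- poly_ala(8)
  phi <- c(NA, -57, -139, 60, -100, -57, -139, -75)
  psi <- c(140, -47, 135, 30, 10, -47, 135, NA)
  cf <- build_chain(seq, phi, psi)
  d <- backbone_dihedrals(cf)
  expect_equal(d$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(d$psi[2:7], psi[2:7], tolerance = 1e-6)
  expect_equal(abs(d$omega[-1]), rep(180, 7), tolerance = 1e-6)
})

test_that("ideal helix geometry yields i -> i+4 H-bond distances", {
  cf <- ideal_helix_conf()
  co <- cf$coords
  d <- vapply(6:30, function(i) sqrt(sum((co[i, "O", ] - co[i + 4, "H", ])^2)),
              0)
  expect_true(all(d > 1.8 & d < 2.3))
})

test_that("ideal strand dihedrals give an extended chain", {
  seq <- poly_ala()
  cf <- build_chain(seq, rep(-139, 37), rep(135, 37))
  ee <- sqrt(sum((cf$coords[1, "CA", ] - cf$coords[37, "CA", ])^2))
  expect_gt(ee, 100)          # >= 2.9 A per residue of extension
})

test_that("build_chain validates input lengths", {
  expect_error(build_chain(poly_ala(), rep(-57, 36), rep(-47, 37)),
               "one entry per residue")
})

test_that("motif definitions carry the canonical residue ranges", {
  hc <- make_motif("helix-coil")
  expect_equal(hc$segments$start[hc$segments$type == "helix"], 8)
  expect_equal(hc$segments$end[hc$segments$type == "helix"], 17)
  bh <- make_motif("beta-hairpin")
  expect_equal(bh$segments[bh$segments$type == "turn", c("start", "end")],
               data.frame(start = 18, end = 22), ignore_attr = TRUE)
  expect_equal(bh$segments[bh$segments$type == "strand", "start"], c(9, 23))
  expect_equal(bh$segments[bh$segments$type == "strand", "end"], c(17, 33))
  hh <- make_motif("helix-hairpin")
  expect_equal(hh$segments[hh$segments$type == "turn", c("start", "end")],
               data.frame(start = 28, end = 31), ignore_attr = TRUE)
  expect_equal(hh$segments[hh$segments$type == "strand", "start"], c(25, 33))
  expect_equal(hh$segments[hh$segments$type == "strand", "end"], c(27, 36))
  expect_error(make_motif("zigzag"))
})

test_that("closure refinement registers the cross-strand H-bonds", {
  seq <- iapp_sequence("human")
  for (label in c("beta-hairpin", "helix-hairpin")) {
    m <- make_motif(label)
    cf <- refine_closure(build_chain(seq, m$phi, m$psi), m, max_iter = 2000)
    expect_true(attr(cf, "converged"))
    co <- cf$coords
    # the two innermost cross-strand H-bonds are below the energy cutoff
    for (k in 1:2) {
      a <- m$hbond_pairs[k, 1]; dn <- m$hbond_pairs[k, 2]
      e <- hbond_energy(co[dn, "N", ], co[dn, "H", ], co[a, "C", ],
                        co[a, "O", ])
      expect_lt(e, -0.5)
    }
  }
})

test_that("refinement leaves motifs without a closure range unchanged", {
  seq <- poly_ala()
  m <- make_motif("helix-coil")
  cf <- build_chain(seq, m$phi, m$psi)
  cf2 <- refine_closure(cf, m)
  expect_identical(cf2$coords, cf$coords)
})

test_that("refinement never increases its objective on a closed hairpin", {
  seq <- iapp_sequence("human")
  m <- make_motif("beta-hairpin")
  first <- idpens:::refine_closure_dihedrals(m$phi, m$psi, m,
                                             seq$residues == "P")
  again <- idpens:::.refine_closure_cpp(first$phi, first$psi,
                                        rep(180, 37), seq$residues == "P",
                                        as.integer(m$closure_residues),
                                        m$hbond_pairs, max_iter = 500)
  expect_lte(again$objective, first$objective + 1e-9)
})

test_that("sampling is deterministic under a seed and leaves the RNG alone", {
  mix <- variant_preset("human", n = 10, sigma = 3, seed = 99)
  set.seed(1234)
  before <- .Random.seed
  e1 <- sample_ensemble(mix)
  expect_identical(.Random.seed, before)
  e2 <- sample_ensemble(mix)
  expect_identical(lapply(e1$conformations, `[[`, "coords"),
                   lapply(e2$conformations, `[[`, "coords"))
  expect_identical(e1$truth, e2$truth)
})

test_that("zero jitter and a single component collapse the ensemble", {
  mix <- mixture_spec(list(make_motif("helix-coil", sigma = 0)), 1,
                      n = 5, seed = 7)
  e <- sample_ensemble(mix, poly_ala())
  m <- rmsd_matrix(e)
  expect_lt(max(m), 1e-6)
})

test_that("mixture weights are validated", {
  hc <- make_motif("helix-coil")
  expect_error(mixture_spec(list(hc), -1, n = 5), "non-negative")
  expect_error(mixture_spec(list(hc), 0, n = 5), "positive")
})

test_that("component counts follow the mixture weights", {
  w <- c(0.5, 0.5)
  mix <- mixture_spec(list(make_motif("helix-coil", sigma = 3),
                           make_motif("beta-hairpin", sigma = 3)),
                      w, n = 2000, seed = 31)
  # counts drawn before any geometry: reproduce the draw cheaply
  set.seed(31)
  comp <- sample.int(2, 2000, replace = TRUE, prob = w)
  expect_lt(abs(sum(comp == 1) - 1000), 3 * sqrt(2000 * 0.25))

  # chi-square consistency pooled over 20 seeds
  w3 <- c(0.5, 0.3, 0.2)
  counts <- c(0, 0, 0)
  for (s in 1:20) {
    set.seed(s)
    comp <- sample.int(3, 200, replace = TRUE, prob = w3)
    counts <- counts + tabulate(comp, 3)
  }
  expect_gt(stats::chisq.test(counts, p = w3)$p.value, 0.01)
})

test_that("ground-truth labels are recovered from dihedral-mode assignment", {
  e <- cached_ensemble("human", 120, 5, 17)
  ssm <- ss_profile(e, mode = "dihedral")$ss
  labs <- apply(ssm, 1, classify_superfamily)
  expect_gte(mean(labs == e$truth), 0.95)
})
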