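single_atom <- function(q = 1, radius = 2.09, x = 0) {
  data.frame(residue = 1, atom = "X", x = x, y = 0, z = 0,
             charge = q, radius = radius, scale = 0.8)
}

test_that("an isolated atom keeps its offset-reduced intrinsic radius", {
  p <- solv_params()
  expect_equal(born_radii(single_atom(), p), 2.09 - p$offset,
               tolerance = 1e-12)
})

test_that("burial grows the effective radius; separation shrinks it", {
  p <- solv_params()
  # dense cluster around a central atom
  grid <- expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3), z = c(-3, 0, 3))
  cl <- data.frame(residue = 1, atom = "X", x = grid$x, y = grid$y,
                   z = grid$z, charge = 0, radius = 2.09, scale = 0.8)
  rad <- born_radii(cl, p)
  centre <- which(grid$x == 0 & grid$y == 0 & grid$z == 0)
  expect_gt(rad[centre], 2.0)
  expect_true(all(rad >= 2.0))

  seps <- seq(4, 30, by = 2)
  r1 <- vapply(seps, function(s) {
    pair <- rbind(single_atom(), single_atom(x = s))
    born_radii(pair, p)[1]
  }, 0)
  expect_true(all(diff(r1) < 1e-12))          # monotone towards isolation
  expect_equal(r1[length(r1)], 2.0, tolerance = 1e-3)
  expect_error(born_radii(rbind(single_atom(), single_atom(x = 0.1)), p),
               "overlapping")
})

test_that("GB energy recovers the Born ion and Coulomb screening limits", {
  p0 <- solv_params(salt_M = 0)
  e1 <- gb_energy(single_atom(), radii = 2.0, params = p0)
  expect_equal(e1, -166.03 * (1 - 1 / 78.5) / 2.0, tolerance = 1e-6)
  expect_lt(e1, 0)

  pair <- rbind(single_atom(), single_atom(x = 60))
  e2 <- gb_energy(pair, radii = c(2, 2), params = p0)
  inter <- e2 - 2 * e1
  expect_equal(inter, -332.06 * (1 - 1 / 78.5) / 60, tolerance = 0.01,
               ignore_attr = TRUE)

  zero <- single_atom(q = 0)
  expect_equal(gb_energy(zero, radii = 2, params = p0), 0)

  # Debye screening of the solvent term makes solvating a like-charge pair
  # more favourable (the salt screens the vacuum repulsion)
  p_salt <- solv_params(salt_M = 0.2)
  expect_equal(p_salt$kappa, 0.1413, tolerance = 1e-3)
  e_salt <- gb_energy(pair, radii = c(2, 2), params = p_salt)
  e_salt1 <- gb_energy(single_atom(), radii = 2, params = p_salt)
  expect_lt(e_salt - 2 * e_salt1, inter)
})

test_that("surface areas match sphere closed forms", {
  p <- solv_params()
  s <- sasa(single_atom(), p)
  expect_equal(s$total, 4 * pi * (2.09 + 1.4)^2, tolerance = 0.01)

  # far-apart atoms are additive
  pair <- rbind(single_atom(), single_atom(x = 50))
  s2 <- sasa(pair, p)
  expect_equal(s2$total, 2 * s$total, tolerance = 0.01)

  # near-coincident duplicates occlude each other
  dup <- rbind(single_atom(), single_atom(x = 0.5))
  s3 <- sasa(dup, p)
  expect_true(all(s3$per_atom < s$total))
})

test_that("total energy assembles GB and surface terms", {
  cf <- ideal_helix_conf(iapp_sequence("human"))
  p <- solv_params()
  g <- gbsa_total(cf, p)
  expect_equal(g$E_total, g$E_gb + g$E_surf, tolerance = 1e-12)
  expect_gt(g$E_surf, 0)

  p_g0 <- solv_params(gamma = 0)
  g0 <- gbsa_total(cf, p_g0)
  expect_equal(g0$E_total, g0$E_gb, tolerance = 1e-12)

  # chargeless conformer: only the positive surface term remains
  tbl <- gb_param_table()
  tbl$charge <- 0
  p_q0 <- solv_params(table = tbl,
                      charge_convention = c(nterm = 0, cterm = 0))
  gq <- gbsa_total(cf, p_q0)
  expect_equal(gq$E_gb, 0, tolerance = 1e-9)
  expect_gt(gq$E_total, 0)

  # an extended chain exposes more surface than a helix
  ext <- build_chain(iapp_sequence("human"), rep(-139, 37), rep(135, 37))
  expect_gt(gbsa_total(ext, p)$E_surf, g$E_surf)
})

test_that("solvation energies are invariant under rigid motion", {
  set.seed(3)
  cf <- refined_motif_conf("helix-hairpin")
  cf2 <- transform_rigid(cf, random_rotation(), rnorm(3, sd = 15))
  p <- solv_params()
  a1 <- solvation_atoms(cf, p); a2 <- solvation_atoms(cf2, p)
  r1 <- born_radii(a1, p); r2 <- born_radii(a2, p)
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_equal(gb_energy(a1, r1, p), gb_energy(a2, r2, p),
               tolerance = 1e-6)
  expect_equal(sasa(a1, p)$total, sasa(a2, p)$total, tolerance = 1e-6)
  g1 <- gbsa_total(cf, p); g2 <- gbsa_total(cf2, p)
  expect_equal(g1$E_total, g2$E_total,
               tolerance = 1e-6 * abs(g1$E_total))
})

test_that("peptide total charge equals the formal charge", {
  for (v in c("human", "rat")) {
    seq <- iapp_sequence(v)
    cf <- ideal_helix_conf(seq)
    atoms <- solvation_atoms(cf)
    expect_equal(sum(atoms$charge), formal_charge(seq), tolerance = 1e-9)
  }
})

test_that("solvation report applies the two relative conventions", {
  e <- cached_ensemble("rat", 24, 3, 33)
  blocks <- make_blocks(24, 6)
  energies <- as.numeric(seq_len(24))        # synthetic per-frame energies
  rep1 <- solvation_report(e, e$truth, blocks, energies = energies)
  expect_equal(rep1$delta_vs_helix_coil[rep1$label == "helix-coil"], 0)
  expect_true(is.na(rep1$delta_vs_helix_coil[rep1$label == "average"]))
  # constant shift leaves the delta column unchanged
  rep2 <- solvation_report(e, e$truth, blocks, energies = energies + 100)
  expect_equal(rep2$delta_vs_helix_coil, rep1$delta_vs_helix_coil)
  expect_true(all(rep1$std >= 0))

  reports <- list(rat = rep1, human = rep2)
  rel <- relative_solvation(reports, reference = "human")
  expect_equal(rel$delta_vs_reference[rel$variant == "human"], 0)
  expect_equal(rel$delta_vs_reference[rel$variant == "rat"], -100)
})
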