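test_that("peptide_sequence validates codes and disulfide topology", {
  s <- peptide_sequence("KCNTATC", c_amidated = TRUE, disulfide = c(2, 7))
  expect_equal(s$residues[2], "C")
  expect_error(peptide_sequence("KXN"), "invalid amino-acid")
  expect_error(peptide_sequence("KCNTATC", disulfide = c(2, 2)), "distinct")
  expect_error(peptide_sequence("KCNTATC", disulfide = c(1, 7)), "cysteine")
  expect_error(peptide_sequence("KCNTATC", disulfide = c(2, 9)), "within")
})

test_that("formal charge follows the protonation convention", {
  expect_equal(formal_charge(peptide_sequence(strrep("A", 5))), 0)
  expect_equal(formal_charge(peptide_sequence(strrep("A", 5),
                                              c_amidated = TRUE)), 1)
  # His-neutral convention: N-term + K + R
  expect_equal(formal_charge(peptide_sequence("KRH", c_amidated = TRUE)), 3)
  expect_equal(formal_charge(peptide_sequence("KRH", c_amidated = TRUE),
                             convention = c(K = 1, R = 1, H = 1, nterm = 1,
                                            cterm = -1)), 4)
  expect_equal(formal_charge(peptide_sequence("DE")), -2)
})

test_that("FASTA sequence records round-trip with feature tags", {
  f <- withr::local_tempfile(fileext = ".fasta")
  s <- iapp_sequence("rat")
  write_sequence(s, f)
  s2 <- read_sequence(f)
  expect_equal(s2$residues, s$residues)
  expect_true(s2$c_amidated)
  expect_equal(s2$disulfide, c(2L, 7L))
})

test_that("multi-model PDB write/read is identity within PDB precision", {
  seq <- iapp_sequence("rat")
  e <- cached_ensemble("rat", 3, 2, 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  expect_length(grep("^MODEL", readLines(f)), 3)
  e2 <- read_ensemble(f, seq)
  expect_length(e2, 3)
  for (m in 1:3) {
    dev <- abs(e$conformations[[m]]$coords - e2$conformations[[m]]$coords)
    expect_lt(max(dev, na.rm = TRUE), 1e-3)
  }
})

test_that("single-model PDB reads as an ensemble of length 1", {
  seq <- poly_ala()
  e <- ensemble(list(ideal_helix_conf(seq)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  e2 <- read_ensemble(f, seq)
  expect_length(e2, 1)
})

test_that("missing backbone atoms and sequence mismatches are reported", {
  seq <- iapp_sequence("rat")
  e <- cached_ensemble("rat", 3, 2, 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  drop <- which(grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA " &
                  trimws(substr(lines, 23, 26)) == "12")
  drop <- drop[drop > starts[2] & drop < starts[3]]
  writeLines(lines[-drop], f)
  expect_error(read_ensemble(f, seq), "model 2, residue 12")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, f2)
  expect_error(read_ensemble(f2, iapp_sequence("human")),
               "sequence mismatch at residue 18")
  expect_error(read_ensemble("no/such/file.pdb", seq), "not found")
})

test_that("write_ensemble rejects an invalid path", {
  e <- ensemble(list(ideal_helix_conf()))
  expect_error(write_ensemble(e, ""), "path")
})

test_that("reconstructed amide H has the contracted geometry", {
  seq <- iapp_sequence("rat")   # contains prolines
  e <- cached_ensemble("rat", 2, 3, 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(e, f)
  # strip all H records to force reconstruction on read
  lines <- readLines(f)
  keep <- !(grepl("^ATOM", lines) & substr(lines, 13, 16) == " H  ")
  writeLines(lines[keep], f)
  e2 <- read_ensemble(f, seq)
  co <- e2$conformations[[1]]$coords
  for (i in 2:37) {
    if (seq$residues[i] == "P") {
      expect_true(anyNA(co[i, "H", ]))
      next
    }
    h <- co[i, "H", ]; n <- co[i, "N", ]
    expect_gt(sqrt(sum((h - n)^2)), 0.95)
    expect_lt(sqrt(sum((h - n)^2)), 1.05)
    u1 <- co[i - 1, "C", ] - n; u2 <- co[i, "CA", ] - n
    bis <- u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2))
    bis <- bis / sqrt(sum(bis^2))
    nh <- (h - n) / sqrt(sum((h - n)^2))
    expect_gt(acos(max(-1, min(1, sum(nh * bis)))) * 180 / pi, 150)
  }
  expect_true(anyNA(co[1, "H", ]))   # first residue never has an amide H
})

test_that("conformation validation catches bad geometry", {
  cf <- ideal_helix_conf()
  bad <- cf$coords
  bad[10, "CA", ] <- bad[10, "CA", ] + 5
  expect_error(conformation(bad, cf$sequence), "bond length")
  bad2 <- cf$coords
  bad2[10, "O", ] <- bad2[11, "N", ] + 0.1
  expect_error(conformation(bad2, cf$sequence), "")
})
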