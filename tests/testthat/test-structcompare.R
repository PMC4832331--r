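test_that("Kabsch superposition recovers applied rigid transforms", {
  set.seed(12)
  P <- matrix(rnorm(30), ncol = 3)
  s0 <- kabsch_superpose(P, P)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation()
  t <- c(3, -1, 7)
  Q <- sweep(P %*% t(R), 2, t, `+`)
  s <- kabsch_superpose(P, Q)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$rotation, R, tolerance = 1e-9)
  expect_equal(s$translation, t, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(s, P), Q, tolerance = 1e-9)
})

test_that("Kabsch RMSD equals the quaternion oracle on random instances", {
  set.seed(13)
  for (rep in 1:200) {
    P <- matrix(rnorm(30), ncol = 3)
    Q <- matrix(rnorm(30), ncol = 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, horn_rmsd(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and mismatched point sets are rejected", {
  P <- matrix(rnorm(30), ncol = 3)
  expect_error(kabsch_superpose(P, P[1:9, ]), "differ in size")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "three points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("residue pairing counts overlap correctly", {
  mk <- function(resno, chain = "A", aa = "A") {
    structure_model(data.frame(chain = chain, resno = resno, aa = aa,
                               x = resno * 1.1, y = 0, z = 0.5 * resno))
  }
  a <- mk(1:100); b <- mk(51:150)
  pr <- pair_residues(a, b)
  expect_equal(nrow(pr), 50)
  expect_equal(range(pr$resno_a), c(51, 100))
  prs <- pair_residues(a, a)
  expect_equal(nrow(prs), 100)
  # sequence-aligned mode drops an indel column
  seq_a <- "ACDEFGHIK"; seq_b <- "ACDEGHIK"   # F deleted
  ma <- structure_model(data.frame(chain = "A", resno = 1:9,
                                   aa = strsplit(seq_a, "")[[1]],
                                   x = 1:9, y = (1:9)^1.3, z = 9:1))
  mb <- structure_model(data.frame(chain = "A", resno = 1:8,
                                   aa = strsplit(seq_b, "")[[1]],
                                   x = 1:8, y = (1:8)^1.3, z = 8:1))
  pr2 <- pair_residues(ma, mb, mode = "sequence-aligned")
  expect_equal(nrow(pr2), 8)
  expect_false(5 %in% pr2$resno_a)   # the F at position 5 is unpaired
})

test_that("domain reports are null for identical models and respect
           the RMSD_min bound everywhere", {
  td <- gen_toy_decamer(toy_decamer_spec(ctd_swing_angle = 7,
                                         ctd_stretch = 2, seed = 14))
  self <- domain_rmsd_report(td$reference, td$reference)
  expect_equal(max(self$in_context), 0, tolerance = 1e-12)
  rep <- domain_rmsd_report(td$reference, td$moved)
  expect_true(all(rep$rmsd_min <= rep$in_context + 1e-9))
  expect_true(all(rep$in_context >= 0))
})

test_that("whole-model rigid motion leaves every RMSD unchanged", {
  td <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 3, seed = 15))
  rep1 <- domain_rmsd_report(td$reference, td$moved)
  set.seed(16)
  R <- random_rotation(); t <- c(5, -2, 9)
  moved2 <- td$moved
  X <- as.matrix(moved2[c("x", "y", "z")])
  X2 <- sweep(X %*% t(R), 2, t, `+`)
  moved2$x <- X2[, 1]; moved2$y <- X2[, 2]; moved2$z <- X2[, 3]
  rep2 <- domain_rmsd_report(td$reference, moved2)
  expect_equal(rep1$in_context, rep2$in_context, tolerance = 1e-6)
  expect_equal(rep1$rmsd_min, rep2$rmsd_min, tolerance = 1e-6)
})

test_that("monomer-scope fits are offered and consistent", {
  td <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 2, seed = 17))
  repm <- domain_rmsd_report(td$reference, td$moved, scope = "monomer")
  ctd <- repm[repm$domain == "ctd", ]
  # per-monomer fit partially absorbs the CTD shift into the fit, so the
  # in-context value drops below the decamer-scope value but stays >= 0
  expect_true(all(ctd$in_context <= 2 + 1e-9))
  expect_true(all(repm$rmsd_min <= repm$in_context + 1e-9))
})

test_that("segment centroid shifts report planted radial displacements", {
  td <- gen_toy_decamer(toy_decamer_spec(seed = 18))
  z <- segment_centroid_shift(td$reference, td$reference, c(564, 583),
                              axis = "estimate")
  expect_equal(max(abs(z$shift)), 0, tolerance = 1e-12)
  td2 <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 3.5, seed = 18))
  s <- segment_centroid_shift(td2$reference, td2$moved, c(564, 583),
                              axis = "estimate")
  expect_equal(s$shift, rep(3.5, 10), tolerance = 0.01)
  expect_equal(s$radial, rep(3.5, 10), tolerance = 0.01)
  expect_error(segment_centroid_shift(td2$reference, td2$moved,
                                      c(716, 720), axis = NULL),
               "unpaired")
})

test_that("PDB and mmCIF renderings round-trip identically", {
  td <- gen_toy_decamer(toy_decamer_spec(points_per_domain = 5,
                                         seed = 19))
  f_pdb <- tempfile(fileext = ".pdb")
  f_cif <- tempfile(fileext = ".cif")
  write_ca_pdb(td$reference, f_pdb)
  write_ca_cif(td$reference, f_cif)
  m_pdb <- suppressWarnings(read_structure(f_pdb))
  m_cif <- suppressWarnings(read_structure(f_cif))
  expect_equal(as.data.frame(m_pdb), as.data.frame(m_cif),
               ignore_attr = TRUE)
  ref <- td$reference[order(td$reference$chain, td$reference$resno), ]
  expect_equal(m_pdb$x, ref$x, tolerance = 1e-3)
  expect_equal(m_pdb$z, ref$z, tolerance = 1e-3)
  expect_equal(m_pdb$resno, ref$resno)
})

test_that("altloc resolution keeps the highest-occupancy Calpha", {
  lines <- c(
    "ATOM      1  CA AALA A   1      11.000  22.000   1.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1      99.000  98.000  97.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       1.000   2.000   3.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- suppressWarnings(read_structure(f))
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$resno == 1], 99.0)
  # insertion codes are rejected outright
  lines_ins <- c(
    "ATOM      1  CA  ALA A   1      11.000  22.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1A     12.000  23.000   2.000  1.00  0.00           C",
    "END")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines_ins, f2)
  expect_error(suppressWarnings(read_structure(f2)), "insertion")
  # a file without Calpha atoms is an empty model
  f3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB  ALA A   1      11.000  22.000   1.000  1.00  0.00           C",
    "END"), f3)
  expect_error(suppressWarnings(read_structure(f3)), "no Calpha")
})
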