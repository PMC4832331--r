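test_that("sampled trees have the right shape and are seed-determined", {
  tr3 <- sample_tree(3, 0.5, seed = 1)
  expect_equal(length(tr3$tip.label), 3)
  expect_equal(nrow(tr3$edge), 4)          # 2n - 2 for a rooted binary tree
  tr22 <- sample_tree(22, 0.8, seed = 7)
  expect_equal(length(tr22$tip.label), 22)
  expect_equal(nrow(tr22$edge), 42)
  expect_true(all(tr22$edge.length > 0))
  expect_identical(ape::write.tree(sample_tree(22, 0.8, seed = 7)),
                   ape::write.tree(tr22))
  # mean root-to-tip depth is calibrated to the requested height
  depth <- ape::node.depth.edgelength(tr22)[1:22]
  expect_equal(mean(depth), 0.8, tolerance = 1e-9)
  expect_error(sample_tree(2, 0.5, seed = 1), "three")
})

test_that("simulated alignments obey indel and signature constraints", {
  p <- reduced_params(seed = 23, n_per_group = 5)
  fam <- simulate_ldc_family(p)
  aln <- fam$alignment
  # no indels by default: every row is full length and gap-free
  expect_false(any(grepl("-", unclass(aln), fixed = TRUE)))
  expect_true(all(nchar(aln) == 160))
  # signature purity: planted slots draw only from the group's set
  m <- msa_matrix(aln)
  tb <- p$signature_table
  for (i in seq_len(nrow(tb))) {
    setA <- strsplit(tb$groupA[i], "")[[1]]
    setB <- strsplit(tb$groupB[i], "")[[1]]
    colA <- m[fam$groups[rownames(m)] == "A", tb$position[i]]
    colB <- m[fam$groups[rownames(m)] == "B", tb$position[i]]
    expect_true(all(colA %in% setA))
    expect_true(all(colB %in% setB))
  }
  # determinism: same params give byte-identical output
  fam2 <- simulate_ldc_family(reduced_params(seed = 23, n_per_group = 5))
  expect_identical(unclass(fam$alignment), unclass(fam2$alignment))
  expect_equal(fam$neighborhoods, fam2$neighborhoods,
               ignore_attr = TRUE)
})

test_that("the full-scale defaults plant the strict Y697/K697 dimorphism", {
  p <- simulation_params(n_taxa_per_group = 4, seed = 2)
  tr <- two_group_tree(4, between = p$between_divergence,
                       within = p$within_height, seed = 2)
  aln <- evolve_alignment(tr, p)
  m <- msa_matrix(aln)
  groups <- attr(tr, "groups")
  expect_true(all(m[groups[rownames(m)] == "A", 697] == "Y"))
  expect_true(all(m[groups[rownames(m)] == "B", 697] == "K"))
})

test_that("zero-height trees give invariant background columns", {
  p <- reduced_params(seed = 41, n_per_group = 3)
  p$within_height <- 0
  p$between_divergence <- 0
  tr <- two_group_tree(3, between = 0, within = 0, seed = 41)
  aln <- evolve_alignment(tr, p)
  m <- msa_matrix(aln)
  planted <- p$signature_table$position
  bg <- setdiff(seq_len(160), planted)
  expect_true(all(apply(m[, bg], 2, function(col)
    length(unique(col)) == 1)))
})

test_that("indel events gap only unprotected columns", {
  p <- reduced_params(seed = 52, n_per_group = 4)
  p$indel_rate <- 0.02
  tr <- two_group_tree(4, between = 0.5, within = 0.15, seed = 52)
  aln <- evolve_alignment(tr, p)
  m <- msa_matrix(aln)
  expect_true(any(m == "-"))
  protected <- unlist(lapply(p$signature_regions,
                             function(r) seq(r[1], r[2])))
  expect_false(any(m[, protected] == "-"))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(seq_length = 100,
                                 signature_regions = list(c(60, 69),
                                                          c(120, 138))),
               "outside")
  expect_error(simulation_params(
    signature_table = data.frame(position = 631L, groupA = "Y",
                                 groupB = "YK")), "overlap")
})

test_that("toy decamers reproduce their template at zero motion", {
  td <- gen_toy_decamer(toy_decamer_spec(seed = 3))
  expect_identical(td$reference, td$moved)
  expect_equal(length(unique(td$reference$chain)), 10)
  expect_equal(nrow(td$reference), 10 * 5 * 20)
  # determinism
  td2 <- gen_toy_decamer(toy_decamer_spec(seed = 3))
  expect_identical(td$reference, td2$reference)
})

test_that("a pure CTD translation is a rigid in-context displacement", {
  td <- gen_toy_decamer(toy_decamer_spec(ctd_stretch = 4, seed = 6))
  rep <- domain_rmsd_report(td$reference, td$moved)
  ctd <- rep[rep$domain == "ctd", ]
  expect_equal(ctd$in_context, rep(4, 10), tolerance = 1e-9)
  expect_equal(ctd$rmsd_min, rep(0, 10), tolerance = 1e-9)
  others <- rep[rep$domain %in% c("wing", "linker", "plp_sd",
                                  "subdomain4"), ]
  expect_equal(max(others$in_context), 0, tolerance = 1e-9)
})

test_that("a CTD swing matches explicit point arithmetic", {
  spec <- toy_decamer_spec(ctd_swing_angle = 5, seed = 8)
  td <- gen_toy_decamer(spec)
  rep <- domain_rmsd_report(td$reference, td$moved)
  # oracle: global fit by the quaternion method, then the plain RMS of
  # the CTD displacement, computed directly from the coordinates
  Xa <- as.matrix(td$reference[c("x", "y", "z")])
  Xb <- as.matrix(td$moved[c("x", "y", "z")])
  expect_lt(horn_rmsd(Xa, Xb), max(rep$in_context) + 1e-9)
  ctd_idx <- td$reference$resno >= 564
  # the global fit is the identity by D5 symmetry, so the in-context CTD
  # RMSD equals the raw displacement RMS
  raw <- sqrt(mean(rowSums((Xa[ctd_idx, ] - Xb[ctd_idx, ])^2)))
  expect_equal(max(abs(rep$in_context[rep$domain == "ctd"] - raw)), 0,
               tolerance = 1e-6)
  # the motion is rigid: RMSD_min of the CTD vanishes
  expect_equal(max(rep$rmsd_min[rep$domain == "ctd"]), 0,
               tolerance = 1e-9)
})

test_that("degenerate toy templates are rejected", {
  expect_error(toy_decamer_spec(points_per_domain = 2), ">= 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  lay <- list(wing = line, linker = line, plp_sd = line,
              subdomain4 = line, ctd = line)
  expect_error(gen_toy_decamer(toy_decamer_spec(domain_layout = lay)),
               "collinear")
})
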