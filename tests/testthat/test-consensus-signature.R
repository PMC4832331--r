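toy_aln <- function() {
  ldc_msa(c(a1 = "YKAD", a2 = "YKAD", b1 = "YRC-", b2 = "KRCD"))
}

test_that("consensus frequencies equal hand counts and sum to one", {
  prof <- build_consensus(toy_aln())
  fam <- prof$groups$family
  expect_equal(unname(fam$freq["Y", 1]), 3 / 4)
  expect_equal(unname(fam$freq["K", 1]), 1 / 4)
  expect_equal(unname(fam$freq["K", 2]), 2 / 4)
  expect_equal(unname(fam$freq["R", 2]), 2 / 4)
  expect_equal(unname(fam$freq["-", 4]), 1 / 4)
  expect_equal(colSums(fam$freq), rep(1, 4), tolerance = 1e-9)
  expect_equal(fam$conservation[1], 0.75)
  # per-group profiles
  gp <- build_consensus(toy_aln(),
                        group_labels = c(a1 = "A", a2 = "A",
                                         b1 = "B", b2 = "B"))
  expect_equal(unname(gp$groups$A$freq["Y", 1]), 1)
  expect_equal(gp$groups$A$conservation[1], 1)
  expect_error(build_consensus(toy_aln(),
                               group_labels = c(a1 = "A", a2 = "A",
                                                b1 = "B")),
               "unlabelled")
})

test_that("information mode is maximal for invariant columns", {
  aln <- ldc_msa(c(x = "YY", y = "YK"))
  prof <- build_consensus(aln, mode = "information")
  expect_equal(prof$groups$family$conservation[1], log2(20))
  expect_equal(prof$groups$family$conservation[2], log2(20) - 1)
  # ties resolve to the first residue in the fixed alphabet order (K < Y)
  expect_identical(consensus_sequence(prof), "YK")
})

test_that("signature extraction honors the reference numbering", {
  p <- reduced_params(seed = 13, n_per_group = 4)
  fam <- simulate_ldc_family(p)
  aln <- fam$alignment   # indel-free, so column == reference position
  refmap <- map_to_reference(aln, names(aln)[1])
  sd <- reduced_sigdef()
  log <- attr(aln, "signature_log")
  for (tx in names(aln)[c(1, 5)]) {
    sig <- extract_signature(aln, tx, refmap, sd)
    pos <- attr(sig, "positions")
    chars <- strsplit(as.character(sig), "")[[1]]
    planted <- log[log$taxon == tx, ]
    for (k in seq_len(nrow(planted))) {
      slot <- which(pos == planted$position[k])
      expect_identical(chars[slot], planted$residue[k])
    }
  }
  # a gap in a signature slot is reported and flagged
  rows <- unclass(aln)
  substr(rows[[2]], 60, 60) <- "-"
  aln2 <- ldc_msa(setNames(unlist(rows), names(aln)))
  sig2 <- extract_signature(aln2, names(aln)[2],
                            map_to_reference(aln2, names(aln)[1]), sd)
  expect_true(attr(sig2, "has_gaps"))
  expect_identical(substr(as.character(sig2), 1, 1), "-")
})

test_that("the Y/K dimorphism alone separates the two groups", {
  # training signatures ambiguous everywhere except the Y/K slot
  sigs <- c(i1 = "AY", i2 = "CY", c1 = "AK", c2 = "CK")
  labs <- c(i1 = "ldcI-like", i2 = "ldcI-like",
            c1 = "ldcC-like", c2 = "ldcC-like")
  prof <- signature_profiles(sigs, labs)
  expect_equal(classify_by_signature("GY", prof)$label, "ldcI-like")
  expect_equal(classify_by_signature("GK", prof)$label, "ldcC-like")
  expect_equal(classify_by_signature("--", prof)$label, "unknown")
  expect_true(2 %in% prof$discriminating)
  expect_false(1 %in% prof$discriminating)
})

test_that("classifier is symmetric under group relabelling", {
  set.seed(21)
  sigs <- setNames(vapply(1:8, function(i) random_protein(6),
                          character(1)), paste0("s", 1:8))
  labs <- setNames(rep(c("G1", "G2"), 4), names(sigs))
  prof <- signature_profiles(sigs, labs)
  swapped <- setNames(ifelse(labs == "G1", "G2", "G1"), names(labs))
  # keep the same group-name ordering trick: rename so sort order flips
  labs2 <- setNames(ifelse(labs == "G1", "H2", "H1"), names(labs))
  prof2 <- signature_profiles(sigs, labs2)
  q <- random_protein(6)
  r1 <- classify_by_signature(q, prof)
  r2 <- classify_by_signature(q, prof2)
  expect_equal(r1$score, -r2$score, tolerance = 1e-9)
  if (r1$label != "unknown") {
    map <- c(G1 = "H2", G2 = "H1")
    expect_equal(unname(map[r1$label]), r2$label)
  }
})

test_that("leave-one-out signature classification is perfect on planted groups", {
  for (seed in c(101, 202, 303)) {
    p <- reduced_params(seed = seed, n_per_group = 6)
    fam <- simulate_ldc_family(p)
    aln <- fam$alignment
    refmap <- map_to_reference(aln, names(aln)[1])
    sd <- reduced_sigdef()
    sigs <- vapply(names(aln), function(tx)
      as.character(extract_signature(aln, tx, refmap, sd)), character(1))
    labs <- fam$groups[names(sigs)]
    for (tx in names(sigs)) {
      prof <- signature_profiles(sigs[names(sigs) != tx],
                                 labs[names(sigs) != tx])
      expect_equal(classify_by_signature(sigs[[tx]], prof)$label,
                   unname(labs[tx]))
    }
  }
})

test_that("chimera design swaps exactly the signature regions", {
  set.seed(33)
  bb <- random_protein(160)
  dn_chars <- strsplit(bb, "")[[1]]
  mut <- sample(160, 40)
  dn_chars[mut] <- sample(AA20_T, 40, replace = TRUE)
  dn <- paste(dn_chars, collapse = "")
  sd <- reduced_sigdef()
  # self-swap is the identity
  self <- design_chimera(c(s = bb), c(s2 = bb), sigdef = sd)
  expect_identical(as.character(self), bb)
  # swap, then swap back from the original donor regions: involution on
  # gap-free regions
  ch <- design_chimera(c(bb = bb), c(dn = dn), sigdef = sd)
  back <- design_chimera(ch, c(bb = bb), sigdef = sd)
  expect_identical(as.character(back), bb)
  # outside the regions the chimera is byte-identical to the backbone
  regions <- c(60:69, 120:138)
  ch_chars <- strsplit(unname(ch), "")[[1]]
  bb_chars <- strsplit(bb, "")[[1]]
  expect_identical(ch_chars[-regions], bb_chars[-regions])
  expect_identical(paste(ch_chars[regions], collapse = ""),
                   paste(dn_chars[regions], collapse = ""))
  # junction report names both segments
  j <- attr(ch, "junctions")
  expect_equal(nrow(j), 2)
  expect_identical(j$donor_segment[1],
                   paste(dn_chars[60:69], collapse = ""))
})

test_that("chimeras flip the signature classification, mirroring the
           RavA-binding phenotype of the swapped beta-sheets", {
  p <- reduced_params(seed = 55, n_per_group = 6)
  fam <- simulate_ldc_family(p)
  aln <- fam$alignment
  refmap <- map_to_reference(aln, names(aln)[1])
  sd <- reduced_sigdef()
  sigs <- vapply(names(aln), function(tx)
    as.character(extract_signature(aln, tx, refmap, sd)), character(1))
  labs <- setNames(ifelse(fam$groups == "A", "ldcI-like", "ldcC-like"),
                   names(fam$groups))[names(sigs)]
  prof <- signature_profiles(sigs, labs)
  seqs <- setNames(gsub("-", "", unclass(aln)), names(aln))
  iname <- names(fam$groups)[fam$groups == "A"][1]
  cname <- names(fam$groups)[fam$groups == "B"][1]
  ldcIC <- design_chimera(seqs[iname], seqs[cname], sigdef = sd)
  ldcCI <- design_chimera(seqs[cname], seqs[iname], sigdef = sd)
  aln_ic <- progressive_msa(c(seqs[1], ldcIC))
  aln_ci <- progressive_msa(c(seqs[1], ldcCI))
  sig_ic <- extract_signature(aln_ic, names(ldcIC),
                              map_to_reference(aln_ic, names(seqs)[1]), sd)
  sig_ci <- extract_signature(aln_ci, names(ldcCI),
                              map_to_reference(aln_ci, names(seqs)[1]), sd)
  expect_equal(classify_by_signature(as.character(sig_ic), prof)$label,
               "ldcC-like")
  expect_equal(classify_by_signature(as.character(sig_ci), prof)$label,
               "ldcI-like")
  # donor entirely gapped inside a region is a design failure
  short <- c(s = substr(bb <- unname(seqs[iname]), 1, 100))
  expect_error(design_chimera(seqs[iname], short, sigdef = sd),
               "gapped")
})
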