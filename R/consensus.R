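#' Residue polarity classes
#'
#' Fixed four-class scheme used for consensus colouring and signature
#' reports: acidic \{D, E\}; basic \{K, R, H\}; hydrophilic
#' \{S, T, N, Q, C, G, Y\}; hydrophobic \{A, V, L, I, P, F, M, W\}.
#'
#' @return Named character vector mapping each of the 20 residues to its
#'   class.
#' @export
polarity_scheme <- function() {
  out <- c(D = "acidic", E = "acidic",
           K = "basic", R = "basic", H = "basic",
           S = "hydrophilic", T = "hydrophilic", N = "hydrophilic",
           Q = "hydrophilic", C = "hydrophilic", G = "hydrophilic",
           Y = "hydrophilic",
           A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
           I = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
           M = "hydrophobic", W = "hydrophobic")
  out[AA20]
}

#' Signature region definition in reference numbering
#'
#' The two C-terminal beta-strand regions that discriminate ldcI-like from
#' ldcC-like lysine decarboxylases, in E. coli LdcI numbering: strand 1
#' spans residues 631-640 and strand 2 runs from residue 697 to the
#' C-terminus (residue 715 in E. coli LdcI).
#'
#' @param strand1,strand2 Integer vectors `c(start, end)`, 1-based
#'   inclusive, in reference numbering.
#' @param reference_length Length of the reference protein (E. coli LdcI:
#'   715).
#' @return A `signature_definition` with the two regions and the flat
#'   vector of signature positions.
#' @export
signature_definition <- function(strand1 = c(631, 640),
                                 strand2 = c(697, 715),
                                 reference_length = 715) {
  stopifnot(length(strand1) == 2, length(strand2) == 2)
  r1 <- seq(strand1[1], strand1[2])
  r2 <- seq(strand2[1], strand2[2])
  if (length(intersect(r1, r2)) > 0)
    stop("signature regions must not overlap", call. = FALSE)
  if (max(r1, r2) > reference_length || min(r1, r2) < 1)
    stop("signature regions outside the reference length", call. = FALSE)
  structure(list(strand1 = strand1, strand2 = strand2,
                 positions = c(r1, r2),
                 reference_length = reference_length),
            class = "signature_definition")
}

#' Per-column consensus profiles for an alignment
#'
#' Residue (and gap) frequencies, conservation, majority residue and its
#' polarity class for every alignment column; computed for the whole family
#' and, when `group_labels` is given, for each group.
#'
#' @param aln An [ldc_msa()].
#' @param group_labels Optional named vector mapping row names to group
#'   ids; every row must be labelled and each group needs at least two
#'   rows.
#' @param mode Conservation measure: `"frequency"` (majority-residue
#'   relative frequency, 0-1) or `"information"` (information content in
#'   bits, 0 to log2 20, computed over residues with gaps excluded).
#' @return A `consensus_profile`: list of per-group components, each with
#'   `freq` (21 x L matrix, rows `c(AA20, "-")`, columns summing to 1),
#'   `conservation`, `majority` and `polarity` vectors.
#' @export
build_consensus <- function(aln, group_labels = NULL,
                            mode = c("frequency", "information")) {
  mode <- match.arg(mode)
  m <- msa_matrix(aln)
  groups <- list(family = rownames(m))
  if (!is.null(group_labels)) {
    missing <- setdiff(rownames(m), names(group_labels))
    if (length(missing) > 0)
      stop("unlabelled rows: ", paste(missing, collapse = ", "),
           call. = FALSE)
    for (g in unique(group_labels[rownames(m)])) {
      members <- rownames(m)[group_labels[rownames(m)] == g]
      if (length(members) < 2)
        stop(sprintf("group '%s' has fewer than two sequences", g),
             call. = FALSE)
      groups[[g]] <- members
    }
  }
  out <- lapply(groups, function(members)
    column_profile(m[members, , drop = FALSE], mode))
  structure(list(mode = mode, groups = out,
                 n = vapply(groups, length, integer(1))),
            class = "consensus_profile")
}

column_profile <- function(m, mode) {
  L <- ncol(m)
  lev <- c(AA20, GAP)
  freq <- apply(m, 2, function(col)
    as.numeric(table(factor(col, levels = lev))) / length(col))
  dimnames(freq) <- list(lev, NULL)
  res_freq <- freq[AA20, , drop = FALSE]
  maj_idx <- apply(res_freq, 2, which.max)
  majority <- AA20[maj_idx]
  all_gap <- colSums(res_freq) == 0
  majority[all_gap] <- NA_character_
  conservation <- if (mode == "frequency") {
    res_freq[cbind(maj_idx, seq_len(L))]
  } else {
    apply(res_freq, 2, function(p) {
      tot <- sum(p)
      if (tot == 0) return(0)
      p <- p[p > 0] / tot
      log2(20) + sum(p * log2(p))
    })
  }
  pol <- polarity_scheme()[majority]
  list(freq = freq, conservation = unname(conservation),
       majority = majority, polarity = unname(pol))
}

#' Consensus sequence of a profile
#'
#' Majority residue per column; columns that are entirely gaps yield `-`.
#'
#' @param profile A `consensus_profile`.
#' @param group Which component to use (default `"family"`).
#' @return A single character string.
#' @export
consensus_sequence <- function(profile, group = "family") {
  comp <- profile$groups[[group]]
  if (is.null(comp)) stop("no such group: ", group, call. = FALSE)
  maj <- comp$majority
  maj[is.na(maj)] <- GAP
  paste(maj, collapse = "")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("Consensus profile (%s mode): %d columns\n",
              x$mode, length(x$groups$family$conservation)))
  for (g in names(x$groups))
    cat(sprintf("  %-10s n = %2d  mean conservation %.3f\n", g, x$n[[g]],
                mean(x$groups[[g]]$conservation)))
  invisible(x)
}

#' Plot per-column conservation coloured by polarity class
#'
#' @param x A `consensus_profile`.
#' @param group Component to plot.
#' @param columns Optional column range to restrict to.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.consensus_profile <- function(x, group = "family", columns = NULL,
                                   ...) {
  comp <- x$groups[[group]]
  if (is.null(comp)) stop("no such group: ", group, call. = FALSE)
  idx <- if (is.null(columns)) seq_along(comp$conservation) else columns
  cols <- c(acidic = "red3", basic = "blue3",
            hydrophilic = "green4", hydrophobic = "black")
  graphics::barplot(comp$conservation[idx],
                    names.arg = comp$majority[idx],
                    col = cols[comp$polarity[idx]], border = NA,
                    ylab = if (x$mode == "frequency") "conservation"
                           else "bits",
                    xlab = "alignment column", ...)
  invisible(x)
}

#' Write a consensus profile component as TSV
#' @param profile A `consensus_profile`.
#' @param file Output path.
#' @param group Component to write.
#' @return Invisibly, `file`.
#' @export
write_consensus_tsv <- function(profile, file, group = "family") {
  comp <- profile$groups[[group]]
  if (is.null(comp)) stop("no such group: ", group, call. = FALSE)
  df <- data.frame(column = seq_along(comp$conservation),
                   majority = comp$majority,
                   conservation = comp$conservation,
                   polarity = comp$polarity,
                   t(comp$freq), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Extract the signature residues of one aligned sequence
#'
#' Pulls the residues at the signature columns (located through the
#' reference map) out of a gapped alignment row. Positions where the row
#' carries a gap are reported as `-` and flagged.
#'
#' @param aln An [ldc_msa()].
#' @param id Row name of the sequence to extract.
#' @param refmap A [map_to_reference()] result for the same alignment.
#' @param sigdef A [signature_definition()].
#' @return A single string of signature residues with attributes
#'   `positions` (reference numbering) and `has_gaps`.
#' @export
extract_signature <- function(aln, id, refmap,
                              sigdef = signature_definition()) {
  if (!id %in% names(aln)) stop("no such row: ", id, call. = FALSE)
  cols <- ref_columns(refmap, sigdef$positions)
  if (all(is.na(cols)))
    stop("signature regions entirely unmapped on the reference",
         call. = FALSE)
  chars <- strsplit(unclass(aln)[[id]], "")[[1]]
  sig <- ifelse(is.na(cols), GAP, chars[ifelse(is.na(cols), 1L, cols)])
  structure(paste(sig, collapse = ""),
            positions = sigdef$positions,
            has_gaps = any(sig == GAP))
}

#' Per-group signature profiles
#'
#' Residue counts at every signature position for each group of training
#' sequences, plus the list of discriminating positions (positions whose
#' majority residue sets are disjoint between the two groups).
#'
#' @param signatures Named character vector of signature strings (all the
#'   same length), e.g. from [extract_signature()].
#' @param labels Named vector mapping sequence names to group ids (exactly
#'   two groups).
#' @param positions Optional reference positions of the signature slots.
#' @return A `signature_profiles` object with per-group count matrices.
#' @export
signature_profiles <- function(signatures, labels, positions = NULL) {
  stopifnot(!is.null(names(signatures)))
  labels <- labels[names(signatures)]
  if (anyNA(labels)) stop("every signature needs a group label",
                          call. = FALSE)
  gs <- sort(unique(labels))
  if (length(gs) != 2) stop("need exactly two groups", call. = FALSE)
  P <- nchar(signatures[1])
  if (any(nchar(signatures) != P))
    stop("signatures differ in length", call. = FALSE)
  chars <- do.call(rbind, strsplit(signatures, ""))
  counts <- lapply(gs, function(g) {
    sub <- chars[labels == g, , drop = FALSE]
    apply(sub, 2, function(col)
      as.numeric(table(factor(col, levels = AA20))))
  })
  counts <- lapply(counts, function(x) {
    dimnames(x) <- list(AA20, NULL); x
  })
  names(counts) <- gs
  maj_sets <- lapply(counts, function(cm)
    apply(cm, 2, function(v)
      if (max(v) == 0) character(0) else AA20[v == max(v)],
      simplify = FALSE))
  disc <- vapply(seq_len(P), function(j) {
    a <- maj_sets[[1]][[j]]; b <- maj_sets[[2]][[j]]
    length(a) > 0 && length(b) > 0 && length(intersect(a, b)) == 0
  }, logical(1))
  structure(list(counts = counts,
                 n = table(labels),
                 positions = if (is.null(positions)) seq_len(P)
                             else positions,
                 discriminating = which(disc)),
            class = "signature_profiles")
}

#' @export
print.signature_profiles <- function(x, ...) {
  gs <- names(x$counts)
  cat(sprintf("Signature profiles: %d positions, groups %s (n = %d, %d)\n",
              length(x$positions), paste(gs, collapse = " / "),
              x$n[[1]], x$n[[2]]))
  cat("discriminating positions:",
      paste(x$positions[x$discriminating], collapse = ", "), "\n")
  invisible(x)
}

#' Classify a sequence from its signature residues alone
#'
#' Position-wise log-odds against the per-group signature profiles with a
#' pseudocount and a uniform 1/20 background: the score of group g is
#' `sum_p log(((count_g(p, a) + k) / (n_g + 20 k)) / (1/20))` over the
#' non-gap signature positions. The label is the higher-scoring group; the
#' reported score is the (first group minus second group) log-odds
#' difference, and `"unknown"` is returned when no position is usable or
#' the margin is not exceeded.
#'
#' @param sig Signature string (as from [extract_signature()]).
#' @param profiles A [signature_profiles()] object.
#' @param pseudocount Added to every residue count (default 0.5).
#' @param margin Minimum absolute log-odds difference for a call
#'   (default 0: only exact ties are unknown).
#' @return List with `label`, `score` (signed log-odds, positive favours
#'   the first group) and per-group `scores`.
#' @export
classify_by_signature <- function(sig, profiles, pseudocount = 0.5,
                                  margin = 0) {
  chars <- strsplit(sig, "")[[1]]
  if (length(chars) != length(profiles$positions))
    stop("signature length does not match the profiles", call. = FALSE)
  usable <- chars %in% AA20
  gs <- names(profiles$counts)
  if (!any(usable))
    return(list(label = "unknown", score = 0,
                scores = setNames(c(0, 0), gs)))
  scores <- vapply(gs, function(g) {
    cm <- profiles$counts[[g]]
    n <- profiles$n[[g]]
    idx <- which(usable)
    sum(log((cm[cbind(match(chars[idx], AA20), idx)] + pseudocount) /
              (n + 20 * pseudocount)) - log(1 / 20))
  }, numeric(1))
  score <- scores[[1]] - scores[[2]]
  label <- if (abs(score) <= margin) "unknown"
           else gs[which.max(scores)]
  list(label = label, score = unname(score), scores = scores)
}

#' Design a chimeric sequence by swapping the signature regions
#'
#' Replaces the backbone's residues inside the signature regions by the
#' aligned donor residues, leaving every other backbone position
#' untouched - the in-silico analogue of the LdcIC / LdcCI constructs
#' (backbone LdcI with the C-terminal beta-sheet of LdcC, and vice versa).
#' Signature regions are located on the reference row of the pairwise
#' alignment (the backbone by default, since the region definition uses
#' E. coli LdcI numbering).
#'
#' @param backbone,donor Named single protein sequences.
#' @param sigdef A [signature_definition()].
#' @param aln Optional precomputed [global_align()] of backbone and donor;
#'   computed with default scoring when `NULL`.
#' @param reference Which sequence carries the reference numbering for
#'   `sigdef`: `"backbone"` (default) or `"donor"`.
#' @return Named chimeric sequence (single string) with attribute
#'   `junctions`, a data.frame reporting, per region, the replaced
#'   backbone segment and the donor segment inserted.
#' @export
design_chimera <- function(backbone, donor,
                           sigdef = signature_definition(), aln = NULL,
                           reference = c("backbone", "donor")) {
  reference <- match.arg(reference)
  bb_id <- if (!is.null(names(backbone))) names(backbone)[1] else "backbone"
  dn_id <- if (!is.null(names(donor))) names(donor)[1] else "donor"
  if (is.null(aln)) aln <- global_align(backbone, donor)
  ga <- strsplit(aln$a, "")[[1]]
  gb <- strsplit(aln$b, "")[[1]]
  if (degap(aln$a) != unname(backbone[1]) ||
      degap(aln$b) != unname(donor[1]))
    stop("alignment does not degap to the given sequences", call. = FALSE)
  ref_chars <- if (reference == "backbone") ga else gb
  ref_cols <- which(ref_chars != GAP)

  regions <- list(strand1 = sigdef$strand1, strand2 = sigdef$strand2)
  in_region <- logical(length(ga))
  junctions <- data.frame(region = character(0), ref_start = integer(0),
                          ref_end = integer(0),
                          backbone_segment = character(0),
                          donor_segment = character(0))
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    pos <- seq(rg[1], min(rg[2], length(ref_cols)))
    if (length(pos) == 0) next
    cols <- ref_cols[pos]
    dn_seg <- gb[min(cols):max(cols)]
    if (all(dn_seg == GAP))
      stop(sprintf("donor is entirely gapped in region %s: %d-%d",
                   rn, rg[1], rg[2]), call. = FALSE)
    in_region[min(cols):max(cols)] <- TRUE
    junctions <- rbind(junctions, data.frame(
      region = rn, ref_start = rg[1], ref_end = rg[2],
      backbone_segment = paste(ga[min(cols):max(cols)][
        ga[min(cols):max(cols)] != GAP], collapse = ""),
      donor_segment = paste(dn_seg[dn_seg != GAP], collapse = "")))
  }
  out_chars <- ifelse(in_region, gb, ga)
  chimera <- paste(out_chars[out_chars != GAP], collapse = "")
  structure(setNames(chimera, paste0(bb_id, "_", dn_id, "_chimera")),
            junctions = junctions)
}
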