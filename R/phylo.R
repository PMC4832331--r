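# Distance-based phylogenetics for the lysine-decarboxylase family:
# pairwise distances (WAG maximum-likelihood, Poisson-corrected, or raw
# p-distance), neighbor-joining, column-resampling bootstrap supports and
# the two-group bipartition test.

#' Pairwise evolutionary distances from a protein alignment
#'
#' Gap-containing columns are excluded pairwise. `"wag"` maximizes the
#' two-sequence likelihood over the branch length under the WAG empirical
#' substitution model (via phangorn); `"poisson"` applies the correction
#' `-ln(1 - p)` to the mismatch fraction p; `"p"` is the raw mismatch
#' fraction. Poisson distances at `p >= saturation_p` are capped at
#' `saturation_cap` and flagged in the `"saturated"` attribute.
#'
#' @param aln An [ldc_msa()].
#' @param model One of `"wag"`, `"poisson"`, `"p"`.
#' @param saturation_p,saturation_cap Saturation handling for the Poisson
#'   correction (defaults 0.85 and 5.0).
#' @return Symmetric numeric matrix with taxon dimnames; attributes
#'   `model` and (for `"poisson"`) `saturated`.
#' @export
pairwise_distance <- function(aln, model = c("wag", "poisson", "p"),
                              saturation_p = 0.85, saturation_cap = 5.0) {
  model <- match.arg(model)
  m <- msa_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences", call. = FALSE)
  if (model == "wag") {
    pd <- phangorn::phyDat(m, type = "AA")
    D <- as.matrix(phangorn::dist.ml(pd, model = "WAG"))
    D <- D[rownames(m), rownames(m)]
    attr(D, "model") <- "wag"
    return(D)
  }
  codes <- t(apply(m, 1, function(r) {
    v <- match(r, AA20)
    v[is.na(v)] <- 0L
    v
  }))
  res <- pdist_cpp(codes)
  if (any(res$n[upper.tri(res$n)] == 0)) {
    bad <- which(res$n == 0 & upper.tri(res$n), arr.ind = TRUE)[1, ]
    stop(sprintf("no overlapping ungapped columns for pair %s / %s",
                 rownames(m)[bad[1]], rownames(m)[bad[2]]), call. = FALSE)
  }
  p <- res$p
  dimnames(p) <- list(rownames(m), rownames(m))
  if (model == "p") {
    attr(p, "model") <- "p"
    return(p)
  }
  sat <- p >= saturation_p
  D <- -log(1 - pmin(p, saturation_p - 1e-12))
  D[sat] <- saturation_cap
  diag(D) <- 0
  dimnames(D) <- dimnames(p)
  attr(D, "model") <- "poisson"
  attr(D, "saturated") <- sat
  if (any(sat[upper.tri(sat)]))
    warning("saturated pairs capped at ", saturation_cap)
  D
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance input must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(d)))
    stop("distance matrix has non-finite entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch lengths, which NJ
#' can produce on non-additive input, are clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with taxon dimnames (3+ taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 3) stop("need at least three taxa", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# canonical string keys for the non-trivial bipartitions of an unrooted
# tree: each internal edge splits the leaves in two; the key is the sorted
# smaller side (ties broken lexicographically)
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tips[p])
    if (length(side) <= 1 || length(side) >= n - 1) next
    other <- sort(setdiff(tips, side))
    pick <- if (length(side) < length(other)) side
            else if (length(side) > length(other)) other
            else if (paste(side, collapse = "|") <
                     paste(other, collapse = "|")) side else other
    keys <- c(keys, paste(pick, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the
#' point-estimate tree the percentage of replicates whose tree contains the
#' same bipartition. Supports are attached as `node.label` (NA for nodes
#' without an associated non-trivial bipartition) and the replicate trees
#' are kept in the `"replicates"` attribute.
#'
#' @param aln An [ldc_msa()].
#' @param model Distance model passed to [pairwise_distance()]; the
#'   default `"poisson"` keeps replicates fast.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; required, for reproducible resampling.
#' @return The point-estimate `phylo` tree with `node.label` supports in
#'   \[0, 100\] and attributes `n_reps` and `replicates`.
#' @export
bootstrap_supports <- function(aln, model = "poisson", n_reps = 100,
                               seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  point <- nj_tree(pairwise_distance(aln, model))
  m <- msa_matrix(aln)
  L <- ncol(m)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- ldc_msa(setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                      collapse = ""), rownames(m)))
    reps[[r]] <- suppressWarnings(
      nj_tree(pairwise_distance(rep_aln, model)))
  }
  rep_keys <- lapply(reps, tree_bipartitions)
  # per internal node of the point tree: bipartition key of the edge above
  tips <- point$tip.label
  n_tip <- length(tips)
  node_support <- rep(NA_real_, point$Nnode)
  for (node in seq_len(point$Nnode) + n_tip) {
    desc <- tips[phangorn::Descendants(point, node, "tips")[[1]]]
    if (length(desc) <= 1 || length(desc) >= n_tip - 1) next
    side <- sort(desc)
    other <- sort(setdiff(tips, side))
    pick <- if (length(side) < length(other)) side
            else if (length(side) > length(other)) other
            else if (paste(side, collapse = "|") <
                     paste(other, collapse = "|")) side else other
    key <- paste(pick, collapse = "|")
    node_support[node - n_tip] <-
      100 * mean(vapply(rep_keys, function(k) key %in% k, logical(1)))
  }
  point$node.label <- node_support
  attr(point, "n_reps") <- n_reps
  attr(point, "replicates") <- reps
  point
}

#' Does some internal edge split the tree exactly into two given groups?
#'
#' @param tree A `phylo` tree.
#' @param groupA,groupB Character vectors of taxon names; together they
#'   must partition the leaf set and must not overlap.
#' @return `TRUE` or `FALSE`, with attribute `"support"` carrying the
#'   bootstrap support of the separating edge when `tree` has node labels
#'   from [bootstrap_supports()].
#' @export
bipartition_separates <- function(tree, groupA, groupB) {
  if (length(intersect(groupA, groupB)) > 0)
    stop("groups overlap", call. = FALSE)
  if (!setequal(c(groupA, groupB), tree$tip.label))
    stop("groups must partition the leaf set", call. = FALSE)
  if (length(groupA) < 1 || length(groupB) < 1)
    return(structure(FALSE, support = NA_real_))
  tips <- tree$tip.label
  n_tip <- length(tips)
  targetA <- sort(groupA)
  targetB <- sort(groupB)
  found <- FALSE
  support <- NA_real_
  for (node in seq_len(tree$Nnode) + n_tip) {
    desc <- sort(tips[phangorn::Descendants(tree, node, "tips")[[1]]])
    if (identical(desc, targetA) || identical(desc, targetB)) {
      found <- TRUE
      if (!is.null(tree$node.label))
        support <- as.numeric(tree$node.label[node - n_tip])
      break
    }
  }
  structure(found, support = support)
}

#' Fraction of bootstrap replicates separating two groups
#'
#' @param boot_tree Result of [bootstrap_supports()] (carries the
#'   replicate trees).
#' @param groupA,groupB Taxon sets partitioning the leaves.
#' @return Percentage of replicates whose tree contains the exact
#'   \{groupA | groupB\} bipartition.
#' @export
group_edge_support <- function(boot_tree, groupA, groupB) {
  reps <- attr(boot_tree, "replicates")
  if (is.null(reps)) stop("no replicate trees attached", call. = FALSE)
  100 * mean(vapply(reps, function(tr)
    as.logical(bipartition_separates(tr, groupA, groupB)), logical(1)))
}

#' Write a distance matrix in square PHYLIP format
#' @param d Distance matrix.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_phylip_dist <- function(d, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(file)
}
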