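# Synthetic two-group lysine-decarboxylase families: sequences evolved
# along a shared tree under an empirical substitution model, with
# group-specific residues planted in the two C-terminal signature regions,
# plus matching gene-neighborhood tables. Everything is seeded and
# deterministic.

default_signature_table <- function() {
  # Y697 (groupA) / K697 (groupB) mirrors the strict dimorphism of the
  # family; the remaining rows are synthetic polarity-contrasting pairs.
  data.frame(
    position = c(631L, 632L, 634L, 636L, 640L,
                 697L, 701L, 705L, 710L, 715L),
    groupA = c("D", "E", "R", "F", "IV", "Y", "N", "K", "W", "LM"),
    groupB = c("N", "Q", "T", "D", "KR", "K", "L", "E", "S", "DE"),
    stringsAsFactors = FALSE)
}

#' Parameters for the synthetic family generator
#'
#' Defaults emulate the study conditions of the enterobacterial
#' lysine-decarboxylase family: 11 taxa per group (22 total), full protein
#' length 715, signature regions 631-640 and 697-715 in reference
#' numbering with a strict Y/K dimorphism at position 697, WAG background
#' evolution, 0.5 expected substitutions/site between the two groups and
#' no indels (so reference numbering is trivial).
#'
#' @param n_taxa_per_group Taxa per group (>= 2).
#' @param seq_length Protein length (columns of the true alignment).
#' @param signature_regions List of two `c(start, end)` intervals,
#'   1-based inclusive, in reference numbering.
#' @param signature_table Data frame with columns `position`, `groupA`,
#'   `groupB`; each group entry is a string of allowed residues (e.g.
#'   `"IV"` for \{I, V\}) and the two sets must be disjoint per position.
#' @param background_model `"WAG"` (empirical exchangeabilities) or
#'   `"uniform"` (equal-rate 20-state model).
#' @param between_divergence Expected substitutions/site separating the
#'   two group ancestors.
#' @param within_height Expected root-to-tip substitutions/site inside
#'   each group.
#' @param indel_rate Deletion events per site per sequence (default 0;
#'   signature regions are always indel-protected).
#' @param seed Integer seed; fully determines the output.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_taxa_per_group = 11,
                              seq_length = 715,
                              signature_regions = list(c(631, 640),
                                                       c(697, 715)),
                              signature_table = default_signature_table(),
                              background_model = c("WAG", "uniform"),
                              between_divergence = 0.5,
                              within_height = 0.15,
                              indel_rate = 0,
                              seed = 1) {
  background_model <- match.arg(background_model)
  stopifnot(n_taxa_per_group >= 2, seq_length >= 1,
            length(signature_regions) == 2,
            between_divergence >= 0, within_height >= 0, indel_rate >= 0)
  region_pos <- unlist(lapply(signature_regions,
                              function(r) seq(r[1], r[2])))
  if (any(region_pos < 1) || any(region_pos > seq_length))
    stop("signature interval outside sequence length", call. = FALSE)
  if (anyDuplicated(region_pos))
    stop("signature regions overlap", call. = FALSE)
  tb <- signature_table
  stopifnot(all(c("position", "groupA", "groupB") %in% names(tb)))
  if (!all(tb$position %in% region_pos))
    stop("signature table positions must lie inside the regions",
         call. = FALSE)
  for (i in seq_len(nrow(tb))) {
    sa <- strsplit(tb$groupA[i], "")[[1]]
    sb <- strsplit(tb$groupB[i], "")[[1]]
    if (!all(c(sa, sb) %in% AA20))
      stop("signature residues must be standard amino acids",
           call. = FALSE)
    if (length(intersect(sa, sb)) > 0)
      stop(sprintf("group residue sets overlap at position %d",
                   tb$position[i]), call. = FALSE)
  }
  structure(list(n_taxa_per_group = n_taxa_per_group,
                 seq_length = seq_length,
                 signature_regions = signature_regions,
                 signature_table = tb,
                 background_model = background_model,
                 between_divergence = between_divergence,
                 within_height = within_height,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Sample a random rooted binary tree
#'
#' Random topology (via ape) with branch lengths rescaled so the mean
#' root-to-tip path length equals `height`.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param height Target mean root-to-tip path in substitutions/site.
#' @param seed Integer seed.
#' @return A rooted binary `phylo` tree with positive branch lengths.
#' @export
sample_tree <- function(n_taxa, height, seed) {
  if (n_taxa < 3) stop("need at least three taxa", call. = FALSE)
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  depth <- mean(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
  tr$edge.length <- tr$edge.length * height / depth
  tr
}

#' Two-group tree: two random subtrees joined by a long internal branch
#'
#' @param n_per_group Taxa per group (>= 2).
#' @param between Expected substitutions/site between the group ancestors
#'   (the joining branch).
#' @param within Mean root-to-tip height inside each subtree.
#' @param seed Integer seed.
#' @return A rooted `phylo` tree with tips `A01..` / `B01..` and a
#'   `"groups"` attribute (named vector of `"A"` / `"B"`).
#' @export
two_group_tree <- function(n_per_group, between = 0.5, within = 0.15,
                           seed = 1) {
  stopifnot(n_per_group >= 2)
  set.seed(seed)
  grow_subtree <- function(prefix) {
    tr <- ape::rtree(n_per_group)
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    depth <- mean(ape::node.depth.edgelength(tr)[seq_len(n_per_group)])
    tr$edge.length <- tr$edge.length * within / max(depth, 1e-12)
    tr$tip.label <- sprintf("%s%02d", prefix,
                            as.integer(sub("t", "", tr$tip.label)))
    tr
  }
  tA <- grow_subtree("A"); tB <- grow_subtree("B")
  nwk <- sprintf("(%s:%f,%s:%f);",
                 sub(";$", "", ape::write.tree(tA)), between / 2,
                 sub(";$", "", ape::write.tree(tB)), between / 2)
  tr <- ape::read.tree(text = nwk)
  groups <- setNames(substr(tr$tip.label, 1, 1), tr$tip.label)
  attr(tr, "groups") <- groups
  tr
}

#' Evolve a signature-planted protein alignment along a tree
#'
#' Background columns evolve under the chosen substitution model
#' (phangorn's sequence simulator); the planted signature positions are
#' then overwritten, per leaf, with a residue drawn uniformly from that
#' leaf's group set. With `indel_rate > 0`, deletion events of geometric
#' length are scattered over non-signature columns.
#'
#' @param tree A `phylo` tree whose tips are the taxa.
#' @param params A [simulation_params()] object.
#' @param group_labels Named vector mapping tip labels to `"A"` / `"B"`;
#'   taken from `attr(tree, "groups")` when missing.
#' @return An [ldc_msa()] with attributes `groups`, `signature_log`
#'   (data.frame: taxon, position, residue) and `params`.
#' @export
evolve_alignment <- function(tree, params, group_labels = NULL) {
  if (is.null(group_labels)) group_labels <- attr(tree, "groups")
  if (is.null(group_labels) ||
      !all(tree$tip.label %in% names(group_labels)))
    stop("every leaf needs a group label", call. = FALSE)
  if (!all(group_labels[tree$tip.label] %in% c("A", "B")))
    stop("group labels must be 'A' or 'B'", call. = FALSE)
  set.seed(params$seed)
  sim <- if (params$background_model == "WAG") {
    phangorn::simSeq(tree, l = params$seq_length, type = "AA",
                     model = "WAG")
  } else {
    phangorn::simSeq(tree, l = params$seq_length, type = "AA")
  }
  m <- toupper(as.character(sim))
  m <- m[tree$tip.label, , drop = FALSE]

  tb <- params$signature_table
  log <- data.frame(taxon = character(0), position = integer(0),
                    residue = character(0))
  for (i in seq_len(nrow(tb))) {
    pos <- tb$position[i]
    sets <- list(A = strsplit(tb$groupA[i], "")[[1]],
                 B = strsplit(tb$groupB[i], "")[[1]])
    for (tx in tree$tip.label) {
      set <- sets[[group_labels[[tx]]]]
      res <- set[sample.int(length(set), 1)]
      m[tx, pos] <- res
      log <- rbind(log, data.frame(taxon = tx, position = pos,
                                   residue = res))
    }
  }

  if (params$indel_rate > 0) {
    protected <- unlist(lapply(params$signature_regions,
                               function(r) seq(r[1], r[2])))
    for (tx in tree$tip.label) {
      n_ev <- stats::rpois(1, params$indel_rate * params$seq_length)
      if (n_ev == 0) next
      for (e in seq_len(n_ev)) {
        len <- stats::rgeom(1, 0.5) + 1
        start <- sample.int(params$seq_length, 1)
        cols <- setdiff(seq(start, min(start + len - 1,
                                       params$seq_length)), protected)
        if (length(cols) > 0) m[tx, cols] <- GAP
      }
    }
  }

  aln <- ldc_msa(setNames(apply(m, 1, paste, collapse = ""),
                          rownames(m)))
  attr(aln, "groups") <- group_labels[names(aln)]
  attr(aln, "signature_log") <- log
  attr(aln, "params") <- params
  aln
}

#' Generate a gene-neighborhood table consistent with the group labels
#'
#' Group-A genes get a cadB-style antiporter partner flagged same-operon
#' (the ldcI-like context); group-B genes are flanked by accA and yaeR
#' (the ldcC-like context). With `mislabel_rate > 0`, a fraction of the
#' stated annotations is corrupted (A -> "ldcC"; B -> "ldcI" or "cadA"),
#' and the corrupted rows are recorded in the `"injection_log"` attribute
#' for audit tests.
#'
#' @param leaves Character vector of taxon ids.
#' @param group_labels Named vector of `"A"` / `"B"` covering `leaves`.
#' @param mislabel_rate Fraction of rows whose stated annotation is
#'   corrupted (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns `gene_id`, `taxon`, `strand`,
#'   `upstream_gene`, `downstream_gene`, `same_operon_flag`,
#'   `stated_annotation`; attribute `injection_log`.
#' @export
gen_neighborhood_table <- function(leaves, group_labels,
                                   mislabel_rate = 0, seed = 1) {
  if (!all(leaves %in% names(group_labels)))
    stop("every leaf needs a group label", call. = FALSE)
  set.seed(seed)
  other_genes <- c("yjdC", "pheA", "trpB", "metE", "rpoD")
  n <- length(leaves)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  up <- character(n); down <- character(n)
  operon <- logical(n); stated <- character(n)
  for (i in seq_len(n)) {
    g <- group_labels[[leaves[i]]]
    if (g == "A") {
      side <- sample(c("up", "down"), 1)
      filler <- sample(other_genes, 1)
      if (side == "up") { up[i] <- "cadB"; down[i] <- filler }
      else { up[i] <- filler; down[i] <- "cadB" }
      operon[i] <- TRUE
      stated[i] <- "ldcI"
    } else {
      if (sample(c(TRUE, FALSE), 1)) { up[i] <- "accA"; down[i] <- "yaeR" }
      else { up[i] <- "yaeR"; down[i] <- "accA" }
      operon[i] <- FALSE
      stated[i] <- "ldcC"
    }
  }
  flip <- runif(n) < mislabel_rate
  for (i in which(flip)) {
    g <- group_labels[[leaves[i]]]
    stated[i] <- if (g == "A") "ldcC" else sample(c("ldcI", "cadA"), 1)
  }
  tab <- data.frame(gene_id = paste0("ldc_", leaves), taxon = leaves,
                    strand = strand, upstream_gene = up,
                    downstream_gene = down, same_operon_flag = operon,
                    stated_annotation = stated,
                    stringsAsFactors = FALSE)
  attr(tab, "injection_log") <-
    data.frame(gene_id = tab$gene_id[flip], taxon = leaves[flip],
               true_group = unname(group_labels[leaves[flip]]),
               stated = stated[flip], stringsAsFactors = FALSE)
  tab
}

#' Simulate a complete synthetic family (tree, alignment, neighborhoods)
#'
#' Convenience wrapper chaining [two_group_tree()], [evolve_alignment()]
#' and [gen_neighborhood_table()] under a single seed.
#'
#' @param params A [simulation_params()].
#' @param mislabel_rate Passed to [gen_neighborhood_table()].
#' @return List with `tree`, `alignment`, `neighborhoods`, `groups`.
#' @export
simulate_ldc_family <- function(params = simulation_params(),
                                mislabel_rate = 0) {
  tree <- two_group_tree(params$n_taxa_per_group,
                         between = params$between_divergence,
                         within = params$within_height,
                         seed = params$seed)
  aln <- evolve_alignment(tree, params)
  groups <- attr(tree, "groups")
  nb <- gen_neighborhood_table(tree$tip.label, groups,
                               mislabel_rate = mislabel_rate,
                               seed = params$seed + 1L)
  list(tree = tree, alignment = aln, neighborhoods = nb,
       groups = groups)
}
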