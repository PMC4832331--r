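# End-to-end concordance analysis: do the genetic environment, the
# C-terminal beta-sheet signature alone, and the whole-sequence phylogeny
# partition a set of lysine decarboxylases into the same two groups?

#' Run the full context / signature / tree concordance analysis
#'
#' Stages: (1) audit the gene-neighborhood table and classify every gene
#' by genetic environment; (2) align the sequences (unless an alignment
#' is supplied); (3) extract the two C-terminal signature regions via the
#' reference numbering and classify every sequence from the signature
#' alone, training the per-group profiles on the context calls with the
#' query held out (leave-one-out); (4) build the NJ tree and test whether
#' an internal edge separates the two signature-defined groups, in which
#' case the edge's sides define the tree grouping; optionally (5)
#' bootstrap the alignment and report the support of the group edge.
#'
#' @param sequences Named character vector of protein sequences, or a
#'   FASTA path. Names must match the `taxon` column of `neighborhoods`.
#' @param neighborhoods Neighborhood table (data.frame) or TSV path.
#' @param reference_id Row whose residue numbering anchors the signature
#'   regions; defaults to the first sequence.
#' @param sigdef A [signature_definition()].
#' @param model Distance model for the tree stage (see
#'   [pairwise_distance()]).
#' @param n_boot Bootstrap replicates for the group-edge support
#'   (0 = skip).
#' @param seed Integer seed (bootstrap resampling).
#' @param aln Optional precomputed [ldc_msa()]; when `NULL` the sequences
#'   are aligned with [progressive_msa()].
#' @return A `concordance_report`: per-taxon calls, pairwise agreement
#'   rates (percent), discordant taxa, and the group-edge bootstrap
#'   support when requested.
#' @export
run_concordance <- function(sequences, neighborhoods,
                            reference_id = NULL,
                            sigdef = signature_definition(),
                            model = "poisson", n_boot = 0, seed = 1,
                            aln = NULL) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.character(neighborhoods) && length(neighborhoods) == 1)
    neighborhoods <- read_neighborhood_tsv(neighborhoods)
  if (length(sequences) == 0)
    stop("no input sequences", call. = FALSE)
  taxa <- names(sequences)
  off_seq <- setdiff(taxa, neighborhoods$taxon)
  off_nb <- setdiff(neighborhoods$taxon, taxa)
  if (length(off_seq) > 0 || length(off_nb) > 0)
    stop("taxa mismatch between sequences and neighborhoods: ",
         paste(c(off_seq, off_nb), collapse = ", "), call. = FALSE)
  if (is.null(reference_id)) reference_id <- taxa[1]

  # stage 1: genetic environment
  ctx <- audit_annotations(neighborhoods)
  context_call <- setNames(ctx$call, ctx$taxon)[taxa]

  # stage 2: alignment + reference numbering
  if (is.null(aln)) aln <- progressive_msa(sequences)
  refmap <- map_to_reference(aln, reference_id)

  # stage 3: signature classification (leave-one-out on context labels)
  sigs <- vapply(taxa, function(tx)
    as.character(extract_signature(aln, tx, refmap, sigdef)),
    character(1))
  train_lab <- context_call[context_call %in% c("ldcI-like", "ldcC-like")]
  if (length(unique(train_lab)) < 2)
    stop("context stage found fewer than two groups; cannot train ",
         "the signature classifier", call. = FALSE)
  signature_call <- setNames(rep("unknown", length(taxa)), taxa)
  for (tx in taxa) {
    keep <- setdiff(names(train_lab), tx)
    if (length(unique(train_lab[keep])) < 2) next
    prof <- signature_profiles(sigs[keep], train_lab[keep],
                               positions = sigdef$positions)
    signature_call[tx] <- classify_by_signature(sigs[tx], prof)$label
  }

  # stage 4: tree grouping from the signature-defined split
  dist <- pairwise_distance(aln, model)
  tree <- nj_tree(dist)
  gI <- taxa[signature_call == "ldcI-like"]
  gC <- taxa[signature_call == "ldcC-like"]
  tree_call <- setNames(rep(NA_character_, length(taxa)), taxa)
  separable <- FALSE
  if (length(gI) >= 1 && length(gC) >= 1 &&
      length(gI) + length(gC) == length(taxa)) {
    separable <- as.logical(bipartition_separates(tree, gI, gC))
    if (separable) {
      tree_call[gI] <- "ldcI-like"
      tree_call[gC] <- "ldcC-like"
    }
  }

  # stage 5: bootstrap support of the group edge
  support <- NA_real_
  if (n_boot > 0 && length(gI) >= 1 && length(gC) >= 1) {
    boot <- bootstrap_supports(aln, model = model, n_reps = n_boot,
                               seed = seed)
    support <- group_edge_support(boot, gI, gC)
  }

  agree <- function(x, y) {
    ok <- !is.na(x) & !is.na(y) & x != "unknown" & y != "unknown"
    if (!any(ok)) return(NA_real_)
    100 * mean(x[ok] == y[ok])
  }
  rates <- c(context_signature = agree(context_call, signature_call),
             context_tree = agree(context_call, tree_call),
             signature_tree = agree(signature_call, tree_call))
  tab <- data.frame(taxon = taxa, context = unname(context_call),
                    signature = unname(signature_call),
                    tree = unname(tree_call), stringsAsFactors = FALSE)
  disc <- tab$taxon[apply(tab[2:4], 1, function(r) {
    r <- r[!is.na(r) & r != "unknown"]
    length(unique(r)) > 1
  })]
  structure(list(calls = tab, rates = rates, discordant = disc,
                 tree_separable = separable, group_edge_support = support,
                 tree = tree, alignment = aln, context = ctx,
                 params = list(reference_id = reference_id, model = model,
                               n_boot = n_boot, seed = seed)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance of context / signature / tree groupings\n")
  cat(sprintf("  taxa: %d   tree split separable: %s\n",
              nrow(x$calls), x$tree_separable))
  r <- x$rates
  fmt <- function(v) if (is.na(v)) "not separable" else sprintf("%.1f%%", v)
  cat(sprintf("  context vs signature: %s\n", fmt(r["context_signature"])))
  cat(sprintf("  context vs tree:      %s\n", fmt(r["context_tree"])))
  cat(sprintf("  signature vs tree:    %s\n", fmt(r["signature_tree"])))
  if (!is.na(x$group_edge_support))
    cat(sprintf("  group-edge bootstrap support: %.1f%% (%d replicates)\n",
                x$group_edge_support, x$params$n_boot))
  if (length(x$discordant) > 0)
    cat("  discordant taxa:", paste(x$discordant, collapse = ", "), "\n")
  else cat("  no discordant taxa\n")
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  print(object)
  cat("\nPer-taxon calls:\n")
  print.data.frame(object$calls, row.names = FALSE)
  invisible(object)
}
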